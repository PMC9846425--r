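// Glocal profile-HMM dynamic programming (forward and Viterbi), log space.
//
// State layout follows the classic profile architecture: match states
// M_1..M_k, insert states I_0..I_k, delete states D_1..D_k, with Begin
// treated as M_0 and End as M_{k+1}. Transition matrices have k+1 rows
// (row j+1 holds transitions out of column j, 0-based j = 0..k) and three
// columns: to next-M (End when j = k), to I_j, to next-D (invalid at
// j = k, kept at -Inf).
//
// EM is k x L: log emission of query residue i under match state j.
// EI is (k+1) x L: log emission under insert state j (j = 0..k).
// All probabilities natural-log; impossible events are -Inf.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(const NumericMatrix& EM, const NumericMatrix& EI,
                    const NumericMatrix& tM, const NumericMatrix& tI,
                    const NumericMatrix& tD) {
  const int k = EM.nrow();
  const int L = EM.ncol();
  // DP tables (k+1) x (L+1); index [j][i]
  NumericMatrix M(k + 1, L + 1), I(k + 1, L + 1), D(k + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  M(0, 0) = 0.0;  // Begin

  // i = 0 column: delete chain only
  for (int j = 1; j <= k; ++j) {
    D(j, 0) = lse3(M(j - 1, 0) + tM(j - 1, 2),
                   I(j - 1, 0) + tI(j - 1, 2),
                   D(j - 1, 0) + tD(j - 1, 2));
  }
  for (int i = 1; i <= L; ++i) {
    for (int j = 0; j <= k; ++j) {
      I(j, i) = EI(j, i - 1) + lse3(M(j, i - 1) + tM(j, 1),
                                    I(j, i - 1) + tI(j, 1),
                                    D(j, i - 1) + tD(j, 1));
      if (j > 0) {
        M(j, i) = EM(j - 1, i - 1) + lse3(M(j - 1, i - 1) + tM(j - 1, 0),
                                          I(j - 1, i - 1) + tI(j - 1, 0),
                                          D(j - 1, i - 1) + tD(j - 1, 0));
      }
    }
    for (int j = 1; j <= k; ++j) {
      D(j, i) = lse3(M(j - 1, i) + tM(j - 1, 2),
                     I(j - 1, i) + tI(j - 1, 2),
                     D(j - 1, i) + tD(j - 1, 2));
    }
  }
  return lse3(M(k, L) + tM(k, 0), I(k, L) + tI(k, 0), D(k, L) + tD(k, 0));
}

// Viterbi. Returns list(logp, path) where path is an n_steps x 2 integer
// matrix: column 1 state type (1 = M, 2 = I, 3 = D), column 2 the profile
// column index (M/D: 1..k, I: 0..k). Begin/End are omitted from the path.
// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(const NumericMatrix& EM, const NumericMatrix& EI,
                  const NumericMatrix& tM, const NumericMatrix& tI,
                  const NumericMatrix& tD) {
  const int k = EM.nrow();
  const int L = EM.ncol();
  NumericMatrix M(k + 1, L + 1), I(k + 1, L + 1), D(k + 1, L + 1);
  IntegerMatrix PM(k + 1, L + 1), PI(k + 1, L + 1), PD(k + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  M(0, 0) = 0.0;

  auto best3 = [](double a, double b, double c, int& arg) {
    double m = a; arg = 1;
    if (b > m) { m = b; arg = 2; }
    if (c > m) { m = c; arg = 3; }
    if (m == NEG_INF) arg = 0;
    return m;
  };

  int arg;
  for (int j = 1; j <= k; ++j) {
    D(j, 0) = best3(M(j - 1, 0) + tM(j - 1, 2),
                    I(j - 1, 0) + tI(j - 1, 2),
                    D(j - 1, 0) + tD(j - 1, 2), arg);
    PD(j, 0) = arg;
  }
  for (int i = 1; i <= L; ++i) {
    for (int j = 0; j <= k; ++j) {
      I(j, i) = EI(j, i - 1) + best3(M(j, i - 1) + tM(j, 1),
                                     I(j, i - 1) + tI(j, 1),
                                     D(j, i - 1) + tD(j, 1), arg);
      PI(j, i) = arg;
      if (j > 0) {
        M(j, i) = EM(j - 1, i - 1) + best3(M(j - 1, i - 1) + tM(j - 1, 0),
                                           I(j - 1, i - 1) + tI(j - 1, 0),
                                           D(j - 1, i - 1) + tD(j - 1, 0), arg);
        PM(j, i) = arg;
      }
    }
    for (int j = 1; j <= k; ++j) {
      D(j, i) = best3(M(j - 1, i) + tM(j - 1, 2),
                      I(j - 1, i) + tI(j - 1, 2),
                      D(j - 1, i) + tD(j - 1, 2), arg);
      PD(j, i) = arg;
    }
  }
  double logp = best3(M(k, L) + tM(k, 0), I(k, L) + tI(k, 0),
                      D(k, L) + tD(k, 0), arg);
  if (arg == 0) {
    return List::create(Named("logp") = logp,
                        Named("path") = IntegerMatrix(0, 2));
  }
  // traceback
  std::vector<int> types, cols;
  int type = arg, j = k, i = L;
  while (!(type == 1 && j == 0 && i == 0)) {
    types.push_back(type);
    cols.push_back(j);
    int prev;
    if (type == 1) { prev = PM(j, i); --j; --i; }
    else if (type == 2) { prev = PI(j, i); --i; }
    else { prev = PD(j, i); --j; }
    type = prev;
  }
  const int n = (int) types.size();
  IntegerMatrix path(n, 2);
  for (int s = 0; s < n; ++s) {
    path(s, 0) = types[n - 1 - s];
    path(s, 1) = cols[n - 1 - s];
  }
  return List::create(Named("logp") = logp, Named("path") = path);
}
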