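// Profile-profile global alignment with affine gap costs (Needleman-
// Wunsch / Gotoh), used by the internal progressive backbone aligner.
//
// Profiles are A x L matrices of per-column residue frequencies
// (normalized by the number of sequences in the profile; gap mass is the
// remainder and contributes nothing to the column-column score).
// The first column of a gap run costs `gap_open`, each further column
// `gap_ext` (both negative).
//
// Returns an integer vector of edit ops over the merged columns:
// 1 = columns from both profiles, 2 = column from profile 1 against gaps,
// 3 = column from profile 2 against gaps.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_profile")]]
IntegerVector nw_profile(const NumericMatrix& p1, const NumericMatrix& p2,
                         const NumericMatrix& S,
                         double gap_open, double gap_ext) {
  const int A = p1.nrow();
  const int L1 = p1.ncol(), L2 = p2.ncol();

  // column-column substitution scores
  NumericMatrix sub(L1, L2);
  // precompute S %*% p2 for speed: (A x L2)
  NumericMatrix Sp2(A, L2);
  for (int j = 0; j < L2; ++j)
    for (int a = 0; a < A; ++a) {
      double acc = 0.0;
      for (int b = 0; b < A; ++b) acc += S(a, b) * p2(b, j);
      Sp2(a, j) = acc;
    }
  for (int i = 0; i < L1; ++i)
    for (int j = 0; j < L2; ++j) {
      double acc = 0.0;
      for (int a = 0; a < A; ++a) acc += p1(a, i) * Sp2(a, j);
      sub(i, j) = acc;
    }

  // Gotoh: M = i,j aligned; X = gap in p2 (consume p1 col); Y = gap in p1
  NumericMatrix M(L1 + 1, L2 + 1), X(L1 + 1, L2 + 1), Y(L1 + 1, L2 + 1);
  IntegerMatrix PM(L1 + 1, L2 + 1), PX(L1 + 1, L2 + 1), PY(L1 + 1, L2 + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(X.begin(), X.end(), NEG_INF);
  std::fill(Y.begin(), Y.end(), NEG_INF);
  M(0, 0) = 0.0;
  for (int i = 1; i <= L1; ++i) {
    X(i, 0) = gap_open + (i - 1) * gap_ext;
    PX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= L2; ++j) {
    Y(0, j) = gap_open + (j - 1) * gap_ext;
    PY(0, j) = (j == 1) ? 1 : 3;
  }

  auto best3 = [](double a, double b, double c, int& arg) {
    double m = a; arg = 1;
    if (b > m) { m = b; arg = 2; }
    if (c > m) { m = c; arg = 3; }
    return m;
  };

  int arg;
  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      M(i, j) = sub(i - 1, j - 1) +
        best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), arg);
      PM(i, j) = arg;
      X(i, j) = best3(M(i - 1, j) + gap_open, X(i - 1, j) + gap_ext,
                      Y(i - 1, j) + gap_open, arg);
      PX(i, j) = arg;
      Y(i, j) = best3(M(i, j - 1) + gap_open, X(i, j - 1) + gap_open,
                      Y(i, j - 1) + gap_ext, arg);
      PY(i, j) = arg;
    }
  }

  int state;
  best3(M(L1, L2), X(L1, L2), Y(L1, L2), state);
  std::vector<int> ops;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    if (state == 1) {
      ops.push_back(1);
      state = PM(i, j); --i; --j;
    } else if (state == 2) {
      ops.push_back(2);
      state = PX(i, j); --i;
    } else {
      ops.push_back(3);
      state = PY(i, j); --j;
    }
  }
  IntegerVector out(ops.size());
  for (size_t s = 0; s < ops.size(); ++s) out[s] = ops[ops.size() - 1 - s];
  return out;
}
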