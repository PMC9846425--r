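## Dirichlet prior over outgoing transitions, one weight vector per source
## state type (targets M, I, D), scaled by the pseudocount. An informative
## prior -- strongly favoring match continuation and making delete runs
## sticky -- is what keeps Viterbi placements of short fragments contiguous
## when subset alignments are tiny (a flat prior leaves unobserved delete
## states with uniform exits, so a fragment pays nothing to hop out of a
## delete run onto any coincidentally matching column). Weights follow the
## shape of the single-component priors used by standard profile builders.
TRANS_PRIOR <- list(
  M = c(0.951, 0.033, 0.016),
  I = c(0.530, 0.450, 0.020),
  D = c(0.615, 0.025, 0.360))

#' Build a profile HMM from a subset alignment
#'
#' Constructs a glocal (global in the model, global in the query) profile
#' hidden Markov model in the classic match/insert/delete architecture.
#' Columns whose non-gap fraction is at least 0.5 become match states
#' (mirroring the default match-column rule of standard profile builders);
#' the remaining columns train the insert states. Emissions are count
#' estimates over the training rows with a Laplace pseudocount; transitions
#' are count estimates regularized by an informative Dirichlet prior scaled
#' by the same pseudocount (see `TRANS_PRIOR` in the sources). Every
#' parameter is strictly positive, so all scores stay finite. The null
#' model is the background residue frequency of the whole subalignment.
#'
#' @param subaln An [msa] to train on.
#' @param pseudocount Positive Laplace pseudocount (default 1).
#' @return An object of class `profile_hmm` with elements `k` (number of
#'   match states), `match_cols` (subalignment column indices of the match
#'   columns), log emission matrices, log transition matrices and the log
#'   background (null) frequencies.
#' @export
build_profile <- function(subaln, pseudocount = 1) {
  stopifnot(inherits(subaln, "msa"), pseudocount > 0)
  alph <- resolve_alphabet(subaln$alphabet)
  res <- alph$canonical
  A <- length(res)
  m <- as.matrix(subaln)
  nres_row <- rowSums(m != "-")
  if (any(nres_row == 0L)) {
    stop(sprintf("row %s of the subalignment has no residues",
                 sQuote(names(subaln$rows)[nres_row == 0L][1])))
  }
  nongap_frac <- colMeans(m != "-")
  match_cols <- which(nongap_frac >= 0.5)
  k <- length(match_cols)
  if (k == 0L) stop("no column reaches the 0.5 match-column threshold")

  # background from the whole subalignment (canonical residues only)
  all_res <- m[m %in% res]
  bg_counts <- table(factor(all_res, levels = res))
  bg <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + pseudocount * A)
  names(bg) <- res

  # match emissions
  log_match <- matrix(0, k, A, dimnames = list(NULL, res))
  for (jj in seq_len(k)) {
    col <- m[, match_cols[jj]]
    cnt <- table(factor(col[col %in% res], levels = res))
    log_match[jj, ] <- log((as.numeric(cnt) + pseudocount) /
                             (sum(cnt) + pseudocount * A))
  }
  log_ins <- log(bg)

  # transition counts from observed state paths; rows j+1 = from column j,
  # columns = (to next-M / End, to I_j, to next-D)
  cM <- matrix(0, k + 1, 3)
  cI <- matrix(0, k + 1, 3)
  cD <- matrix(0, k + 1, 3)
  is_match <- logical(ncol(m))
  is_match[match_cols] <- TRUE
  for (r in seq_len(nrow(m))) {
    type <- "M"; j <- 0L   # Begin
    for (c in seq_len(ncol(m))) {
      resident <- m[r, c] != "-"
      if (is_match[c]) {
        tgt <- if (resident) "M" else "D"
        ti <- match(tgt, c("M", "I", "D"))
        if (type == "M") cM[j + 1, ti] <- cM[j + 1, ti] + 1
        else if (type == "I") cI[j + 1, ti] <- cI[j + 1, ti] + 1
        else cD[j + 1, ti] <- cD[j + 1, ti] + 1
        type <- tgt; j <- j + 1L
      } else if (resident) {
        if (type == "M") cM[j + 1, 2] <- cM[j + 1, 2] + 1
        else if (type == "I") cI[j + 1, 2] <- cI[j + 1, 2] + 1
        else cD[j + 1, 2] <- cD[j + 1, 2] + 1
        type <- "I"
      }
    }
    # exit to End (the to-M slot at column k)
    if (type == "M") cM[k + 1, 1] <- cM[k + 1, 1] + 1
    else if (type == "I") cI[k + 1, 1] <- cI[k + 1, 1] + 1
    else cD[k + 1, 1] <- cD[k + 1, 1] + 1
  }

  norm_row <- function(counts, j, prior) {
    # at column k only next-M (= End) and I are legal targets
    n_tgt <- if (j == k) 2L else 3L
    a <- prior[seq_len(n_tgt)] / sum(prior[seq_len(n_tgt)])
    mass <- pseudocount * 3
    p <- (counts[seq_len(n_tgt)] + mass * a) /
      (sum(counts[seq_len(n_tgt)]) + mass)
    out <- rep(-Inf, 3)
    out[seq_len(n_tgt)] <- log(p)
    out
  }
  tM <- tI <- tD <- matrix(-Inf, k + 1, 3)
  for (j in 0:k) {
    tM[j + 1, ] <- norm_row(cM[j + 1, ], j, TRANS_PRIOR$M)
    tI[j + 1, ] <- norm_row(cI[j + 1, ], j, TRANS_PRIOR$I)
    tD[j + 1, ] <- norm_row(cD[j + 1, ], j, TRANS_PRIOR$D)
  }
  # D_0 does not exist; make its row impossible so no path can use it
  tD[1, ] <- -Inf

  structure(
    list(k = k, match_cols = match_cols, ncols = ncol(m),
         alphabet = alph$name, residues = res,
         log_match = log_match, log_ins = log_ins,
         tM = tM, tI = tI, tD = tD,
         log_bg = log(bg), pseudocount = pseudocount),
    class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match states over %d alignment columns (%s)\n",
              x$k, x$ncols, x$alphabet))
  invisible(x)
}

## Per-position emission matrices for a query; ambiguity codes emit with
## probability 1 under model and null alike (scoring-neutral).
query_emissions <- function(hmm, residues) {
  idx <- match(residues, hmm$residues)   # NA = ambiguity
  L <- length(residues)
  EM <- matrix(0, hmm$k, L)
  known <- which(!is.na(idx))
  if (length(known) > 0) {
    EM[, known] <- hmm$log_match[, idx[known], drop = FALSE]
  }
  ei_col <- numeric(L)
  ei_col[known] <- hmm$log_ins[idx[known]]
  EI <- matrix(rep(ei_col, each = hmm$k + 1), hmm$k + 1, L)
  null_log <- sum(hmm$log_bg[idx[known]])
  list(EM = EM, EI = EI, null_log = null_log)
}

prep_query <- function(hmm, q) {
  if (length(q) != 1L || !is.character(q)) {
    stop("query must be a single character string")
  }
  residues <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  if (length(residues) == 0L) stop("query sequence is empty")
  alph <- resolve_alphabet(hmm$alphabet)
  bad <- setdiff(unique(residues), c(alph$canonical, alph$ambiguity))
  if (length(bad) > 0L) {
    stop(sprintf("query contains non-%s character(s) %s",
                 alph$name, paste(sQuote(bad), collapse = ", ")))
  }
  residues
}

#' Forward bit-score of a query under a profile HMM
#'
#' Computes `log2( P(q | hmm) / P(q | null) )` where the numerator sums the
#' probability of all glocal state paths (forward algorithm, log space) and
#' the null model emits each residue at its background frequency. Returns
#' `-Inf` when no state path can emit the query.
#'
#' @param hmm A [build_profile] model.
#' @param q Query sequence (single character string, no gaps).
#' @return Bit-score (numeric scalar, possibly `-Inf`).
#' @export
forward_bitscore <- function(hmm, q) {
  stopifnot(inherits(hmm, "profile_hmm"))
  residues <- prep_query(hmm, q)
  e <- query_emissions(hmm, residues)
  logp <- .phmm_forward(e$EM, e$EI, hmm$tM, hmm$tI, hmm$tD)
  (logp - e$null_log) / log(2)
}

#' Viterbi alignment of a query to a profile HMM
#'
#' Returns the maximum-probability glocal state path as a
#' `query_alignment_trace`: one row per query residue stating whether it was
#' emitted by a match state (and which) or by an insert state (and which
#' match state precedes it), plus a deletion flag per match state.
#'
#' @inheritParams forward_bitscore
#' @return A list of class `query_alignment_trace` with elements `steps`
#'   (data.frame: `pos`, `type`, `mstate`), `deleted` (logical of length
#'   `k`) and `log2p` (the path score in bits against the null model).
#' @export
viterbi_align <- function(hmm, q) {
  stopifnot(inherits(hmm, "profile_hmm"))
  residues <- prep_query(hmm, q)
  e <- query_emissions(hmm, residues)
  v <- .phmm_viterbi(e$EM, e$EI, hmm$tM, hmm$tI, hmm$tD)
  if (!is.finite(v$logp) || nrow(v$path) == 0L) {
    stop("no valid state path for this query; was it assigned to the wrong model?")
  }
  path <- v$path
  emit <- path[, 1] != 3L
  steps <- data.frame(
    pos = cumsum(emit)[emit],
    type = c("match", "insert")[path[emit, 1]],
    mstate = path[emit, 2])
  deleted <- logical(hmm$k)
  deleted[path[path[, 1] == 3L, 2]] <- TRUE
  structure(list(steps = steps, deleted = deleted,
                 log2p = (v$logp - e$null_log) / log(2)),
            class = "query_alignment_trace")
}
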