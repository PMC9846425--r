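#' Enumerate the residue homology pairs of an alignment
#'
#' For every column and every unordered pair of rows that both hold
#' residues in that column, emits one homology pair identified by the two
#' (sequence id, residue index) coordinates. Residue indices count non-gap
#' characters from the start of each sequence, so pairs are comparable
#' between different alignments of the same sequences. Cells flagged in
#' the insertion mask (lowercase convention) are unaligned by definition
#' and contribute no pairs.
#'
#' @param aln An [msa].
#' @return Character vector of pair keys (`"idA\\u001friA\\u001fidB\\u001friB"`,
#'   rows ordered by id), one per homology pair.
#' @export
homology_pairs <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- as.matrix(aln)
  ids <- rownames(m)
  occ <- m != "-"
  ri <- t(apply(occ, 1L, cumsum))          # residue index at each column
  usable <- occ
  if (!is.null(aln$mask)) usable <- usable & !aln$mask
  out <- character(0)
  for (cc in seq_len(ncol(m))) {
    rows <- which(usable[, cc])
    if (length(rows) < 2L) next
    pr <- utils::combn(rows, 2L)
    # canonical pair order: lexicographically by id, so keys are
    # comparable between alignments with different row orders
    swap <- ids[pr[1, ]] > ids[pr[2, ]]
    pr[, swap] <- pr[2:1, swap]
    keys <- paste(ids[pr[1, ]], ri[cbind(pr[1, ], cc)],
                  ids[pr[2, ]], ri[cbind(pr[2, ], cc)], sep = "\x1f")
    out <- c(out, keys)
  }
  out
}

#' Sum-of-pairs alignment error (SPFN / SPFP)
#'
#' Compares an estimated alignment to a reference: SPFN is the fraction of
#' the reference's homology pairs missing from the estimate (false
#' negatives), SPFP the fraction of the estimate's pairs absent from the
#' reference (false positives). The comparison is restricted to the
#' reference's sequence ids; insertion-masked cells never contribute pairs.
#' Degenerate inputs with zero pairs report an error rate of 0 and set the
#' `degenerate` flag (with a warning).
#'
#' @param est Estimated [msa]; its row ids must include all of `ref`'s.
#' @param ref Reference [msa].
#' @return An object of class `error_report`: `spfn`, `spfp`,
#'   `n_ref_pairs`, `n_est_pairs`, `n_shared_pairs`, `degenerate`.
#' @export
spfn_spfp <- function(est, ref) {
  stopifnot(inherits(est, "msa"), inherits(ref, "msa"))
  ids <- msa_ids(ref)
  missing <- setdiff(ids, msa_ids(est))
  if (length(missing) > 0) {
    stop(sprintf("estimated alignment lacks sequence %s", sQuote(missing[1])))
  }
  est <- induced_subalignment(est, ids)
  ue <- ungap(est)[ids]; ur <- ungap(ref)[ids]
  if (!identical(unname(ue), unname(ur))) {
    bad <- ids[which(unname(ue) != unname(ur))[1]]
    stop(sprintf("sequence %s differs between estimated and reference alignments",
                 sQuote(bad)))
  }
  rp <- homology_pairs(ref)
  ep <- homology_pairs(est)
  shared <- sum(ep %in% rp)
  degenerate <- length(rp) == 0L || length(ep) == 0L
  if (degenerate) {
    warning("alignment with zero homology pairs; reporting 0 error")
  }
  spfn <- if (length(rp) == 0L) 0 else (length(rp) - shared) / length(rp)
  spfp <- if (length(ep) == 0L) 0 else (length(ep) - shared) / length(ep)
  structure(list(spfn = spfn, spfp = spfp,
                 n_ref_pairs = length(rp), n_est_pairs = length(ep),
                 n_shared_pairs = shared, degenerate = degenerate),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("SPFN = %.4f  SPFP = %.4f  (ref pairs %d, est pairs %d, shared %d)\n",
              x$spfn, x$spfp, x$n_ref_pairs, x$n_est_pairs, x$n_shared_pairs))
  invisible(x)
}

#' Summary statistics of an alignment
#'
#' Reports the statistics used to characterize benchmark datasets: number
#' of sequences, mean ungapped length, gap fraction of alignment cells,
#' and average / maximum pairwise p-distance (normalized Hamming distance
#' over co-occupied sites). Exact over all pairs up to 2000 rows; above
#' that a seeded random subsample of 2e6 pairs is used.
#'
#' @param aln An [msa] with at least 2 rows.
#' @param seed Seed for the pair subsample of very large alignments.
#' @return A list of class `dataset_stats`.
#' @export
dataset_stats <- function(aln, seed = 1L) {
  stopifnot(inherits(aln, "msa"), nrow(aln) >= 2)
  m <- as.matrix(aln)
  n <- nrow(m)
  lens <- rowSums(m != "-")
  gap_fraction <- mean(m == "-")
  pdist_pair <- function(i, j) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    nb <- sum(both)
    if (nb == 0L) return(NA_real_)
    sum(m[i, both] != m[j, both]) / nb
  }
  if (n <= 2000) {
    pairs <- utils::combn(n, 2L)
  } else {
    set.seed(seed)
    npair <- 2e6
    pairs <- rbind(sample.int(n, npair, replace = TRUE),
                   sample.int(n, npair, replace = TRUE))
    pairs <- pairs[, pairs[1, ] != pairs[2, ], drop = FALSE]
  }
  pd <- vapply(seq_len(ncol(pairs)),
               function(s) pdist_pair(pairs[1, s], pairs[2, s]), 0.0)
  if (anyNA(pd)) {
    warning(sprintf("%d pair(s) share no co-occupied site; skipped",
                    sum(is.na(pd))))
    pd <- pd[!is.na(pd)]
  }
  structure(list(n_sequences = n, mean_length = mean(lens),
                 gap_fraction = gap_fraction,
                 avg_p_distance = mean(pd), max_p_distance = max(pd)),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(paste0("%d sequences; mean length %.1f; gap fraction %.3f; ",
                     "p-distance avg %.3f max %.3f\n"),
              x$n_sequences, x$mean_length, x$gap_fraction,
              x$avg_p_distance, x$max_p_distance))
  invisible(x)
}
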