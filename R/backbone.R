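#' Backbone selection configuration
#'
#' Stage 1 selects the sequences deemed full-length ("backbone"); everything
#' else becomes a query to be inserted later. Two strategies are provided:
#'
#' * `median_window`: eligible sequences lie within `window` (default 25%)
#'   of the median sequence length; up to `target_size` are kept (uniform
#'   random downsample when more are eligible).
#' * `sliding_window`: scans candidate lengths `L` and picks the `L*`
#'   maximizing the number of sequences within `window * L` of `L`; the
#'   backbone is every sequence of length at least `(1 - window) * L*`
#'   (again downsampled to `target_size`). Designed for datasets with
#'   severe length heterogeneity, where the median may fall between length
#'   classes.
#'
#' @param target_size Maximum backbone size. `NULL` (default) resolves to
#'   1000, or to 10000 for large inputs (at least 25000 sequences).
#' @param window Length window as a fraction (default 0.25).
#' @param strategy `"median_window"` or `"sliding_window"`.
#' @param method Backbone alignment method: `"internal"` for the built-in
#'   progressive aligner or `"cmd:<template>"` to shell out (the template
#'   receives `{input}` and `{output}` placeholders).
#' @param tree_method Backbone tree method: `"internal"` (neighbor joining
#'   on p-distances) or `"cmd:<template>"`.
#' @param seed Optional RNG seed for the downsampling step.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(target_size = NULL, window = 0.25,
                            strategy = c("median_window", "sliding_window"),
                            method = "internal", tree_method = "internal",
                            seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(target_size)) stopifnot(target_size >= 2)
  stopifnot(window > 0, window < 1)
  structure(list(target_size = target_size, window = window,
                 strategy = strategy, method = method,
                 tree_method = tree_method, seed = seed),
            class = "backbone_config")
}

resolve_target_size <- function(cfg, n) {
  if (!is.null(cfg$target_size)) return(cfg$target_size)
  if (n >= 25000) 10000 else 1000
}

finish_selection <- function(seqs, eligible_ids, target) {
  if (length(eligible_ids) > target) {
    eligible_ids <- sort(sample(eligible_ids, target))
    # keep input order
    eligible_ids <- names(seqs)[names(seqs) %in% eligible_ids]
  }
  list(backbone = eligible_ids,
       queries = setdiff(names(seqs), eligible_ids))
}

#' Select backbone sequences around the median length
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param cfg A [backbone_config].
#' @return List with character vectors `backbone` and `queries`
#'   (a partition of `names(seqs)`).
#' @export
select_backbone_median_window <- function(seqs, cfg = backbone_config()) {
  stopifnot(length(seqs) >= 2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lens <- nchar(seqs)
  m <- stats::median(lens)
  lo <- (1 - cfg$window) * m
  hi <- (1 + cfg$window) * m
  eligible <- names(seqs)[lens >= lo & lens <= hi]
  if (length(eligible) == 0L) {
    stop("no sequence lies within the median length window; ",
         "use the sliding_window strategy for length-heterogeneous data")
  }
  finish_selection(seqs, eligible, resolve_target_size(cfg, length(seqs)))
}

#' Select backbone sequences with the sliding-window rule
#'
#' Candidate window centers are the distinct observed lengths; ties in the
#' maximizing count are broken toward the larger `L` (preferring
#' full-length sequences).
#'
#' @inheritParams select_backbone_median_window
#' @return List with character vectors `backbone` and `queries`.
#' @export
select_backbone_sliding_window <- function(seqs, cfg = backbone_config()) {
  stopifnot(length(seqs) >= 2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lens <- nchar(seqs)
  cand <- sort(unique(lens), decreasing = TRUE)  # ties -> larger L wins
  counts <- vapply(cand, function(L) sum(abs(lens - L) <= cfg$window * L), 0L)
  L_star <- cand[which.max(counts)]
  eligible <- names(seqs)[lens >= (1 - cfg$window) * L_star]
  finish_selection(seqs, eligible, resolve_target_size(cfg, length(seqs)))
}

select_backbone <- function(seqs, cfg) {
  switch(cfg$strategy,
         median_window = select_backbone_median_window(seqs, cfg),
         sliding_window = select_backbone_sliding_window(seqs, cfg))
}

## ---- internal progressive aligner -------------------------------------

kmer_counts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(table(substr(s, 1, n)))
  kmers <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  table(kmers)
}

kmer_distance_matrix <- function(seqs, k) {
  n <- length(seqs)
  tabs <- lapply(seqs, kmer_counts, k = k)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- tabs[[i]]; tj <- tabs[[j]]
      common <- intersect(names(ti), names(tj))
      shared <- sum(pmin(ti[common], tj[common]))
      denom <- max(1, min(sum(ti), sum(tj)))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

score_matrix_for <- function(alphabet) {
  alph <- resolve_alphabet(alphabet)
  res <- alph$canonical
  if (alph$name == "protein") {
    S <- get_blosum62()[res, res]
    list(S = S, gap_open = -11, gap_ext = -1)
  } else {
    S <- matrix(-1, length(res), length(res), dimnames = list(res, res))
    diag(S) <- 1
    list(S = S, gap_open = -3, gap_ext = -1)
  }
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

profile_freqs <- function(mat, res) {
  # A x L residue frequencies, normalized by row count (gap mass implicit)
  A <- length(res)
  out <- matrix(0, A, ncol(mat))
  for (a in seq_len(A)) out[a, ] <- colSums(mat == res[a])
  out / nrow(mat)
}

merge_alignments_nw <- function(m1, m2, sc, res) {
  ops <- .nw_profile(profile_freqs(m1, res), profile_freqs(m2, res),
                     sc$S, sc$gap_open, sc$gap_ext)
  n1 <- nrow(m1); n2 <- nrow(m2)
  out <- matrix("-", n1 + n2, length(ops))
  i <- 0L; j <- 0L
  for (s in seq_along(ops)) {
    op <- ops[s]
    if (op != 3L) { i <- i + 1L; out[seq_len(n1), s] <- m1[, i] }
    if (op != 2L) { j <- j + 1L; out[n1 + seq_len(n2), s] <- m2[, j] }
  }
  rownames(out) <- c(rownames(m1), rownames(m2))
  out
}

#' Align backbone sequences
#'
#' `method = "internal"` runs the built-in progressive aligner: a UPGMA
#' guide tree on k-mer distances, then profile-profile Needleman-Wunsch
#' merges with affine gap costs (+1/-1 with gap open -3 / extend -1 for
#' nucleotides; BLOSUM62 with -11/-1 for proteins). A `"cmd:<template>"`
#' method shells out to an external aligner (e.g. MAGUS, PASTA, MAFFT) and
#' parses its aligned-FASTA output.
#'
#' @param seqs Named character vector of at least two ungapped sequences.
#' @param method `"internal"` or `"cmd:<template>"`.
#' @param alphabet Alphabet name or `NULL` to guess.
#' @return An [msa] whose rows ungap exactly to `seqs`, in input order.
#' @export
align_backbone <- function(seqs, method = "internal", alphabet = NULL) {
  stopifnot(length(seqs) >= 2)
  if (is.null(alphabet)) alphabet <- guess_alphabet(seqs)
  if (startsWith(method, "cmd:")) {
    out <- run_external(sub("^cmd:", "", method), seqs)
    aln <- msa(out, alphabet = alphabet)
    check_backbone_alignment(aln, seqs)
    return(aln)
  }
  if (!identical(method, "internal")) {
    stop(sprintf("unknown alignment method %s", sQuote(method)))
  }
  alph <- resolve_alphabet(alphabet)
  res <- alph$canonical
  sc <- score_matrix_for(alphabet)
  kk <- if (alph$name == "protein") 2L else 4L
  d <- stats::as.dist(kmer_distance_matrix(seqs, kk))
  mats <- lapply(seqs, function(s) {
    matrix(strsplit(toupper(s), "")[[1]], nrow = 1)
  })
  names(mats) <- names(seqs)
  for (i in seq_along(mats)) rownames(mats[[i]]) <- names(seqs)[i]
  if (length(seqs) == 2L) {
    merged <- merge_alignments_nw(mats[[1]], mats[[2]], sc, res)
  } else {
    hc <- stats::hclust(d, method = "average")
    clusters <- mats
    node_aln <- vector("list", nrow(hc$merge))
    for (s in seq_len(nrow(hc$merge))) {
      pick <- function(x) if (x < 0) clusters[[-x]] else node_aln[[x]]
      node_aln[[s]] <- merge_alignments_nw(pick(hc$merge[s, 1]),
                                           pick(hc$merge[s, 2]), sc, res)
    }
    merged <- node_aln[[nrow(hc$merge)]]
  }
  merged <- merged[names(seqs), , drop = FALSE]
  keep <- colSums(merged != "-") > 0L
  merged <- merged[, keep, drop = FALSE]
  rows <- apply(merged, 1L, paste, collapse = "")
  names(rows) <- names(seqs)
  aln <- msa(rows, alphabet = alph$name)
  check_backbone_alignment(aln, seqs)
  aln
}

check_backbone_alignment <- function(aln, seqs) {
  u <- ungap(aln)[names(seqs)]
  if (!identical(unname(u), unname(toupper(seqs)))) {
    bad <- names(seqs)[which(unname(u) != unname(toupper(seqs)))[1]]
    stop(sprintf("aligned sequence %s does not ungap to its input", sQuote(bad)))
  }
  invisible(TRUE)
}

## ---- tree estimation ---------------------------------------------------

#' Pairwise p-distance matrix of an alignment
#'
#' Normalized Hamming distance over sites where both rows hold residues.
#'
#' @param aln An [msa].
#' @param on_empty Value for pairs with no co-occupied site (default `NA`).
#' @return Symmetric numeric matrix.
#' @export
p_distance_matrix <- function(aln, on_empty = NA_real_) {
  m <- as.matrix(aln)
  n <- nrow(m)
  occ <- m != "-"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      both <- occ[i, ] & occ[j, ]
      nb <- sum(both)
      d[i, j] <- d[j, i] <- if (nb == 0L) on_empty
        else sum(m[i, both] != m[j, both]) / nb
    }
  }
  d
}

#' Estimate a backbone tree
#'
#' `method = "internal"` runs neighbor joining ([ape::nj]) on the pairwise
#' p-distance matrix of the alignment; `"cmd:<template>"` shells out (e.g.
#' to FastTree) and parses the newick output. Negative branch lengths from
#' NJ are clamped to zero.
#'
#' @param aln An [msa] with at least three rows.
#' @param method `"internal"` or `"cmd:<template>"`.
#' @return An unrooted [ape::phylo] whose tip labels equal `msa_ids(aln)`.
#' @export
estimate_tree <- function(aln, method = "internal") {
  stopifnot(inherits(aln, "msa"))
  if (nrow(aln) < 3L) stop("tree estimation needs at least 3 sequences")
  if (startsWith(method, "cmd:")) {
    tr <- run_external(sub("^cmd:", "", method), aln, parse = "newick")
  } else if (identical(method, "internal")) {
    d <- p_distance_matrix(aln, on_empty = 1)
    tr <- ape::nj(stats::as.dist(d))
    tr$edge.length[tr$edge.length < 0] <- 0
  } else {
    stop(sprintf("unknown tree method %s", sQuote(method)))
  }
  if (!setequal(tr$tip.label, msa_ids(aln))) {
    stop("tree leaf set does not match the alignment ids")
  }
  tr
}

## Run an external command template with {input}/{output} placeholders.
## `x` is written as FASTA; output parsed as aligned FASTA or newick.
run_external <- function(template, x, parse = c("fasta", "newick")) {
  parse <- match.arg(parse)
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = if (parse == "fasta") ".fasta" else ".nwk")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(x, fin)
  cmd <- gsub("{input}", fin, gsub("{output}", fout, template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE)
  if (status != 0L) {
    stop(sprintf("external command failed with exit status %d: %s",
                 status, cmd))
  }
  if (!file.exists(fout) || file.size(fout) == 0L) {
    stop(sprintf("external command produced no output: %s", cmd))
  }
  if (parse == "newick") {
    tr <- tryCatch(ape::read.tree(fout),
                   error = function(e) stop(sprintf(
                     "could not parse newick output of %s: %s",
                     cmd, conditionMessage(e))))
    return(tr)
  }
  set <- tryCatch(Biostrings::readBStringSet(fout),
                  error = function(e) stop(sprintf(
                    "could not parse FASTA output of %s: %s",
                    cmd, conditionMessage(e))))
  raw <- as.character(set)
  names(raw) <- sub("\\s.*$", "", names(raw))
  raw
}
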