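#' Configuration for the sequence simulator
#'
#' The simulator evolves a root sequence down a phylogeny under a
#' Jukes-Cantor-style uniform substitution process with geometric-length
#' indels, keeping exact column bookkeeping so the *true* alignment is known.
#' It emulates the structure of simulated MSA benchmarks (many taxa, indel
#' heterogeneity, known reference homologies); it makes no attempt to model
#' realistic substitution matrices or site rate variation.
#'
#' Rates are per site per unit branch length; a branch of length `t` applies
#' a substitution probability `1 - exp(-sub_rate * t)` at each site and an
#' expected `indel_rate * t` indel events per site.
#'
#' @param n_taxa Number of leaf sequences (default 1000, the scale of the
#'   simulated benchmark collections this emulates).
#' @param root_length Length of the root sequence (default 1000).
#' @param sub_rate Substitution rate per site per unit branch length.
#' @param indel_rate Indel event rate per site per unit branch length.
#' @param indel_mean Mean indel tract length (geometric distribution).
#' @param tree Tree shape: `"random"` (Yule-like via [ape::rtree]),
#'   `"balanced"`, or an [ape::phylo] object supplied by the caller.
#' @param tree_height Total root-to-tip height the tree is rescaled to.
#' @param alphabet Residue alphabet (default `"dna"`).
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 1000, root_length = 1000,
                       sub_rate = 0.2, indel_rate = 0.01, indel_mean = 2,
                       tree = "random", tree_height = 1,
                       alphabet = "dna", seed = NULL) {
  stopifnot(n_taxa >= 2, root_length >= 1,
            sub_rate >= 0, indel_rate >= 0, indel_mean >= 1,
            tree_height > 0)
  structure(list(n_taxa = n_taxa, root_length = root_length,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, tree = tree,
                 tree_height = tree_height, alphabet = alphabet,
                 seed = seed),
            class = "sim_config")
}

sim_tree <- function(cfg) {
  tr <- cfg$tree
  if (inherits(tr, "phylo")) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (identical(tr, "balanced")) {
    k <- ceiling(log2(cfg$n_taxa))
    tr <- ape::stree(2^k, type = "balanced")
    tr <- ape::keep.tip(tr, tr$tip.label[seq_len(cfg$n_taxa)])
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    tr <- ape::rtree(cfg$n_taxa)
  }
  # rescale to the requested height
  depths <- ape::node.depth.edgelength(tr)
  h <- max(depths[seq_len(ape::Ntip(tr))])
  if (h > 0) tr$edge.length <- tr$edge.length * cfg$tree_height / h
  tr$tip.label <- sprintf("t%03d", seq_len(ape::Ntip(tr)))
  tr
}

#' Simulate a multiple sequence alignment with a known truth
#'
#' Evolves a random root sequence down a tree with substitutions and indels.
#' Insertions open fresh columns in the bookkept master alignment (gaps are
#' back-filled into every other lineage), so ungapping any row of the true
#' alignment reproduces that taxon's sequence exactly.
#'
#' @param cfg A [sim_config].
#' @return A list with elements `alignment` (the true [msa]), `sequences`
#'   (named character vector of ungapped leaf sequences) and `tree`
#'   (the [ape::phylo] used).
#' @export
simulate_msa <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  alph <- resolve_alphabet(cfg$alphabet)
  res <- alph$canonical
  tr <- sim_tree(cfg)
  tr <- ape::reorder.phylo(tr, "cladewise")
  ntip <- ape::Ntip(tr)
  root <- ntip + 1L

  # rows for every node visited so far, as character vectors over the
  # current master columns; insertions splice gap columns into all of them
  store <- new.env(parent = emptyenv())
  store$rows <- list()
  store$ncol <- cfg$root_length

  splice <- function(at, width, new_residues, into) {
    # insert `width` columns after master column `at` (0 = before first);
    # `into` receives new_residues, everyone else gets gaps
    for (nm in names(store$rows)) {
      r <- store$rows[[nm]]
      fill <- if (identical(nm, into)) new_residues else rep("-", width)
      store$rows[[nm]] <- append(r, fill, after = at)
    }
    store$ncol <- store$ncol + width
  }

  evolve_branch <- function(row, len, node_name) {
    store$rows[[node_name]] <- row
    occupied <- which(store$rows[[node_name]] != "-")
    nres <- length(occupied)
    if (nres == 0L) return(invisible(NULL))
    # substitutions
    p_sub <- 1 - exp(-cfg$sub_rate * len)
    if (p_sub > 0 && nres > 0) {
      hit <- occupied[stats::runif(nres) < p_sub]
      if (length(hit) > 0) {
        cur <- store$rows[[node_name]][hit]
        repl <- vapply(cur, function(b) sample(setdiff(res, b), 1L), "")
        store$rows[[node_name]][hit] <- repl
      }
    }
    # indels: Poisson number of events, geometric tract lengths
    n_events <- stats::rpois(1L, cfg$indel_rate * len * nres)
    for (ev in seq_len(n_events)) {
      occupied <- which(store$rows[[node_name]] != "-")
      nres <- length(occupied)
      if (nres <= 1L) break  # refuse to delete a lineage to nothing
      w <- stats::rgeom(1L, 1 / cfg$indel_mean) + 1L
      if (stats::runif(1) < 0.5) {
        # deletion of w residues starting at a uniform residue position
        w <- min(w, nres - 1L)
        start <- sample.int(nres - w + 1L, 1L)
        store$rows[[node_name]][occupied[start:(start + w - 1L)]] <- "-"
      } else {
        # insertion after a uniform residue boundary (0 .. nres)
        b <- sample.int(nres + 1L, 1L) - 1L
        at <- if (b == 0L) 0L else occupied[b]
        splice(at, w, sample(res, w, replace = TRUE), node_name)
      }
    }
    invisible(NULL)
  }

  node_name <- function(v) {
    if (v <= ntip) tr$tip.label[v] else sprintf(".node%d", v)
  }

  store$rows[[node_name(root)]] <- sample(res, cfg$root_length, replace = TRUE)
  # cladewise edge order visits parents before children
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
    evolve_branch(store$rows[[node_name(par)]], tr$edge.length[e],
                  node_name(chl))
  }

  leaf_rows <- store$rows[tr$tip.label]
  mat <- do.call(rbind, leaf_rows)
  keep <- colSums(mat != "-") > 0L
  mat <- mat[, keep, drop = FALSE]
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- tr$tip.label
  aln <- msa(rows, alphabet = alph$name)
  seqs <- ungap(aln)
  if (any(nchar(seqs) == 0L)) {
    warning("a lineage lost all residues; rerun with a different seed")
  }
  list(alignment = aln, sequences = seqs, tree = tr)
}

#' Configuration for the fragmentation procedure
#'
#' Builds "high-fragmentary" (HF) variants of a dataset: a random half of
#' the sequences (by default) are cut down to contiguous substrings of about
#' a quarter of the original median sequence length, emulating the standard
#' HF benchmark construction.
#'
#' @param fraction Share of sequences to fragment (default 0.5).
#' @param mean_ratio Target mean fragment length as a fraction of the
#'   original median sequence length (default 0.25).
#' @param length_sd Standard deviation of the fragment length draw
#'   (default 0: every fragment has exactly the target length).
#' @param seed Optional RNG seed.
#' @return A `frag_config` list.
#' @export
frag_config <- function(fraction = 0.5, mean_ratio = 0.25,
                        length_sd = 0, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1,
            mean_ratio > 0, mean_ratio < 1, length_sd >= 0)
  structure(list(fraction = fraction, mean_ratio = mean_ratio,
                 length_sd = length_sd, seed = seed),
            class = "frag_config")
}

#' Fragment a sequence dataset
#'
#' Replaces a seeded random subset of `floor(fraction * n)` sequences with
#' contiguous substrings. Fragment lengths are drawn from
#' `Normal(mean_ratio * median_length, length_sd)`, rounded and clipped to
#' `[1, nchar(seq)]`; start positions are uniform over valid offsets. Ids
#' are preserved.
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param cfg A [frag_config].
#' @return Named character vector with the same names and order as `seqs`.
#' @export
fragmentize <- function(seqs, cfg = frag_config()) {
  stopifnot(inherits(cfg, "frag_config"), length(seqs) >= 2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(seqs)
  n_frag <- floor(cfg$fraction * n)
  if (n_frag == 0L) return(seqs)
  med <- stats::median(nchar(seqs))
  target <- cfg$mean_ratio * med
  pick <- sample.int(n, n_frag)
  out <- seqs
  starts <- ends <- integer(n)
  for (i in pick) {
    len_i <- nchar(seqs[[i]])
    want <- if (cfg$length_sd > 0) {
      round(stats::rnorm(1L, target, cfg$length_sd))
    } else round(target)
    want <- max(1L, want)
    if (want > len_i) {
      warning(sprintf(
        "fragment target %d exceeds sequence %s length %d; clipping",
        want, sQuote(names(seqs)[i]), len_i))
      want <- len_i
    }
    start <- sample.int(len_i - want + 1L, 1L)
    out[[i]] <- substr(seqs[[i]], start, start + want - 1L)
    starts[i] <- start
    ends[i] <- start + want - 1L
  }
  attr(out, "fragments") <- data.frame(
    id = names(seqs)[pick],
    start = starts[pick], end = ends[pick])
  out
}

#' Restrict a reference alignment to fragmented sequences
#'
#' Given the true (or reference) alignment of the original full-length
#' sequences and the output of [fragmentize], blanks every residue that
#' was trimmed away, yielding the reference alignment of the fragmented
#' dataset (the alignment a perfect method would reproduce).
#'
#' @param aln Reference [msa] of the full-length sequences.
#' @param frags Output of [fragmentize] (carries the `fragments`
#'   attribute).
#' @return An [msa] whose rows ungap to the fragmented sequences.
#' @export
fragment_reference <- function(aln, frags) {
  stopifnot(inherits(aln, "msa"))
  fr <- attr(frags, "fragments")
  if (is.null(fr)) stop("frags does not carry fragmentation coordinates")
  m <- as.matrix(aln)
  for (r in seq_len(nrow(fr))) {
    id <- fr$id[r]
    row <- m[id, ]
    ri <- cumsum(row != "-")
    drop <- row != "-" & (ri < fr$start[r] | ri > fr$end[r])
    row[drop] <- "-"
    m[id, ] <- row
  }
  keep <- colSums(m != "-") > 0L
  m <- m[, keep, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- rownames(m)
  msa(rows, col_labels = aln$col_labels[keep], alphabet = aln$alphabet)
}
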