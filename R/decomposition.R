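#' Find a centroid edge of a tree
#'
#' A centroid edge splits the leaf set into two sides as equal as possible:
#' the returned edge minimizes `max(|A|, |B|)` over the bipartition it
#' induces. Among minimizers the first edge encountered in a deterministic
#' pre-order traversal (rooted at the first leaf) is chosen, so repeated
#' calls are reproducible.
#'
#' @param tree An [ape::phylo] with at least two leaves.
#' @return List with character vectors `A` and `B`, the two leaf sides
#'   (`A` contains the tree's first tip).
#' @export
find_centroid_edge <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 2L) stop("cannot split a single-leaf tree")
  if (n == 2L) {
    return(list(A = tree$tip.label[1], B = tree$tip.label[2]))
  }
  first <- tree$tip.label[1]
  rooted <- tryCatch(
    ape::root(ape::unroot(tree), outgroup = first, resolve.root = TRUE),
    error = function(e) tree)
  rooted <- ape::reorder.phylo(rooted, "cladewise")
  edge <- rooted$edge
  # tip sets below each node (postorder accumulation)
  po <- ape::reorder.phylo(rooted, "postorder")$edge
  tips_below <- vector("list", max(edge))
  for (t in seq_len(n)) tips_below[[t]] <- rooted$tip.label[t]
  for (e in seq_len(nrow(po))) {
    tips_below[[po[e, 1]]] <- c(tips_below[[po[e, 1]]], tips_below[[po[e, 2]]])
  }
  sizes <- lengths(tips_below)[edge[, 2]]
  maxside <- pmax(sizes, n - sizes)
  valid <- sizes > 0L & sizes < n
  best <- which(valid & maxside == min(maxside[valid]))[1]
  below <- tips_below[[edge[best, 2]]]
  out <- list(A = setdiff(rooted$tip.label, below), B = below)
  if (!(first %in% out$A)) out <- list(A = out$B, B = out$A)
  out
}

#' Hierarchically decompose a backbone tree into an ensemble of subsets
#'
#' Splits the backbone tree at a centroid edge, recursing on the induced
#' subtrees (degree-2 nodes suppressed) until every subset holds at most
#' `z` sequences. Every subset created along the way -- including the full
#' set at the root -- becomes a node carrying the subalignment induced by
#' the backbone alignment; [build_ehmm] then trains one profile HMM per
#' node. Nodes are numbered in pre-order.
#'
#' @param tree Backbone tree ([ape::phylo]); leaves must match the
#'   alignment ids.
#' @param backbone_aln Backbone [msa].
#' @param z Decomposition threshold (default 2; 10 reproduces the older,
#'   coarser decomposition).
#' @return An object of class `hmm_ensemble`: a flat pre-order list of
#'   nodes, each with `node_id`, `parent`, `children`, `depth`, `ids`,
#'   `size` and `subaln` (and `hmm` after [build_ehmm]).
#' @export
decompose <- function(tree, backbone_aln, z = 2) {
  stopifnot(inherits(tree, "phylo"), inherits(backbone_aln, "msa"))
  if (z < 1) stop("z must be at least 1")
  ids <- msa_ids(backbone_aln)
  if (!setequal(tree$tip.label, ids)) {
    stop("tree leaves and backbone alignment ids differ")
  }
  env <- new.env(parent = emptyenv())
  env$nodes <- list()

  recurse <- function(subtree, subset_ids, parent, depth) {
    node_id <- length(env$nodes) + 1L
    node <- list(node_id = node_id, parent = parent,
                 children = integer(0), depth = depth,
                 ids = subset_ids, size = length(subset_ids),
                 subaln = induced_subalignment(backbone_aln, subset_ids),
                 hmm = NULL)
    env$nodes[[node_id]] <- node
    if (length(subset_ids) > z) {
      halves <- find_centroid_edge(subtree)
      # child A first: the side holding the subset's first id
      kids <- integer(2)
      for (h in 1:2) {
        side <- if (h == 1) halves$A else halves$B
        side <- subset_ids[subset_ids %in% side]   # backbone order
        sub2 <- if (length(side) >= 2L) ape::keep.tip(subtree, side) else NULL
        kids[h] <- recurse(sub2, side, node_id, depth + 1L)
      }
      env$nodes[[node_id]]$children <- kids
    }
    node_id
  }
  recurse(tree, ids, NA_integer_, 0L)
  structure(list(nodes = env$nodes, z = z, root_id = 1L,
                 backbone_ids = ids),
            class = "hmm_ensemble")
}

#' Train the profile HMMs of an ensemble
#'
#' @param ens An `hmm_ensemble` from [decompose].
#' @param pseudocount Laplace pseudocount forwarded to [build_profile].
#' @return The ensemble with every node's `hmm` populated.
#' @export
build_ehmm <- function(ens, pseudocount = 1) {
  stopifnot(inherits(ens, "hmm_ensemble"))
  for (i in seq_along(ens$nodes)) {
    ens$nodes[[i]]$hmm <- tryCatch(
      build_profile(ens$nodes[[i]]$subaln, pseudocount = pseudocount),
      error = function(e) stop(sprintf(
        "HMM construction failed at ensemble node %d: %s",
        i, conditionMessage(e)), call. = FALSE))
  }
  ens
}

#' @export
print.hmm_ensemble <- function(x, ...) {
  sizes <- vapply(x$nodes, `[[`, 0L, "size")
  cat(sprintf(
    "hmm_ensemble: %d nodes over %d backbone sequences (z = %d)\n",
    length(x$nodes), length(x$backbone_ids), x$z))
  cat(sprintf("  leaf subsets: %d; max depth: %d; HMMs trained: %s\n",
              sum(vapply(x$nodes, function(n) length(n$children) == 0L, TRUE)),
              max(vapply(x$nodes, `[[`, 0L, "depth")),
              ifelse(is.null(x$nodes[[1]]$hmm), "no", "yes")))
  invisible(x)
}

#' Sizes and structure of an ensemble as a data.frame
#'
#' @param ens An `hmm_ensemble`.
#' @return data.frame with one row per node: `node_id`, `parent`, `depth`,
#'   `size`, `is_leaf`.
#' @export
ensemble_table <- function(ens) {
  stopifnot(inherits(ens, "hmm_ensemble"))
  data.frame(
    node_id = vapply(ens$nodes, `[[`, 0L, "node_id"),
    parent = vapply(ens$nodes, `[[`, 0L, "parent"),
    depth = vapply(ens$nodes, `[[`, 0L, "depth"),
    size = vapply(ens$nodes, `[[`, 0L, "size"),
    is_leaf = vapply(ens$nodes, function(n) length(n$children) == 0L, TRUE))
}
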