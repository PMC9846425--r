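#' Map a query's Viterbi trace onto backbone coordinates
#'
#' Turns the trace of a query against its selected node's HMM into an
#' *extended alignment*: every match-state residue maps through the node's
#' subalignment column map to a backbone column label, and every
#' insert-state residue becomes an insertion slot keyed by the backbone
#' column of the preceding match state (label 0 for insertions before the
#' first match state).
#'
#' @param q Query sequence (single character string).
#' @param node An `hmm_ensemble` node (with trained `hmm`).
#' @param trace A `query_alignment_trace` from [viterbi_align] of
#'   `node$hmm` on `q`.
#' @return An object of class `extended_alignment`: `id`, `residues`, and
#'   `placement`, a data.frame with one row per query residue (`pos`,
#'   `type`, `col` backbone label for matches, `anchor` + `offset` for
#'   insertions).
#' @export
extend_alignment <- function(q, node, trace) {
  stopifnot(inherits(trace, "query_alignment_trace"))
  hmm <- node$hmm
  if (is.null(hmm)) stop("ensemble node carries no trained HMM")
  residues <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  steps <- trace$steps
  if (nrow(steps) != length(residues)) {
    stop("trace does not cover the query: trace/HMM mismatch")
  }
  if (max(steps$mstate) > hmm$k) stop("trace references unknown match state")
  # match state j -> subalignment column -> backbone column label
  m2backbone <- node$subaln$col_labels[hmm$match_cols]
  col <- rep(NA_integer_, nrow(steps))
  anchor <- rep(NA_integer_, nrow(steps))
  is_match <- steps$type == "match"
  col[is_match] <- m2backbone[steps$mstate[is_match]]
  anchor[!is_match] <- ifelse(steps$mstate[!is_match] == 0L, 0L,
                              m2backbone[pmax(steps$mstate[!is_match], 1L)])
  offset <- integer(nrow(steps))
  if (any(!is_match)) {
    runs <- rle(paste0(steps$type, ":", ifelse(is_match, col, anchor)))
    offset <- sequence(runs$lengths) - 1L
    offset[is_match] <- 0L
  }
  placement <- data.frame(pos = steps$pos, type = steps$type,
                          col = col, anchor = anchor, offset = offset)
  if (is.unsorted(placement$col[is_match], strictly = TRUE)) {
    stop("match columns do not increase along the query: corrupt trace")
  }
  structure(list(id = NA_character_, residues = residues,
                 placement = placement),
            class = "extended_alignment")
}

#' Merge extended alignments into the final alignment by transitivity
#'
#' Output columns are the backbone columns in order, with one private
#' column spliced in per insertion residue, immediately after the backbone
#' column the insertion is anchored to (anchor 0 columns come first).
#' Insertions from different queries are never aligned to each other: each
#' insertion column holds exactly one residue, and all insertion cells are
#' flagged in the result's lowercase mask. Restricting the merged alignment
#' to the backbone rows and dropping all-gap columns reproduces the
#' backbone alignment exactly.
#'
#' @param backbone_aln Backbone [msa].
#' @param exts List of `extended_alignment` objects; `names(exts)` (or
#'   their `id` fields) give the query ids.
#' @return An [msa] over backbone then query rows, with `mask` marking
#'   insertion cells.
#' @export
merge_extended <- function(backbone_aln, exts) {
  stopifnot(inherits(backbone_aln, "msa"))
  labels <- backbone_aln$col_labels
  if (length(exts) > 0 && !is.null(names(exts))) {
    for (i in seq_along(exts)) {
      if (is.na(exts[[i]]$id)) exts[[i]]$id <- names(exts)[i]
    }
  }
  qids <- vapply(exts, `[[`, "", "id")
  if (anyNA(qids) || any(qids == "")) stop("every extended alignment needs an id")
  if (anyDuplicated(c(msa_ids(backbone_aln), qids))) {
    stop("duplicate sequence ids between backbone and queries")
  }

  # collect insertion slots: one output column per (query, anchor, offset)
  ins <- list()
  for (i in seq_along(exts)) {
    p <- exts[[i]]$placement
    bad <- setdiff(stats::na.omit(p$col), labels)
    if (length(bad) > 0) {
      stop(sprintf("extended alignment %s references unknown backbone column %d",
                   sQuote(qids[i]), bad[1]))
    }
    insp <- p[p$type == "insert", , drop = FALSE]
    if (nrow(insp) > 0) {
      ins[[length(ins) + 1L]] <- data.frame(
        ext = i, anchor = insp$anchor, pos = insp$pos)
    }
  }
  ins <- if (length(ins) > 0) do.call(rbind, ins) else
    data.frame(ext = integer(0), anchor = integer(0), pos = integer(0))
  # column layout: for each anchor (0, then each backbone label in order):
  # [backbone column if anchor > 0], then insertion columns in (query,
  # residue) order
  ins <- ins[order(match(ins$anchor, c(0L, labels)), ins$ext, ins$pos), ,
             drop = FALSE]
  n_ins <- nrow(ins)
  C <- length(labels)
  total <- C + n_ins

  # output index of each backbone column: i backbone columns up to and
  # including it, plus every insertion column anchored strictly before it
  # (anchor 0 and anchors at labels[1..i-1])
  ins_per_anchor <- table(factor(ins$anchor, levels = c(0L, labels)))
  cum_before <- cumsum(as.integer(ins_per_anchor))
  backbone_out <- seq_len(C) + cum_before[seq_len(C)]
  if (n_ins > 0) {
    anchor_idx <- match(ins$anchor, c(0L, labels))  # 1..C+1
    ins$out <- integer(n_ins)
    for (a in unique(anchor_idx)) {
      rows <- which(anchor_idx == a)
      base <- if (a == 1L) 0L else backbone_out[a - 1L]
      ins$out[rows] <- base + seq_along(rows)
    }
  }

  ids <- c(msa_ids(backbone_aln), qids)
  mat <- matrix("-", length(ids), total, dimnames = list(ids, NULL))
  mask <- matrix(FALSE, length(ids), total, dimnames = list(ids, NULL))
  bm <- as.matrix(backbone_aln)
  mat[seq_len(nrow(bm)), backbone_out] <- bm
  if (!is.null(backbone_aln$mask)) {
    mask[seq_len(nrow(bm)), backbone_out] <- backbone_aln$mask
  }
  for (i in seq_along(exts)) {
    p <- exts[[i]]$placement
    r <- exts[[i]]$residues
    qrow <- nrow(bm) + i
    mrows <- p$type == "match"
    if (any(mrows)) {
      mat[qrow, backbone_out[match(p$col[mrows], labels)]] <- r[p$pos[mrows]]
    }
    irows <- which(ins$ext == i)
    if (length(irows) > 0) {
      mat[qrow, ins$out[irows]] <- r[ins$pos[irows]]
      mask[qrow, ins$out[irows]] <- TRUE
    }
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- ids
  msa(rows, alphabet = backbone_aln$alphabet,
      mask = if (any(mask)) mask else NULL)
}

#' Drop insertion columns from a merged alignment
#'
#' Returns the backbone-column-only view of a merged alignment: every
#' column holding a masked (insertion) cell is removed. Useful when a
#' downstream tool expects all rows aligned over shared columns only.
#'
#' @param merged An [msa] with an insertion mask (see [merge_extended]).
#' @return An [msa] without insertion columns (mask dropped).
#' @export
drop_insertion_columns <- function(merged) {
  stopifnot(inherits(merged, "msa"))
  if (is.null(merged$mask)) return(merged)
  keep <- colSums(merged$mask) == 0L
  m <- as.matrix(merged)[, keep, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- msa_ids(merged)
  msa(rows, col_labels = merged$col_labels[keep], alphabet = merged$alphabet)
}
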