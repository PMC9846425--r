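#' Gapped multiple sequence alignment
#'
#' An `msa` is a rectangular gapped sequence matrix keyed by sequence id,
#' stored as a named character vector of equal-length strings. Columns carry
#' stable integer labels so that alignments induced on a subset of rows can
#' map their columns back to the source alignment (`col_labels`). Cells may
#' additionally be masked as *insertion* cells (the lowercase convention of
#' hmmalign-style output): masked cells are written in lowercase and are
#' treated as unaligned by the evaluation functions.
#'
#' @param rows Named character vector of gapped sequences (equal lengths).
#' @param col_labels Optional integer vector of per-column labels
#'   (default `1:ncols`); must be strictly increasing.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`; guessed when `NULL`.
#' @param mask Optional logical matrix (same dimensions as the alignment,
#'   rows in the same order) marking insertion cells.
#'
#' @return An object of class `msa`.
#' @export
msa <- function(rows, col_labels = NULL, alphabet = NULL, mask = NULL) {
  if (length(rows) == 0L) stop("alignment must contain at least one sequence")
  ids <- names(rows)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("alignment rows must be named by sequence id")
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id %s", sQuote(ids[duplicated(ids)][1])))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    ref <- widths[1]
    bad <- ids[widths != ref][1]
    stop(sprintf(
      "alignment is not rectangular: row %s has %d columns, expected %d",
      sQuote(bad), widths[names(widths) == bad][1], ref))
  }
  nc <- widths[[1]]
  if (nc == 0L) stop("alignment has zero columns")

  # canonicalize: uppercase residues, '-' for gaps; lowercase becomes mask
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  lower <- mat %in% letters
  dim(lower) <- dim(mat)
  mat[mat == "."] <- "-"
  mat <- toupper(mat)
  if (any(lower)) {
    lower[mat == "-"] <- FALSE
    mask <- if (is.null(mask)) lower else (mask | lower)
  }
  if (is.null(alphabet)) alphabet <- guess_alphabet(rows)
  alph <- resolve_alphabet(alphabet)
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- ids
  for (i in seq_along(rows)) validate_residues(rows[[i]], alph, sQuote(ids[i]))

  if (is.null(col_labels)) col_labels <- seq_len(nc)
  col_labels <- as.integer(col_labels)
  if (length(col_labels) != nc || is.unsorted(col_labels, strictly = TRUE)) {
    stop("col_labels must be strictly increasing with one label per column")
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), nrow(mask) == length(rows), ncol(mask) == nc)
    rownames(mask) <- ids
  }
  structure(
    list(rows = rows, col_labels = col_labels,
         alphabet = alph$name, mask = mask),
    class = "msa")
}

#' @export
dim.msa <- function(x) c(length(x$rows), length(x$col_labels))

#' Sequence ids of an alignment
#' @param x An `msa`.
#' @return Character vector of row ids.
#' @export
msa_ids <- function(x) names(x$rows)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (%s)\n",
              nrow(x), ncol(x), x$alphabet))
  show <- utils::head(x$rows, 6L)
  for (id in names(show)) {
    s <- show[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", id, s))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), "", fixed = TRUE))
  dimnames(m) <- list(names(x$rows), NULL)
  m
}

#' Remove gaps from alignment rows
#'
#' @param x An `msa` or a character vector of (possibly gapped) sequences.
#' @return Named character vector of ungapped residue strings.
#' @export
ungap <- function(x) {
  s <- if (inherits(x, "msa")) x$rows else x
  out <- gsub("[-.]", "", s)
  toupper(out)
}

#' Read a FASTA file
#'
#' Reads aligned or unaligned FASTA. With `aligned = TRUE`, rectangularity
#' is enforced and the result is an [msa]; lowercase residues are flagged in
#' the insertion mask and canonicalized to uppercase, and `.` is accepted as
#' a gap synonym. With `aligned = FALSE` any gap characters are stripped
#' (with a warning) and a named character vector of sequences is returned.
#'
#' @param path FASTA file path.
#' @param aligned Logical; is the file an alignment?
#' @param alphabet `"dna"`, `"rna"`, `"protein"`, or `NULL` to guess.
#' @return An [msa] (`aligned = TRUE`) or named character vector.
#' @export
read_fasta <- function(path, aligned = FALSE, alphabet = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  seqs <- as.character(set)
  # ids: first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id %s in %s",
                 sQuote(ids[duplicated(ids)][1]), path))
  }
  names(seqs) <- ids
  if (aligned) {
    return(msa(seqs, alphabet = alphabet))
  }
  had_gaps <- grepl("[-.]", seqs)
  if (any(had_gaps)) {
    warning(sprintf("stripped gap characters from %d unaligned sequence(s)",
                    sum(had_gaps)))
  }
  out <- ungap(seqs)
  if (any(nchar(out) == 0L)) {
    stop(sprintf("sequence %s has no residues",
                 sQuote(ids[nchar(out) == 0L][1])))
  }
  alph <- resolve_alphabet(if (is.null(alphabet)) guess_alphabet(out) else alphabet)
  for (i in seq_along(out)) validate_residues(out[[i]], alph, sQuote(ids[i]))
  attr(out, "alphabet") <- alph$name
  out
}

#' Write sequences or an alignment to FASTA
#'
#' Alignments round-trip losslessly through [read_fasta]. Cells flagged in
#' the insertion mask (either the `msa`'s own mask or the `lowercase_mask`
#' argument) are emitted in lowercase.
#'
#' @param x An [msa] or a named character vector of sequences.
#' @param path Output file path.
#' @param lowercase_mask Optional logical matrix overriding `x$mask`.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, lowercase_mask = NULL) {
  if (inherits(x, "msa")) {
    mask <- if (is.null(lowercase_mask)) x$mask else lowercase_mask
    rows <- x$rows
    if (!is.null(mask)) {
      m <- as.matrix(x)
      low <- tolower(m)
      m[mask] <- low[mask]
      rows <- apply(m, 1L, paste, collapse = "")
      names(rows) <- names(x$rows)
    }
    out <- rows
  } else {
    if (length(x) == 0L) stop("nothing to write: empty sequence set")
    if (is.null(names(x))) stop("sequences must be named")
    out <- x
  }
  set <- Biostrings::BStringSet(out)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Induce a subalignment on a subset of rows
#'
#' Restricts an alignment to `ids` and removes columns in which every
#' retained row is a gap. Retained columns keep labels that map back to the
#' source alignment's columns, so nested inductions compose.
#'
#' @param aln An [msa].
#' @param ids Character vector of row ids to keep (nonempty subset).
#' @return An [msa] whose `col_labels` index columns of `aln` (through
#'   `aln$col_labels`).
#' @export
induced_subalignment <- function(aln, ids) {
  stopifnot(inherits(aln, "msa"))
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("ids must be nonempty")
  missing <- setdiff(ids, msa_ids(aln))
  if (length(missing) > 0L) {
    stop(sprintf("unknown sequence id %s", sQuote(missing[1])))
  }
  m <- as.matrix(aln)[ids, , drop = FALSE]
  keep <- colSums(m != "-") > 0L
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("induced subalignment has no occupied columns")
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- ids
  mask <- NULL
  if (!is.null(aln$mask)) mask <- aln$mask[ids, keep, drop = FALSE]
  msa(rows, col_labels = aln$col_labels[keep],
      alphabet = aln$alphabet, mask = mask)
}
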