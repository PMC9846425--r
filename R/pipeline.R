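#' Pipeline configuration
#'
#' Bundles the options of all three stages. The defaults are the method's
#' recommended design: adjusted bit-scores, EarlyStop search and a
#' decomposition threshold of `z = 2`. The backbone defaults to the
#' median-window selection rule; switch to `sliding_window` for datasets
#' with severe length heterogeneity (e.g. heavily fragmented inputs, where
#' the median length may fall between the full-length and fragment length
#' classes).
#'
#' @param backbone A [backbone_config].
#' @param z Decomposition threshold (default 2).
#' @param scoring `"adjusted"` (default) or `"raw"` bit-scores.
#' @param search `"earlystop"` (default), `"hierarchical"` or
#'   `"exhaustive"`.
#' @param pseudocount Laplace pseudocount for HMM training.
#' @param seed Seed for the single RNG stream used by every randomized
#'   step (backbone downsampling, search tie-breaks).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(backbone = backbone_config(), z = 2,
                            scoring = c("adjusted", "raw"),
                            search = c("earlystop", "hierarchical",
                                       "exhaustive"),
                            pseudocount = 1, seed = 1L) {
  scoring <- match.arg(scoring)
  search <- match.arg(search)
  stopifnot(inherits(backbone, "backbone_config"), z >= 1, pseudocount > 0)
  structure(list(backbone = backbone, z = z, scoring = scoring,
                 search = search, pseudocount = pseudocount, seed = seed),
            class = "pipeline_config")
}

#' Align a sequence dataset with an ensemble of profile HMMs
#'
#' Runs the full three-stage pipeline: (1) select and align a backbone of
#' full-length sequences and estimate its tree; (2) hierarchically
#' decompose the backbone tree at centroid edges and train one profile HMM
#' per subset (the ensemble); (3) for each remaining (query) sequence,
#' select an HMM by bit-score search, align the query to it with Viterbi,
#' lift the result onto backbone coordinates, and merge all extended
#' alignments by transitivity.
#'
#' A precomputed backbone may be supplied; its rows then define the
#' backbone sequence set and Stage 1 is skipped.
#'
#' @param seqs Named character vector of ungapped input sequences (>= 3).
#' @param config A [pipeline_config].
#' @param backbone_aln Optional precomputed backbone [msa].
#' @param backbone_tree Optional backbone tree ([ape::phylo]); estimated
#'   internally when absent.
#' @return A list of class `ehmm_result`: `alignment` (the merged [msa]
#'   with insertion mask), `backbone_ids`, `ensemble`, and `report` (list
#'   with the per-query search audit data.frame and stage timings).
#' @export
ehmm_align <- function(seqs, config = pipeline_config(),
                       backbone_aln = NULL, backbone_tree = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  seqs <- toupper(seqs)
  set.seed(config$seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  # Stage 1: backbone
  t0 <- tic()
  if (is.null(backbone_aln)) {
    sel <- select_backbone(seqs, config$backbone)
    if (length(sel$backbone) < 2L) {
      stop("stage 1 (backbone selection): fewer than 2 backbone sequences")
    }
    backbone_aln <- tryCatch(
      align_backbone(seqs[sel$backbone], method = config$backbone$method),
      error = function(e) stop("stage 1 (backbone alignment): ",
                               conditionMessage(e), call. = FALSE))
  } else {
    stopifnot(inherits(backbone_aln, "msa"))
    if (!all(msa_ids(backbone_aln) %in% names(seqs))) {
      stop("precomputed backbone contains unknown sequence ids")
    }
    sel <- list(backbone = msa_ids(backbone_aln),
                queries = setdiff(names(seqs), msa_ids(backbone_aln)))
  }
  if (is.null(backbone_tree)) {
    backbone_tree <- tryCatch(
      estimate_tree(backbone_aln, method = config$backbone$tree_method),
      error = function(e) stop("stage 1 (backbone tree): ",
                               conditionMessage(e), call. = FALSE))
  }
  timings["backbone"] <- tic() - t0

  # Stage 2: decomposition and HMM training
  t0 <- tic()
  ens <- tryCatch({
    e <- decompose(backbone_tree, backbone_aln, z = config$z)
    build_ehmm(e, pseudocount = config$pseudocount)
  }, error = function(e) stop("stage 2 (decomposition): ",
                              conditionMessage(e), call. = FALSE))
  timings["ensemble"] <- tic() - t0

  # Stage 3: per-query search, placement, merge
  t0 <- tic()
  search_fun <- switch(config$search,
                       exhaustive = search_exhaustive,
                       hierarchical = search_hierarchical,
                       earlystop = search_earlystop)
  queries <- seqs[sel$queries]
  exts <- list()
  audit <- vector("list", length(queries))
  unplaced <- character(0)
  for (i in seq_along(queries)) {
    qid <- names(queries)[i]
    res <- tryCatch({
      sr <- search_fun(ens, queries[[i]], scoring = config$scoring)
      node <- ens$nodes[[sr$best$node_id]]
      trace <- viterbi_align(node$hmm, queries[[i]])
      ext <- extend_alignment(queries[[i]], node, trace)
      ext$id <- qid
      list(sr = sr, ext = ext)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("query %s could not be placed (%s); appending unaligned",
                      sQuote(qid), conditionMessage(res)))
      unplaced <- c(unplaced, qid)
      audit[[i]] <- data.frame(query = qid, node_id = NA_integer_,
                               raw = NA_real_, adjusted = NA_real_,
                               n_evaluated = NA_integer_)
      next
    }
    exts[[qid]] <- res$ext
    audit[[i]] <- data.frame(query = qid, node_id = res$sr$best$node_id,
                             raw = res$sr$best$raw,
                             adjusted = res$sr$best$adjusted,
                             n_evaluated = res$sr$n_evaluated)
  }
  merged <- merge_extended(backbone_aln, exts)
  if (length(unplaced) > 0) {
    # append unaligned rows: residues in private masked columns at the end
    m <- as.matrix(merged)
    mask <- merged$mask
    if (is.null(mask)) mask <- matrix(FALSE, nrow(m), ncol(m))
    for (qid in unplaced) {
      r <- strsplit(queries[[qid]], "")[[1]]
      pad <- matrix("-", nrow(m) + 1L, ncol(m) + length(r))
      pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      pad[nrow(m) + 1L, ncol(m) + seq_along(r)] <- r
      mpad <- matrix(FALSE, nrow(pad), ncol(pad))
      mpad[seq_len(nrow(m)), seq_len(ncol(m))] <- mask
      mpad[nrow(m) + 1L, ncol(m) + seq_along(r)] <- TRUE
      rownames(pad) <- c(rownames(m), qid)
      m <- pad; mask <- mpad
    }
    rows <- apply(m, 1L, paste, collapse = "")
    names(rows) <- rownames(m)
    merged <- msa(rows, alphabet = merged$alphabet, mask = mask)
  }
  timings["queries"] <- tic() - t0

  audit <- if (length(audit) > 0) do.call(rbind, audit) else
    data.frame(query = character(0), node_id = integer(0),
               raw = numeric(0), adjusted = numeric(0),
               n_evaluated = integer(0))
  structure(
    list(alignment = merged,
         backbone_ids = sel$backbone,
         ensemble = ens,
         report = list(audit = audit, timings = timings,
                       unplaced = unplaced, config = config)),
    class = "ehmm_result")
}

#' @export
print.ehmm_result <- function(x, ...) {
  cat(sprintf(
    "ehmm_result: %d sequences (%d backbone + %d queries), %d columns\n",
    nrow(x$alignment), length(x$backbone_ids),
    nrow(x$alignment) - length(x$backbone_ids), ncol(x$alignment)))
  cat(sprintf("  ensemble: %d HMMs (z = %d); search: %s (%s bit-scores)\n",
              length(x$ensemble$nodes), x$ensemble$z,
              x$report$config$search, x$report$config$scoring))
  if (nrow(x$report$audit) > 0) {
    cat(sprintf("  HMMs evaluated per query: mean %.1f of %d\n",
                mean(x$report$audit$n_evaluated, na.rm = TRUE),
                length(x$ensemble$nodes)))
  }
  invisible(x)
}
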