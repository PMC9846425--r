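#' Adjusted bit-score
#'
#' Corrects a raw profile-HMM bit-score for the number of sequences `s`
#' used to build the HMM: `b + log2(s)`. Under the assumption that exactly
#' one HMM in the ensemble generated the query, normalizing `2^adjusted`
#' over the ensemble yields the posterior probability of each HMM -- the
#' size term is the (size-proportional) prior on which subset the query
#' originated from, and the shared null-model likelihood cancels.
#'
#' @param b Raw bit-score(s).
#' @param s Subset size(s), positive integers.
#' @return Adjusted bit-score(s).
#' @export
adjusted_bitscore <- function(b, s) {
  if (any(s < 1)) stop("subset size must be at least 1")
  b + log2(s)
}

## log2-sum-exp
lse2_base2 <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log2(sum(2^(x - m)))
}

#' Posterior probability of each HMM given a query
#'
#' Normalizes adjusted bit-scores into posterior probabilities
#' `P(H_i | q) = 2^beta_i / sum_j 2^beta_j` (log-sum-exp, so very large
#' scores are safe). Hits with `-Inf` adjusted score get posterior 0.
#'
#' @param hits data.frame with at least an `adjusted` column (as produced
#'   by the search functions), or a numeric vector of adjusted bit-scores.
#' @return The same structure with a `posterior` column (or a numeric
#'   vector of posteriors) summing to 1.
#' @export
posterior_over <- function(hits) {
  beta <- if (is.data.frame(hits)) hits$adjusted else hits
  if (length(beta) == 0L) stop("no hits to normalize")
  if (all(!is.finite(beta))) {
    stop("all adjusted bit-scores are -Inf: the query matches no model")
  }
  denom <- lse2_base2(beta)
  post <- ifelse(is.finite(beta), 2^(beta - denom), 0)
  post <- post / sum(post)  # guard residual rounding
  if (is.data.frame(hits)) {
    hits$posterior <- post
    hits
  } else {
    post
  }
}

score_node <- function(ens, node_id, q) {
  node <- ens$nodes[[node_id]]
  b <- forward_bitscore(node$hmm, q)
  data.frame(node_id = node_id, depth = node$depth, size = node$size,
             raw = b, adjusted = adjusted_bitscore(b, node$size))
}

pick_best <- function(evaluated, scoring) {
  key <- evaluated[[scoring]]
  best <- which(key == max(key))
  # ties broken by smallest pre-order node_id
  best[which.min(evaluated$node_id[best])]
}

finish_search <- function(evaluated, scoring, strategy) {
  evaluated$order <- seq_len(nrow(evaluated))
  best_row <- pick_best(evaluated, scoring)
  structure(list(best = evaluated[best_row, , drop = FALSE],
                 evaluated = evaluated,
                 n_evaluated = nrow(evaluated),
                 scoring = scoring, strategy = strategy),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result (%s, %s): best node %d (%s = %.2f bits), %d HMM(s) evaluated\n",
              x$strategy, x$scoring, x$best$node_id,
              x$scoring, x$best[[x$scoring]], x$n_evaluated))
  invisible(x)
}

#' Score a query against every HMM in the ensemble
#'
#' The all-against-all strategy: every node is scored and the best raw or
#' adjusted bit-score wins (ties to the smallest pre-order node id).
#' Posteriors over the full ensemble are attached to the evaluation table.
#'
#' @param ens A trained `hmm_ensemble` (see [build_ehmm]).
#' @param q Query sequence (character string).
#' @param scoring `"adjusted"` (default) or `"raw"`.
#' @return A `search_result`: `best` (one-row data.frame), `evaluated`
#'   (all scored nodes in evaluation order) and `n_evaluated`.
#' @export
search_exhaustive <- function(ens, q, scoring = c("adjusted", "raw")) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(ens, "hmm_ensemble"))
  evaluated <- do.call(rbind, lapply(seq_along(ens$nodes), score_node,
                                     ens = ens, q = q))
  evaluated <- posterior_over(evaluated)
  finish_search(evaluated, scoring, "exhaustive")
}

descend <- function(ens, q, scoring, early_stop) {
  evaluated <- score_node(ens, ens$root_id, q)
  cur <- ens$root_id
  repeat {
    kids <- ens$nodes[[cur]]$children
    if (length(kids) == 0L) break
    best_before <- max(evaluated[[scoring]])
    s1 <- score_node(ens, kids[1], q)
    s2 <- score_node(ens, kids[2], q)
    evaluated <- rbind(evaluated, s1, s2)
    if (early_stop &&
        max(s1[[scoring]], s2[[scoring]]) < best_before) break
    if (s1[[scoring]] > s2[[scoring]]) {
      cur <- kids[1]
    } else if (s2[[scoring]] > s1[[scoring]]) {
      cur <- kids[2]
    } else {
      cur <- kids[sample.int(2L, 1L)]  # tie: seeded random choice
    }
  }
  evaluated
}

#' Hierarchical search through the HMM ensemble
#'
#' Starts at the root, scores both children of the current node, and
#' descends into the higher-scoring subtree (ties resolved by a seeded
#' random choice) until a leaf is reached. The selected HMM is the best
#' scorer among all nodes evaluated, so at most two HMMs are scored per
#' hierarchy level instead of the whole ensemble.
#'
#' @inheritParams search_exhaustive
#' @return A `search_result`.
#' @export
search_hierarchical <- function(ens, q, scoring = c("adjusted", "raw")) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(ens, "hmm_ensemble"))
  finish_search(descend(ens, q, scoring, early_stop = FALSE),
                scoring, "hierarchical")
}

#' EarlyStop search through the HMM ensemble
#'
#' Identical to [search_hierarchical] but the descent halts as soon as both
#' children of the current node score strictly below the best score seen so
#' far (they are then considered less likely than the current best HMM to
#' have emitted the query), which never evaluates more HMMs than the full
#' hierarchical descent.
#'
#' @inheritParams search_exhaustive
#' @return A `search_result`.
#' @export
search_earlystop <- function(ens, q, scoring = c("adjusted", "raw")) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(ens, "hmm_ensemble"))
  finish_search(descend(ens, q, scoring, early_stop = TRUE),
                scoring, "earlystop")
}
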