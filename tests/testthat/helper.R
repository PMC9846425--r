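# Shared fixtures and independent oracles.

# Write a FASTA string to a temp file and return the path.
tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}

# Independent oracle for the glocal profile-HMM likelihood: explicitly
# enumerates every state path through the model, accumulating transition
# and emission log probabilities, and combines complete paths by
# log-sum-exp ("sum") or max ("max"). Exponential in size; only usable on
# toy instances -- which is the point.
oracle_path_score <- function(hmm, q, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  res_idx <- match(strsplit(toupper(q), "", fixed = TRUE)[[1]], hmm$residues)
  L <- length(res_idx)
  k <- hmm$k
  em <- function(j, i) if (is.na(res_idx[i])) 0 else hmm$log_match[j, res_idx[i]]
  ei <- function(i) if (is.na(res_idx[i])) 0 else hmm$log_ins[[res_idx[i]]]
  acc <- numeric(0)
  recurse <- function(type, j, i, lp) {
    tr <- switch(type, M = hmm$tM, I = hmm$tI, D = hmm$tD)[j + 1, ]
    if (j == k) {
      if (i == L && is.finite(tr[1])) acc <<- c(acc, lp + tr[1])
      if (i < L && is.finite(tr[2])) {
        recurse("I", k, i + 1, lp + tr[2] + ei(i + 1))
      }
      return(invisible(NULL))
    }
    if (i < L && is.finite(tr[1])) {
      recurse("M", j + 1, i + 1, lp + tr[1] + em(j + 1, i + 1))
    }
    if (i < L && is.finite(tr[2])) {
      recurse("I", j, i + 1, lp + tr[2] + ei(i + 1))
    }
    if (is.finite(tr[3])) recurse("D", j + 1, i, lp + tr[3])
  }
  recurse("M", 0L, 0L, 0)
  if (length(acc) == 0L) return(-Inf)
  if (mode == "sum") {
    m <- max(acc)
    m + log(sum(exp(acc - m)))
  } else {
    max(acc)
  }
}

# Forward log-likelihood (not bit-score) through the package's DP kernel,
# for direct comparison against oracle_path_score.
dp_forward_logp <- function(hmm, q) {
  e <- ehmmalign:::query_emissions(
    hmm, strsplit(toupper(q), "", fixed = TRUE)[[1]])
  ehmmalign:::.phmm_forward(e$EM, e$EI, hmm$tM, hmm$tI, hmm$tD)
}

# Random tiny profile HMM: trained on a random alignment with nrows rows
# and ncols columns over DNA.
random_toy_hmm <- function(nrows = 2, ncols = 3, p_gap = 0.25) {
  repeat {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), nrows * ncols,
                       replace = TRUE,
                       prob = c(rep((1 - p_gap) / 4, 4), p_gap)),
                nrows, ncols)
    if (any(colMeans(m != "-") >= 0.5) && all(rowSums(m != "-") > 0)) break
  }
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- paste0("r", seq_len(nrows))
  build_profile(msa(rows, alphabet = "dna"))
}

random_query <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Independent quadratic oracle for homology pairs: walks every row pair
# column by column, tracking residue indices directly.
oracle_pairs <- function(aln) {
  m <- as.matrix(aln)
  ids <- rownames(m)
  mask <- aln$mask
  out <- character(0)
  n <- nrow(m)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ra <- 0L; rb <- 0L
      for (cc in seq_len(ncol(m))) {
        ca <- m[a, cc] != "-"; cb <- m[b, cc] != "-"
        if (ca) ra <- ra + 1L
        if (cb) rb <- rb + 1L
        ok <- ca && cb
        if (ok && !is.null(mask)) ok <- !mask[a, cc] && !mask[b, cc]
        if (ok) {
          pair <- if (ids[a] <= ids[b]) {
            paste(ids[a], ra, ids[b], rb, sep = "\x1f")
          } else {
            paste(ids[b], rb, ids[a], ra, sep = "\x1f")
          }
          out <- c(out, pair)
        }
      }
    }
  }
  out
}

# Ensemble skeleton with prescribed raw scores, for exercising the search
# strategies in isolation (scoring is stubbed via local_mocked_bindings).
fake_ensemble <- function(raw_scores, children, sizes = NULL) {
  n <- length(raw_scores)
  if (is.null(sizes)) sizes <- rep(1L, n)
  depth <- integer(n)
  for (id in seq_len(n)) {
    for (ch in children[[id]]) depth[ch] <- depth[id] + 1L
  }
  nodes <- lapply(seq_len(n), function(id) {
    list(node_id = id, parent = NA_integer_, children = children[[id]],
         depth = depth[id], ids = as.character(id), size = sizes[id],
         subaln = NULL, hmm = NULL)
  })
  structure(list(nodes = nodes, z = 2L, root_id = 1L,
                 backbone_ids = character(0), raw_scores = raw_scores),
            class = "hmm_ensemble")
}

# Stub score_node so search strategies see the prescribed scores.
with_fake_scores <- function(code) {
  testthat::local_mocked_bindings(
    score_node = function(ens, node_id, q) {
      node <- ens$nodes[[node_id]]
      b <- ens$raw_scores[[node_id]]
      data.frame(node_id = node_id, depth = node$depth, size = node$size,
                 raw = b, adjusted = adjusted_bitscore(b, node$size))
    },
    .package = "ehmmalign",
    .env = parent.frame())
  force(code)
}

# Small simulated pipeline fixture shared by merge/pipeline tests.
sim_fixture <- function(n = 20, len = 80, sub = 0.08, indel = 0.005,
                        sim_seed = 3, frag_seed = 5) {
  sim <- simulate_msa(sim_config(n_taxa = n, root_length = len,
                                 sub_rate = sub, indel_rate = indel,
                                 seed = sim_seed))
  frags <- fragmentize(sim$sequences, frag_config(seed = frag_seed))
  list(sim = sim, frags = frags,
       ref = fragment_reference(sim$alignment, frags))
}

# Hand-built viterbi trace (for exercising the mapping rules directly).
hand_trace <- function(pos, type, mstate, k) {
  structure(list(steps = data.frame(pos = pos, type = type,
                                    mstate = mstate),
                 deleted = !seq_len(k) %in% mstate[type == "match"],
                 log2p = 0),
            class = "query_alignment_trace")
}
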