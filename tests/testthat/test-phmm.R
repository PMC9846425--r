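test_that("match columns and emissions follow the counting rules", {
  # two rows, both columns fully occupied: P(A) = (2+1)/(2+4) = 0.5
  hmm <- build_profile(msa(c(x = "AA", y = "AA")), pseudocount = 1)
  expect_equal(hmm$k, 2L)
  expect_equal(unname(exp(hmm$log_match[1, "A"])), 0.5)
  expect_equal(unname(exp(hmm$log_match[2, "A"])), 0.5)

  # a half-occupied column still reaches the 0.5 match threshold
  hmm2 <- build_profile(msa(c(x = "A-", y = "AA")))
  expect_equal(hmm2$k, 2L)
  expect_equal(hmm2$match_cols, 1:2)

  # single-row profile: every column is a match column, dominated by its residue
  hmm3 <- build_profile(msa(c(x = "ACGT")))
  expect_equal(hmm3$k, 4L)
  for (j in 1:4) {
    expect_equal(unname(which.max(hmm3$log_match[j, ])),
                 which(hmm3$residues == substr("ACGT", j, j)))
  }

  # no column half-occupied: constructing the model is impossible
  wide <- msa(c(a = "A---", b = "-C--", c = "--G-", d = "---T"))
  expect_error(build_profile(wide), "threshold")
})

test_that("model parameters normalize to probability distributions", {
  set.seed(13)
  for (rep in 1:10) {
    hmm <- random_toy_hmm(nrows = sample(2:4, 1), ncols = sample(2:5, 1))
    for (j in seq_len(hmm$k)) {
      expect_equal(sum(exp(hmm$log_match[j, ])), 1, tolerance = 1e-9)
    }
    expect_equal(sum(exp(hmm$log_ins)), 1, tolerance = 1e-9)
    for (j in 0:hmm$k) {
      expect_equal(sum(exp(hmm$tM[j + 1, ])), 1, tolerance = 1e-9)
      expect_equal(sum(exp(hmm$tI[j + 1, ])), 1, tolerance = 1e-9)
      if (j > 0) expect_equal(sum(exp(hmm$tD[j + 1, ])), 1, tolerance = 1e-9)
    }
  }
})

test_that("duplicating every training row only dilutes the pseudocount", {
  aln <- msa(c(x = "AC-G", y = "A-CG", z = "ACCG"))
  dup_rows <- c(aln$rows, setNames(aln$rows, paste0(names(aln$rows), "2")))
  hmm1 <- build_profile(aln, pseudocount = 1)
  hmm2 <- build_profile(msa(dup_rows), pseudocount = 1)
  # doubling counts with fixed pseudocount moves emissions toward the MLE;
  # with pseudocount ~0 both converge to the same counts
  h1 <- build_profile(aln, pseudocount = 1e-9)
  h2 <- build_profile(msa(dup_rows), pseudocount = 1e-9)
  expect_equal(exp(h1$log_match), exp(h2$log_match), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(hmm1$log_match, hmm2$log_match)))
})

test_that("a flat one-state model scores zero bits", {
  # uniform match emission over DNA, deterministic B->M1->End transitions,
  # uniform null: likelihood ratio 0.25/0.25 = 1, i.e. exactly 0 bits
  hmm <- build_profile(msa(c(a = "A", b = "C", c = "G", d = "T")))
  hmm$log_match[1, ] <- log(0.25)
  hmm$log_bg[] <- log(0.25)
  det <- matrix(-Inf, 2, 3); det[, 1] <- 0
  hmm$tM <- det
  hmm$tI[, ] <- -Inf
  hmm$tD[, ] <- -Inf
  expect_equal(forward_bitscore(hmm, "A"), 0)
})

test_that("forward equals the brute-force path enumeration on all toy sizes", {
  set.seed(17)
  for (k_target in 1:3) {
    for (L in 1:4) {
      for (rep in 1:5) {
        hmm <- random_toy_hmm(nrows = sample(2:3, 1), ncols = k_target)
        q <- random_query(L)
        expect_equal(dp_forward_logp(hmm, q),
                     oracle_path_score(hmm, q, "sum"),
                     tolerance = 1e-9,
                     info = sprintf("k=%d L=%d rep=%d", hmm$k, L, rep))
      }
    }
  }
})

test_that("viterbi recovers the max-probability path and never beats forward", {
  set.seed(19)
  for (rep in 1:100) {
    hmm <- random_toy_hmm(nrows = sample(2:3, 1), ncols = sample(2:4, 1))
    q <- random_query(sample(1:5, 1))
    fwd <- dp_forward_logp(hmm, q)
    tr <- viterbi_align(hmm, q)
    # path probability (bits) <= forward probability (bits)
    expect_lte(tr$log2p, forward_bitscore(hmm, q) + 1e-9)
    if (nchar(q) <= 4 && hmm$k <= 3) {
      null_log <- sum(hmm$log_bg[match(strsplit(q, "")[[1]], hmm$residues)])
      expect_equal(tr$log2p,
                   (oracle_path_score(hmm, q, "max") - null_log) / log(2),
                   tolerance = 1e-9)
    }
  }
})

test_that("self-alignment of a training row is all matches", {
  hmm <- build_profile(msa(c(x = "ACGTACGT")), pseudocount = 0.1)
  tr <- viterbi_align(hmm, "ACGTACGT")
  expect_true(all(tr$steps$type == "match"))
  expect_equal(tr$steps$mstate, 1:8)
  expect_false(any(tr$deleted))
})

test_that("a query longer than a zero-insert model has no path", {
  hmm <- build_profile(msa(c(a = "A", b = "A")))
  # forbid inserts entirely: impossible-emission sentinel expected
  hmm$tM[, 2] <- -Inf
  hmm$tI[, ] <- -Inf
  expect_equal(forward_bitscore(hmm, "AA"), -Inf)
  expect_error(viterbi_align(hmm, "AA"), "no valid")
})

test_that("bit-score rankings are invariant to a rescaled null model", {
  set.seed(23)
  q <- random_query(4)
  hmms <- lapply(1:5, function(i) random_toy_hmm(ncols = 3))
  base <- vapply(hmms, forward_bitscore, 0.0, q = q)
  shifted <- vapply(hmms, function(h) {
    h$log_bg <- h$log_bg + log(0.5)  # scale all null frequencies by 1/2
    forward_bitscore(h, q)
  }, 0.0)
  # every score shifts by the same per-residue amount ...
  expect_equal(diff(range((shifted - base))), 0, tolerance = 1e-9)
  expect_equal(shifted - base, rep(-nchar(q) * log2(0.5), 5),
               tolerance = 1e-9)
  # ... so the ranking cannot change
  expect_equal(order(base), order(shifted))
})

test_that("ambiguity codes emit with probability one under model and null", {
  hmm <- build_profile(msa(c(x = "ACG", y = "ACG")))
  # the path-enumeration oracle implements the same convention
  expect_equal(dp_forward_logp(hmm, "ANG"),
               oracle_path_score(hmm, "ANG", "sum"), tolerance = 1e-9)
  # an all-ambiguity query is emitted "for free"; only transitions and the
  # empty null remain, so the score is the same for any ambiguity string
  expect_equal(forward_bitscore(hmm, "NNN"), forward_bitscore(hmm, "NRY"))
  expect_error(forward_bitscore(hmm, "AZG"), "non-dna")
})

test_that("all scores stay finite with a positive pseudocount", {
  set.seed(29)
  for (rep in 1:20) {
    hmm <- random_toy_hmm(nrows = 2, ncols = sample(2:4, 1))
    q <- random_query(sample(1:6, 1))
    expect_true(is.finite(forward_bitscore(hmm, q)))
  }
})
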