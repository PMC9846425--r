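# A 7-node balanced hierarchy: 1 -> (2, 5), 2 -> (3, 4), 5 -> (6, 7).
balanced7 <- function(scores, sizes = NULL) {
  fake_ensemble(scores,
                children = list(c(2L, 5L), c(3L, 4L), integer(0), integer(0),
                                c(6L, 7L), integer(0), integer(0)),
                sizes = sizes)
}

test_that("adjusted bit-scores add the log2 subset size", {
  expect_equal(adjusted_bitscore(10, 4), 12)
  expect_equal(adjusted_bitscore(-3.5, 1), -3.5)
  expect_equal(adjusted_bitscore(0, 8), 3)
  expect_error(adjusted_bitscore(1, 0), "at least 1")
  # the adjustment orders candidates exactly like the posterior 2^b * s
  set.seed(31)
  for (rep in 1:20) {
    b <- runif(5, -20, 20); s <- sample(1:64, 5, replace = TRUE)
    expect_equal(which.max(adjusted_bitscore(b, s)), which.max(2^b * s))
  }
})

test_that("posteriors normalize adjusted scores via log-sum-exp", {
  expect_equal(posterior_over(c(3, 3)), c(0.5, 0.5))
  expect_equal(posterior_over(c(1, 0)), c(2 / 3, 1 / 3))
  expect_equal(posterior_over(5), 1)
  expect_equal(posterior_over(c(2, -Inf)), c(1, 0))
  expect_error(posterior_over(c(-Inf, -Inf)), "-Inf")
  # huge scores that would overflow 2^beta directly
  expect_equal(posterior_over(c(5000, 5000)), c(0.5, 0.5))
  set.seed(37)
  for (rep in 1:1000) {
    beta <- runif(sample(2:10, 1), -50, 50)
    expect_equal(sum(posterior_over(beta)), 1, tolerance = 1e-9)
  }
})

test_that("exhaustive search scores every node and applies the tie rule", {
  with_fake_scores({
    ens <- balanced7(c(5, 4, 3, 2, 4.5, 1, 0))
    res <- search_exhaustive(ens, "ACGT")
    expect_equal(res$n_evaluated, 7L)
    expect_equal(res$best$node_id, 1L)
    expect_equal(sum(res$evaluated$posterior), 1, tolerance = 1e-9)

    # all tied: the first node in pre-order wins
    tied <- balanced7(rep(2, 7))
    expect_equal(search_exhaustive(tied, "A")$best$node_id, 1L)
  })
})

test_that("raw and adjusted scoring can select different nodes", {
  with_fake_scores({
    # two children: raw favors the small subset, adjusted the large one
    ens <- fake_ensemble(c(9, 10, 9.5),
                         children = list(c(2L, 3L), integer(0), integer(0)),
                         sizes = c(5L, 1L, 4L))
    raw_pick <- search_exhaustive(ens, "A", scoring = "raw")$best$node_id
    adj_pick <- search_exhaustive(ens, "A", scoring = "adjusted")$best$node_id
    expect_equal(raw_pick, 2L)       # 10 > 9.5
    expect_equal(adj_pick, 3L)       # 9.5 + 2 = 11.5 > 10 + 0
  })
})

test_that("hierarchical descent follows the higher-scoring child", {
  with_fake_scores({
    # root 5; level-1 children {7, 3}; children of the 7-node {6, 2}
    ens <- balanced7(c(5, 7, 6, 2, 3, 0, 0))
    res <- search_hierarchical(ens, "A")
    expect_equal(res$best$node_id, 2L)
    expect_equal(res$best$adjusted, 7)
    expect_equal(res$n_evaluated, 5L)
    expect_equal(res$evaluated$node_id, c(1L, 2L, 5L, 3L, 4L))

    # single-node ensemble: no descent
    single <- fake_ensemble(c(4), children = list(integer(0)))
    expect_equal(search_hierarchical(single, "A")$n_evaluated, 1L)
  })
})

test_that("earlystop halts when both children trail the current best", {
  with_fake_scores({
    # root 5, children {3, 4}: stop right after scoring the children
    ens <- balanced7(c(5, 3, 0, 0, 4, 0, 0))
    res <- search_earlystop(ens, "A")
    expect_equal(res$n_evaluated, 3L)
    expect_equal(res$best$node_id, 1L)

    # strictly increasing toward a leaf: identical to hierarchical
    inc <- balanced7(c(1, 2, 4, 3, 0, 0, 0))
    rh <- search_hierarchical(inc, "A")
    re <- search_earlystop(inc, "A")
    expect_equal(re$best$node_id, rh$best$node_id)
    expect_equal(re$n_evaluated, rh$n_evaluated)

    single <- fake_ensemble(c(4), children = list(integer(0)))
    expect_equal(search_earlystop(single, "A")$n_evaluated, 1L)
  })
})

test_that("evaluation counts order earlystop <= hierarchical <= exhaustive", {
  with_fake_scores({
    set.seed(41)
    for (rep in 1:50) {
      scores <- round(runif(7, 0, 10), 1)
      ens <- balanced7(scores)
      set.seed(rep); ne <- search_earlystop(ens, "A")$n_evaluated
      set.seed(rep); nh <- search_hierarchical(ens, "A")$n_evaluated
      nx <- search_exhaustive(ens, "A")$n_evaluated
      expect_lte(ne, nh)
      expect_lte(nh, nx)
      # at most two HMMs per level below the root
      ev <- search_hierarchical(ens, "A")$evaluated
      expect_true(all(table(ev$depth) <= 2))
      expect_equal(sum(ev$depth == 0), 1)
    }
  })
})

test_that("strategies agree when scores rise along the path to the argmax", {
  with_fake_scores({
    # monotone: every root-to-argmax prefix is non-decreasing
    ens <- balanced7(c(1, 3, 2, 7, 0.5, 0, 0))
    bx <- search_exhaustive(ens, "A")$best$node_id
    bh <- search_hierarchical(ens, "A")$best$node_id
    be <- search_earlystop(ens, "A")$best$node_id
    expect_equal(bh, bx)
    expect_equal(be, bx)
  })
})

test_that("descent ties are reproducible under a fixed seed", {
  with_fake_scores({
    ens <- balanced7(c(5, 4, 1, 2, 4, 3, 6))  # children of root tie at 4
    set.seed(99); a <- search_hierarchical(ens, "A")$evaluated$node_id
    set.seed(99); b <- search_hierarchical(ens, "A")$evaluated$node_id
    expect_identical(a, b)
    # both tie branches are reachable across seeds
    picks <- vapply(1:20, function(s) {
      set.seed(s)
      search_hierarchical(ens, "A")$evaluated$node_id[4]
    }, 0L)
    expect_setequal(unique(picks), c(3L, 6L))
  })
})

test_that("search on a real trained ensemble selects a model containing kin", {
  sim <- simulate_msa(sim_config(n_taxa = 8, root_length = 50,
                                 sub_rate = 0.15, indel_rate = 0,
                                 seed = 51))
  aln <- sim$alignment
  tr <- estimate_tree(aln)
  ens <- build_ehmm(decompose(tr, aln, z = 2))
  # query = prefix fragment of a backbone sequence; its best leaf model
  # should contain that very sequence
  qid <- names(sim$sequences)[3]
  q <- substr(sim$sequences[[qid]], 5, 30)
  res <- search_exhaustive(ens, q)
  expect_true(qid %in% ens$nodes[[res$best$node_id]]$ids)
  resh <- search_hierarchical(ens, q)
  rese <- search_earlystop(ens, q)
  expect_lte(rese$n_evaluated, resh$n_evaluated)
  expect_lte(resh$n_evaluated, res$n_evaluated)
})
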