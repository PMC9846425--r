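# Minimal real ensemble on a hand-built backbone, for placement tests.
toy_node <- function(backbone_rows, ids = names(backbone_rows)) {
  aln <- msa(backbone_rows)
  sub <- induced_subalignment(aln, ids)
  list(aln = aln,
       node = list(node_id = 1L, ids = ids, size = length(ids),
                   subaln = sub, hmm = build_profile(sub, pseudocount = 0.1),
                   children = integer(0), depth = 0L))
}

test_that("an all-match trace maps residues straight onto backbone columns", {
  fx <- toy_node(c(b1 = "ACGT", b2 = "ACGT"))
  trace <- viterbi_align(fx$node$hmm, "ACGT")
  ext <- extend_alignment("ACGT", fx$node, trace)
  expect_true(all(ext$placement$type == "match"))
  expect_equal(ext$placement$col, 1:4)

  merged <- merge_extended(fx$aln, list(q = ext))
  expect_equal(ncol(merged), 4L)
  expect_equal(unname(merged$rows["q"]), "ACGT")
})

test_that("insert residues key to the preceding backbone column", {
  # mapping rule on a hand-built trace: insert between match states 2 and 3
  fx <- toy_node(c(b1 = "ACG", b2 = "ACG"))
  trace <- hand_trace(1:4, c("match", "match", "insert", "match"),
                      c(1L, 2L, 2L, 3L), k = 3)
  ext <- extend_alignment("ACTG", fx$node, trace)
  ins <- ext$placement[ext$placement$type == "insert", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$anchor, 2L)   # keyed to the column of match state 2
  expect_equal(ins$offset, 0L)

  # and through viterbi, with an unambiguous inserted residue
  fx2 <- toy_node(c(b1 = "ACTG", b2 = "ACTG"))
  trace2 <- viterbi_align(fx2$node$hmm, "ACATG")
  ext2 <- extend_alignment("ACATG", fx2$node, trace2)
  ins2 <- ext2$placement[ext2$placement$type == "insert", ]
  expect_equal(ins2$anchor, 2L)
  merged <- merge_extended(fx2$aln, list(q = ext2))
  expect_equal(ncol(merged), 5L)
  expect_equal(unname(merged$rows["q"]), "ACATG")
  expect_equal(unname(merged$rows["b1"]), "AC-TG")
  expect_true(merged$mask["q", 3])
})

test_that("a leading insert keys to the virtual column zero", {
  fx <- toy_node(c(b1 = "CGT", b2 = "CGT"))
  trace <- hand_trace(1:4, c("insert", "match", "match", "match"),
                      c(0L, 1L, 2L, 3L), k = 3)
  ext <- extend_alignment("TCGT", fx$node, trace)
  first <- ext$placement[1, ]
  expect_equal(first$type, "insert")
  expect_equal(first$anchor, 0L)
  merged <- merge_extended(fx$aln, list(q = ext))
  # the inserted column precedes every backbone column
  expect_equal(unname(merged$rows["q"]), "TCGT")
  expect_equal(unname(merged$rows["b1"]), "-CGT")
  # viterbi reaches the same placement when the leading residue has
  # background support
  trace_v <- viterbi_align(fx$node$hmm, "TCGT")
  ext_v <- extend_alignment("TCGT", fx$node, trace_v)
  expect_equal(ext_v$placement, ext$placement)
})

test_that("merging zero queries reproduces the backbone", {
  aln <- msa(c(x = "AC-G", y = "A-CG"))
  merged <- merge_extended(aln, list())
  expect_equal(merged$rows, aln$rows)
  expect_null(merged$mask)
})

test_that("insertions from different queries occupy private columns", {
  fx <- toy_node(c(b1 = "ACG", b2 = "ACG"))
  t12 <- hand_trace(1:4, c("match", "match", "insert", "match"),
                    c(1L, 2L, 2L, 3L), k = 3)
  e1 <- extend_alignment("ACTG", fx$node, t12)
  e2 <- extend_alignment("ACAG", fx$node, t12)
  merged <- merge_extended(fx$aln, list(q1 = e1, q2 = e2))
  # both queries insert after backbone column 2: two distinct new columns
  expect_equal(ncol(merged), 5L)
  ins_cols <- which(colSums(merged$mask) > 0)
  expect_length(ins_cols, 2L)
  m <- as.matrix(merged)
  for (cc in ins_cols) {
    expect_equal(sum(m[, cc] != "-"), 1L)  # exactly one residue each
  }
  # mutual unalignment: the two insertion residues never share a column
  expect_false(any(m["q1", ins_cols] != "-" & m["q2", ins_cols] != "-"))
})

test_that("merge restriction and residue conservation hold on pipeline runs", {
  fx <- sim_fixture()
  res <- ehmm_align(fx$frags,
                    pipeline_config(
                      backbone = backbone_config(strategy = "sliding_window"),
                      seed = 7))
  merged <- res$alignment
  # restriction: merged |_backbone == backbone alignment, exactly
  backbone <- induced_subalignment(merged, res$backbone_ids)
  expect_equal(ungap(backbone), ungap(merged)[res$backbone_ids])
  bb_est <- align_backbone(fx$frags[res$backbone_ids])
  expect_equal(backbone$rows, bb_est$rows)
  # every input residue appears exactly once
  expect_equal(sort(names(merged$rows)), sort(names(fx$frags)))
  expect_equal(unname(nchar(ungap(merged)[names(fx$frags)])),
               unname(nchar(fx$frags)))
  expect_equal(unname(ungap(merged)[names(fx$frags)]), as.character(fx$frags))
  # insertion columns are singletons
  if (!is.null(merged$mask)) {
    m <- as.matrix(merged)
    for (cc in which(colSums(merged$mask) > 0)) {
      expect_equal(sum(m[, cc] != "-"), 1L)
    }
  }
})

test_that("transitivity is lossless per query", {
  fx <- toy_node(c(b1 = "ACGTA", b2 = "ACGTA", b3 = "AC-TA"))
  q <- "CGTA"
  trace <- viterbi_align(fx$node$hmm, q)
  ext <- extend_alignment(q, fx$node, trace)
  merged <- merge_extended(fx$aln, list(q = ext))
  # pairs implied by the extended alignment: each matched query residue is
  # homologous to every backbone residue in its mapped backbone column
  p <- ext$placement
  bm <- as.matrix(fx$aln)
  implied <- character(0)
  for (r in which(p$type == "match")) {
    cc <- match(p$col[r], fx$aln$col_labels)
    for (id in rownames(bm)) {
      if (bm[id, cc] != "-") {
        ri_b <- sum(bm[id, seq_len(cc)] != "-")
        key <- if (id <= "q") {
          paste(id, ri_b, "q", p$pos[r], sep = "\x1f")
        } else {
          paste("q", p$pos[r], id, ri_b, sep = "\x1f")
        }
        implied <- c(implied, key)
      }
    }
  }
  hp <- homology_pairs(merged)
  observed <- hp[grepl("q", hp, fixed = TRUE)]
  expect_setequal(observed, implied)
})
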