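test_that("graph construction contracts unitigs and conserves k-mers", {
  g <- build_graph(c("ACGGT", "CGGTA"), 3)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$len, 4L)
  expect_equal(g$nodes$avg_cov, 1.5)          # (1+2+2+1)/4
  expect_true(g$nodes$seq %in% c("ACGGTA", rc_oracle("ACGGTA")))

  # one read, any k: one unitig equal to the read at coverage 1
  g1 <- build_graph("AGCCTTAAAT", 5)
  expect_equal(nrow(g1$nodes), 1L)
  expect_equal(g1$nodes$avg_cov, 1)
  expect_true(g1$nodes$seq %in% c("AGCCTTAAAT", rc_oracle("AGCCTTAAAT")))

  # 30 error-free reads tiling a 500 bp repeat-free genome: one unitig
  gen <- simulate_genome(500, 0, seed = 11)
  starts <- round(seq(1, 401, length.out = 30))
  reads <- substring(gen$sequence, starts, starts + 99)
  g2 <- build_graph(reads, 15)
  expect_equal(nrow(g2$nodes), 1L)
  expect_true(g2$nodes$seq %in% c(gen$sequence, rc_oracle(gen$sequence)))

  # conservation on arbitrary noisy input (including rc-palindromic unitigs)
  set.seed(9)
  for (reads in list(random_dna(20, 40), c("GAACGTTC", "AACGTT"))) {
    k <- if (max(nchar(reads)) < 15) 3 else 15
    gg <- build_graph(reads, k)
    windows <- sum(pmax(nchar(reads) - k + 1, 0))
    expect_equal(sum(gg$nodes$len * gg$nodes$avg_cov), windows)
    expect_equal(sum(gg$counts), windows)
  }

  expect_error(build_graph(c("ACGT"), 10), "parameter error")
  expect_error(build_graph(c("ACGTACGT"), 4), "odd")
})

test_that("tips and bubbles are flagged by topology, length and coverage", {
  # a clean linear graph has nothing to flag
  gen <- simulate_genome(400, 0, seed = 2)
  reads <- substring(gen$sequence, seq(1, 301, by = 10), seq(100, 400, by = 10))
  g <- build_graph(reads, 15)
  cp <- clean_params(85, cutoff = 10)
  expect_length(detect_erroneous_nodes(g, cp), 0L)

  # dead-end branch at coverage 1 off a main path at coverage 20: flagged
  locus <- substring(gen$sequence, 1, 200)
  tip_read <- paste0(substr(locus, 81, 160), "")
  substr(tip_read, 75, 80) <- "TTTTTT"   # corrupt the read end
  g_tip <- build_graph(c(rep(locus, 20), tip_read), 15)
  bad <- detect_erroneous_nodes(g_tip, cp)
  expect_gt(length(bad), 0L)
  expect_true(all(g_tip$nodes$avg_cov[bad] < 10))
  expect_true(all(g_tip$nodes$len[bad] < 85))

  # bubble: parallel branches at coverage 18 vs 2 -> low branch flagged only
  bub <- locus
  substr(bub, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                   substr(locus, 100, 100))[1]
  g_bub <- build_graph(c(rep(locus, 18), rep(bub, 2)), 15)
  bad2 <- detect_erroneous_nodes(g_bub, cp)
  expect_gt(length(bad2), 0L)
  expect_true(all(g_bub$nodes$avg_cov[bad2] <= 2))
  expect_false(any(g_bub$nodes$avg_cov[bad2] >= 18))
  # with the cutoff below both branches nothing is removed
  expect_length(detect_erroneous_nodes(g_bub, clean_params(85, cutoff = 1)), 0L)
})

test_that("multi-round cleaning removes planted errors and fixpoints on clean graphs", {
  gen <- simulate_genome(400, 0, seed = 4)
  locus <- substr(gen$sequence, 1, 200)
  cp <- clean_params(85, cutoff = 10)

  # error-free input is a fixpoint
  g0 <- build_graph(rep(locus, 20), 15)
  gc0 <- clean_graph(g0, cp)
  expect_equal(attr(gc0, "removed"), 0L)
  expect_equal(gc0$nodes$seq, g0$nodes$seq)

  # 20 clean copies + 1 read with an end substitution -> one clean unitig
  bad <- substr(locus, 1, 100)
  substr(bad, 95, 95) <- setdiff(c("A", "C", "G", "T"), substr(bad, 95, 95))[1]
  g1 <- build_graph(c(rep(locus, 20), bad), 15)
  expect_gt(nrow(g1$nodes), 1L)
  gc1 <- clean_graph(g1, cp)
  expect_equal(nrow(gc1$nodes), 1L)
  expect_true(gc1$nodes$seq %in% c(locus, rc_oracle(locus)))

  # nested artefacts: a mid-read substitution shared by two reads (a bubble
  # branch) with a second error on one of them (a tip off the bubble) resolve
  # over multiple rounds back to the clean unitig
  b1 <- locus
  substr(b1, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(locus, 100, 100))[1]
  b2 <- substr(b1, 41, 108)                       # truncated partner read
  substr(b2, 63, 63) <- setdiff(c("A", "C", "G", "T"), substr(b2, 63, 63))[1]
  g2 <- build_graph(c(rep(locus, 20), b1, b2), 15)
  gc2 <- clean_graph(g2, cp)
  expect_equal(nrow(gc2$nodes), 1L)
  expect_true(gc2$nodes$seq %in% c(locus, rc_oracle(locus)))
  expect_gte(attr(gc2, "rounds"), 2L)
})

test_that("GFA export lists unitigs and k-1 overlaps", {
  g <- build_graph(c("ACGGTAACGGCT", "CGGTAACGGCTT"), 5)
  f <- tempfile(fileext = ".gfa")
  export_gfa(g, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "S")), nrow(g$nodes))
  expect_equal(sum(startsWith(lines, "L")), nrow(g$node_arcs))
  expect_true(all(grepl("4M$", lines[startsWith(lines, "L")])))
})
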