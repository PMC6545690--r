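make_clean_graph <- function(locus, n = 10, k = 15) {
  clean_graph(build_graph(rep(locus, n), k),
              clean_params(nchar(locus) - k, cutoff = n / 2))
}

test_that("seeds are unique k-mers of trusted nodes, in read order", {
  gen <- simulate_genome(400, 0, seed = 21)
  locus <- substr(gen$sequence, 1, 200)
  g <- make_clean_graph(locus)

  # error-free read over a single unitig: one hit per window, collinear
  rd <- substr(locus, 50, 149)
  s <- find_seeds(rd, g)
  expect_equal(nrow(s), 100 - 15 + 1)
  expect_equal(s$read_offset, 0:85)
  expect_equal(length(unique(s$node)), 1L)
  expect_equal(length(unique(s$node_offset - s$read_offset)), 1L)

  # read from elsewhere: no seeds
  expect_equal(nrow(find_seeds(random_dna(1, 100, seed = 3), g)), 0L)

  # k-mers in a two-copy repeat unitig are rejected (coverage ~2x the rest)
  rep_seq <- random_dna(1, 60, seed = 8)
  genome2 <- paste0(random_dna(1, 150, seed = 9), rep_seq,
                    random_dna(1, 150, seed = 10), rep_seq,
                    random_dna(1, 150, seed = 12))
  starts <- seq(1, nchar(genome2) - 100, by = 5)
  g2 <- build_graph(substring(genome2, starts, starts + 99), 15)
  rd2 <- rep_seq  # a read consisting solely of the repeat
  s2 <- find_seeds(rd2, g2)
  expect_equal(nrow(s2), 0L)
  # flank-spanning reads still seed in their unique context
  rd3 <- substr(genome2, 120, 219)
  expect_gt(nrow(find_seeds(rd3, g2)), 0L)
})

test_that("seed-and-extend spells the read through the cleaned graph", {
  gen <- simulate_genome(500, 0, seed = 31)
  locus <- substr(gen$sequence, 1, 250)
  g <- make_clean_graph(locus)
  prm <- correct_params()

  # identity case
  rd <- substr(locus, 60, 159)
  res <- extend_alignment(rd, find_seeds(rd, g), g, prm)
  expect_equal(res$corrected_seq, rd)
  expect_equal(res$identity, 1)
  expect_equal(res$status, "corrected")
  # the graph-aligned span is spelled by the reported path
  spelled <- targetec:::spell_path(g, res$path)
  expect_true(grepl(substr(res$corrected_seq, res$graph_span[1], res$graph_span[2]),
                    spelled, fixed = TRUE) ||
              grepl(substr(res$corrected_seq, res$graph_span[1], res$graph_span[2]),
                    rc_oracle(spelled), fixed = TRUE))

  # one substitution is corrected back to the locus
  rd_err <- rd
  substr(rd_err, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(rd, 40, 40))[1]
  res2 <- extend_alignment(rd_err, find_seeds(rd_err, g), g, prm)
  expect_equal(res2$corrected_seq, rd)
  expect_equal(res2$status, "corrected")
})

test_that("extension follows the fork branch that matches the read flank", {
  set.seed(41)
  shared <- random_dna(1, 80)
  branch1 <- random_dna(1, 60); branch2 <- random_dna(1, 60)
  hap1 <- paste0(shared, branch1); hap2 <- paste0(shared, branch2)
  g <- build_graph(c(rep(hap1, 10), rep(hap2, 10)), 15)
  expect_gte(nrow(g$nodes), 3L)  # shared stem + two branches
  prm <- correct_params(repeat_cov_factor = 5)  # the stem carries 2x coverage

  # read: end of the shared stem + 12 bases of branch 1 with an error at the
  # first branch base, so every seed lies in the stem and the fork decision
  # is made by the flank alignment; the error base must differ from both
  # branches or the read would legitimately read as the other haplotype
  rd <- paste0(substr(shared, 41, 80), substr(branch1, 1, 12))
  truth <- rd
  substr(rd, 41, 41) <- setdiff(c("A", "C", "G", "T"),
                                c(substr(rd, 41, 41), substr(branch2, 1, 1)))[1]
  seeds <- find_seeds(rd, g, prm$repeat_cov_factor)
  expect_true(all(seeds$read_offset <= 40 - 15))
  res <- extend_alignment(rd, seeds, g, prm)
  expect_equal(res$corrected_seq, truth)
})

test_that("cluster correction is conservative, complete and idempotent", {
  gen <- simulate_genome(500, 0, seed = 51)
  locus <- substr(gen$sequence, 1, 250)
  g <- make_clean_graph(locus, n = 12)
  prm <- correct_params()

  # error-free cluster: all corrected, output multiset equals input
  starts <- seq(1, 150, by = 15)
  reads <- substring(locus, starts, starts + 99)
  res <- correct_cluster(reads, g, prm)
  expect_true(all(vapply(res, `[[`, "", "status") == "corrected"))
  expect_identical(sort(vapply(res, `[[`, "", "corrected_seq")), sort(reads))

  # idempotence: correcting the corrected reads changes nothing
  once <- vapply(res, `[[`, "", "corrected_seq")
  twice <- vapply(correct_cluster(once, g, prm), `[[`, "", "corrected_seq")
  expect_identical(twice, once)

  # a read from a different locus is never modified
  foreign <- random_dna(1, 100, seed = 99)
  resf <- correct_cluster(foreign, g, prm)[[1]]
  expect_equal(resf$status, "unaligned")
  expect_equal(resf$corrected_seq, foreign)
})

test_that("dense errors near the homopolymer are mostly removed at 30x", {
  # synthetic cluster: ~30x coverage of a homopolymer locus, reads with 3%
  # error near the run; of the planted errors inside reads the tool accepts
  # for correction, at least 90% must be removed
  set.seed(61)
  locus <- paste0(random_dna(1, 150), strrep("A", 20), random_dna(1, 150))
  starts <- rep(seq(41, 161, by = 4), each = 2)
  mutate <- function(s, e) {
    ch <- strsplit(s, "")[[1]]
    for (h in which(runif(length(ch)) < e))
      ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
    paste(ch, collapse = "")
  }
  truth_reads <- substring(locus, starts, starts + 99)
  reads <- vapply(truth_reads, mutate, "", e = 0.03, USE.NAMES = FALSE)
  g <- build_graph(reads, 15)
  cm <- tryCatch(fit_coverage_model(g$nodes$avg_cov, weight = g$nodes$len)$cutoff,
                 error = function(e) 1.5)
  gc_ <- clean_graph(g, clean_params(85, cm))
  # as in the pipeline: traversal restricted to nodes with >= 2 supporting
  # reads so a read cannot re-align to its own surviving errors
  res <- correct_cluster(reads, gc_, correct_params(min_node_cov = min(cm, 2)))
  corrected <- vapply(res, `[[`, "", "status") == "corrected"
  expect_gte(mean(corrected), 0.7)
  dist_to_truth <- function(x) adist(x, truth_reads[corrected])[cbind(seq_len(sum(corrected)),
                                                                      seq_len(sum(corrected)))]
  errs_before <- sum(dist_to_truth(reads[corrected]))
  errs_after <- sum(dist_to_truth(vapply(res[corrected], `[[`, "", "corrected_seq")))
  expect_gte((errs_before - errs_after) / errs_before, 0.9)
})
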