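test_that("2-bit k-mer encoding is the stated bijection", {
  expect_equal(encode_kmer("A"), 0)
  expect_equal(encode_kmer("C"), 1)
  expect_equal(encode_kmer("T"), 3)
  expect_equal(encode_kmer("ACGT"), 27)  # 0b00011011
  expect_error(encode_kmer("ACGN"), "encoding error")
  expect_error(encode_kmer(strrep("A", 27)), "k must be")

  # decode(encode(x)) == x for 10^4 random 15-mers; codes ordered like strings
  x <- random_dna(10000, 15, seed = 11)
  codes <- encode_kmer(x)
  expect_identical(decode_kmer(codes, 15), x)
  ord <- order(x)
  expect_equal(order(codes), ord)
})

test_that("repetitive pattern matching follows run-length semantics", {
  p <- repetitive_pattern("polyAT", 15)
  expect_true(matches_pattern(paste0("CG", strrep("A", 15), "CG"), p))
  expect_false(matches_pattern(paste0("CG", strrep("A", 14), "CG"), p))
  expect_true(matches_pattern(strrep("T", 20), p))   # "or longer", T-run
  expect_false(matches_pattern(strrep("C", 20), p))
  pc <- repetitive_pattern("polyCG", 15)
  expect_true(matches_pattern(strrep("G", 15), pc))
  # explicit pattern matches itself and its reverse complement
  pe <- repetitive_pattern("explicit", 5, explicit_seq = "ACGTC")
  expect_true(matches_pattern("TTACGTCTT", pe))
  expect_true(matches_pattern("TTGACGTTT", pe))  # rc(ACGTC) = GACGT
  expect_false(matches_pattern("TTTTTTTTT", pe))
  # N never matches
  expect_false(matches_pattern(paste0(strrep("A", 7), "N", strrep("A", 7)), p))
})

test_that("extract_pairs partitions the input exactly, in order", {
  p <- repetitive_pattern("polyAT", 15)
  run <- strrep("A", 16)
  set.seed(3)
  s1 <- random_dna(20, 60)
  s2 <- random_dna(20, 60)
  s2[c(4, 9)] <- paste0(substr(s2[c(4, 9)], 1, 30), run)  # match in r2 only
  pairs <- make_pairs(s1, s2)
  ex <- extract_pairs(pairs, p)
  expect_equal(ex$selected$ordinal, c(3L, 8L))   # whole pair selected
  expect_equal(nrow(ex$selected) + nrow(ex$passthrough), nrow(pairs))
  expect_equal(sort(c(ex$selected$ordinal, ex$passthrough$ordinal)),
               pairs$ordinal)
  # no match: everything passes through
  ex0 <- extract_pairs(make_pairs(s1, s1), p)
  expect_equal(nrow(ex0$selected), 0L)
  expect_equal(ex0$passthrough$ordinal, pairs$ordinal)
})

test_that("expected extracted coverage follows C_k = ((l-k+1)/l) C (1-e)^k", {
  expect_equal(expected_kmer_coverage(50, 100, 15, 0), 43)
  expect_equal(expected_kmer_coverage(33, 100, 15, 0.01),
               (100 - 15 + 1) / 100 * 33 * 0.99^15, tolerance = 1e-12)
  expect_equal(expected_kmer_coverage(30, 100, 100, 0), 30 / 100)  # k = l
  expect_error(expected_kmer_coverage(30, 100, 101, 0), "domain error")
  # monotone non-increasing in k and in e
  ks <- 1:50
  cks <- vapply(ks, function(k) expected_kmer_coverage(30, 100, k, 0.01), 1)
  expect_true(all(diff(cks) < 0))
  es <- seq(0, 0.2, by = 0.01)
  ces <- vapply(es, function(e) expected_kmer_coverage(30, 100, 15, e), 1)
  expect_true(all(diff(ces) < 0))
})

test_that("k-mer counting enumerates every ACGT window once", {
  kc <- count_kmers("ACGGT", 3, canonical = FALSE)
  expect_equal(kc$counts[c("ACG", "CGG", "GGT")], c(ACG = 1L, CGG = 1L, GGT = 1L))
  kc2 <- count_kmers(c("ACGGT", "CGGTA"), 3, canonical = FALSE)
  expect_equal(kc2$counts[c("CGG", "GGT", "ACG", "GTA")],
               c(CGG = 2L, GGT = 2L, ACG = 1L, GTA = 1L))
  # conservation: total count = sum(len - k + 1) over N-free reads
  set.seed(5)
  reads <- random_dna(25, 70)
  for (canon in c(TRUE, FALSE)) {
    kc3 <- count_kmers(reads, 15, canonical = canon)
    expect_equal(sum(kc3$counts), sum(nchar(reads) - 15 + 1))
  }
  # canonical merges reverse complements; windows with N are skipped
  kc4 <- count_kmers(c("ACG", "CGT"), 3, canonical = TRUE)
  expect_equal(kc4$counts, c(ACG = 2L))
  expect_equal(sum(count_kmers("ACNGT", 3)$counts), 0L)
})
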