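test_that("overlap alignment equals the brute-force suffix/prefix oracle", {
  ap <- align_params()
  expect_equal(overlap_align_score("TTTACG", "ACGGGG", ap), 3)
  expect_equal(overlap_align_score("AAAA", "TTTT", ap), 0)  # empty overlap wins
  x <- "ACGTACGT"
  expect_equal(overlap_align_score(x, x, ap), nchar(x) * ap$match)
  expect_error(overlap_align_score("", "ACGT", ap), "non-empty")

  # exhaustive over a 2-letter alphabet up to length 4, under two scoring
  # schemes (the full length-6 sweep runs in the acceptance suite)
  strs <- unlist(lapply(1:4, function(L)
    apply(expand.grid(rep(list(c("A", "T")), L)), 1, paste, collapse = "")))
  for (prm in list(c(1, -1, -3), c(2, -1, -1))) {
    p <- align_params(prm[1], prm[2], prm[3])
    for (a in strs) for (b in strs) {
      expect_equal(overlap_align_score(a, b, p),
                   oracle_overlap(a, b, prm[1], prm[2], prm[3]))
    }
  }
})

test_that("pair similarity is symmetric, rc-invariant and locus-discriminative", {
  ap <- align_params()
  set.seed(21)
  a1 <- random_dna(1, 100); a2 <- random_dna(1, 100)
  b1 <- random_dna(1, 100); b2 <- random_dna(1, 100)
  # identical pairs overlap fully with both mates
  expect_equal(pair_similarity(a1, a2, a1, a2, ap), 2 * 100 * ap$match)
  # symmetry and joint reverse-complement invariance
  s <- pair_similarity(a1, a2, b1, b2, ap)
  expect_equal(pair_similarity(b1, b2, a1, a2, ap), s)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  expect_equal(pair_similarity(rc(a1), rc(a2), rc(b1), rc(b2), ap), s)
  expect_equal(pair_similarity(rc(a2), rc(a1), rc(b2), rc(b1), ap), s)

  # pairs simulated from one locus at 1% error score above tau; pairs from
  # loci sharing only the homopolymer run score below tau
  set.seed(22)
  mutate <- function(s, e) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < e)
    for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
    paste(ch, collapse = "")
  }
  run <- strrep("A", 20)
  locus1 <- paste0(random_dna(1, 200), run, random_dna(1, 200))
  locus2 <- paste0(random_dna(1, 200), run, random_dna(1, 200))
  tau <- 40
  same_ok <- 0L; diff_ok <- 0L; n <- 40L
  for (i in seq_len(n)) {
    off <- sample(0:20, 4, replace = TRUE)
    mk <- function(locus, o) list(
      r1 = mutate(substr(locus, 160 + o, 259 + o), 0.01),
      r2 = mutate(rc(substr(locus, 310 + o, 409 + o)), 0.01))
    A <- mk(locus1, off[1]); B <- mk(locus1, off[2]); C <- mk(locus2, off[3])
    if (pair_similarity(A$r1, A$r2, B$r1, B$r2, ap) > tau) same_ok <- same_ok + 1L
    if (pair_similarity(A$r1, A$r2, C$r1, C$r2, ap) < tau) diff_ok <- diff_ok + 1L
  }
  expect_gte(same_ok / n, 0.95)
  expect_gte(diff_ok / n, 0.95)
})

test_that("similarity graph applies the non-repeated shared k-mer prefilter", {
  ap <- align_params()
  pat <- repetitive_pattern("polyAT", 15)
  run <- strrep("A", 20)
  set.seed(31)
  # two pairs sharing only the poly(A) run: no candidate, no edge
  p1 <- paste0(random_dna(1, 40), run, random_dna(1, 40))
  p2 <- paste0(random_dna(1, 40), run, random_dna(1, 40))
  sel <- make_pairs(c(p1, p2), random_dna(2, 100))
  g <- build_similarity_graph(sel, params = ap, pattern = pat)
  expect_equal(igraph::ecount(g), 0L)
  expect_equal(igraph::vcount(g), 2L)

  # two identical pairs sharing unique flanks: one maximal edge
  sel2 <- make_pairs(rep(p1, 2), rep(p2, 2))
  g2 <- build_similarity_graph(sel2, params = ap, pattern = pat)
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$weight, 2 * 100 * ap$match)

  # simulated 3-locus dataset: cores are homogeneous (fraction of pairs from
  # the majority locus >= 0.9)
  gen <- simulate_genome(6000, 3, c(15, 25), seed = 5)
  sim <- simulate_reads(gen, coverage = 30, read_len = 100, insert_mean = 250,
                        insert_sd = 15, error_rate = 0.001, hotspot_mult = 10,
                        seed = 5)
  ex <- extract_pairs(sim$pairs, pat)
  g3 <- build_similarity_graph(ex$selected, params = ap, pattern = pat)
  sc <- stable_cores(g3, n_runs = 5, theta = 0.8, seed = 2)
  pair_locus <- tapply(sim$truth$locus, sim$truth$ordinal,
                       function(x) if (all(is.na(x))) NA else x[!is.na(x)][1])
  for (core in sc$cores) {
    if (length(core) < 3) next
    l <- pair_locus[core]
    expect_gte(max(table(l)) / length(l), 0.9)
  }
})

test_that("louvain maximises weighted modularity deterministically", {
  # edgeless graph: all singletons
  g0 <- igraph::set_vertex_attr(igraph::make_empty_graph(4, directed = FALSE),
                                "name", value = as.character(1:4))
  expect_equal(length(unique(louvain(g0, 1)$membership)), 4L)

  # two bridged 5-cliques: exactly the cliques (exhaustive optimum is checked
  # in the acceptance suite)
  g <- two_clique_graph()
  p <- louvain(g, seed = 3)
  expect_equal(length(unique(p$membership)), 2L)
  expect_equal(length(unique(p$membership[1:5])), 1L)
  expect_equal(length(unique(p$membership[6:10])), 1L)
  # modularity of the result beats the singleton partition
  m_single <- igraph::modularity(g, seq_len(10), weights = igraph::E(g)$weight)
  expect_gt(p$modularity, m_single)
  # deterministic given the seed
  expect_identical(louvain(g, seed = 99)$membership, louvain(g, seed = 99)$membership)
})

test_that("stable cores aggregate co-clustering across runs", {
  g <- two_clique_graph()
  # n_runs = 1: cores equal the single partition, nothing unassigned
  sc1 <- stable_cores(g, n_runs = 1, theta = 0.8, seed = 5)
  expect_equal(length(sc1$unassigned), 0L)
  expect_equal(sort(lengths(sc1$cores)), c(5L, 5L))

  # stable structure across 20 seeds
  sc <- stable_cores(g, n_runs = 20, theta = 0.8, seed = 1)
  expect_equal(length(sc$cores), 2L)
  expect_setequal(sc$cores[[1]], as.character(0:4))
  expect_setequal(sc$cores[[2]], as.character(5:9))
  expect_equal(length(sc$unassigned), 0L)

  # a node tied equally to two cliques flips between runs: unassigned at
  # theta = 0.9 while the cliques remain stable cores
  ga <- ambivalent_graph()
  sca <- stable_cores(ga, n_runs = 20, theta = 0.9, seed = 1)
  expect_true("10" %in% sca$unassigned)
  expect_equal(sort(lengths(sca$cores)), c(5L, 5L))
})

test_that("edge-list and cluster-map exports are valid TSV", {
  g <- two_clique_graph()
  f <- tempfile(fileext = ".tsv")
  export_edge_list(g, f)
  el <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(el), igraph::ecount(g))
  sc <- stable_cores(g, n_runs = 3, theta = 0.8, seed = 1)
  f2 <- tempfile(fileext = ".tsv")
  export_cluster_map(sc, f2)
  cm <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(sort(as.character(cm$ordinal)), sort(igraph::V(g)$name))
})
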