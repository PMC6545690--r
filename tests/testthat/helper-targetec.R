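# ---- independent alignment oracles (pure R, textbook recurrences) ----

# last row of a global Needleman-Wunsch DP of a vs b: entry j+1 equals the
# global alignment score of a against the prefix b[1..j]
nw_last_row <- function(a, b, match, mismatch, gap) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- (0:m) * gap
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L); cur[1L] <- i * gap
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + if (av[i] == bv[j]) match else mismatch,
                         prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev
}

# brute-force overlap score: enumerate every suffix of one sequence against
# every prefix of the other (both directions), global-align each, keep the max
# (>= 0, the empty overlap)
oracle_overlap <- function(a, b, match, mismatch, gap) {
  best <- 0
  for (x in list(c(a, b), c(b, a))) {
    for (i in 0:(nchar(x[1]) - 1L)) {
      suf <- substring(x[1], i + 1L)
      best <- max(best, max(nw_last_row(suf, x[2], match, mismatch, gap)))
    }
  }
  best
}

rc_oracle <- function(x) chartr("ACGTN", "TGCAN",
                                vapply(strsplit(x, ""), function(v)
                                  paste(rev(v), collapse = ""), character(1)))

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# quick read_pairs builder from two sequence vectors
make_pairs <- function(seq1, seq2, qual_char = "I") {
  read_pairs(sprintf("p%d/1", seq_along(seq1)), seq1,
             strrep(qual_char, nchar(seq1)),
             sprintf("p%d/2", seq_along(seq1)), seq2,
             strrep(qual_char, nchar(seq2)))
}

# ---- igraph fixtures ----

two_clique_graph <- function(bridge = TRUE) {
  el <- cbind(utils::combn(1:5, 2), utils::combn(6:10, 2))
  g <- igraph::make_empty_graph(10, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  if (bridge) g <- igraph::add_edges(g, c(5, 6))
  g <- igraph::set_vertex_attr(g, "name", value = as.character(0:9))
  igraph::E(g)$weight <- 1
  g
}

# two 5-cliques plus one node tied equally to both: its community flips
# between Louvain runs
ambivalent_graph <- function() {
  el <- cbind(utils::combn(1:5, 2), utils::combn(6:10, 2))
  g <- igraph::make_empty_graph(11, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  g <- igraph::add_edges(g, c(11, 1, 11, 2, 11, 6, 11, 7))
  g <- igraph::set_vertex_attr(g, "name", value = as.character(0:10))
  igraph::E(g)$weight <- 1
  g
}

# ---- shared end-to-end benchmark (built once per test run) ----

.bench <- new.env()

default_benchmark <- function() {
  if (is.null(.bench$report)) {
    .bench$genome <- simulate_genome(10000, 5, c(15, 25), seed = 1)
    .bench$sim <- simulate_reads(.bench$genome, coverage = 30, read_len = 100,
                                 insert_mean = 250, insert_sd = 15,
                                 error_rate = 0.01, hotspot_mult = 10, seed = 1)
    .bench$cfg <- pipeline_config(seed = 1)
    .bench$report <- run_correct(.bench$cfg, pairs = .bench$sim$pairs)
  }
  .bench
}
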