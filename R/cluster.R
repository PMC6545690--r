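#' Alignment scoring parameters for read-pair similarity
#'
#' Defaults favour a confident overlap of at least ~40 bp for 100 bp reads:
#' match +1, mismatch -1, linear gap -3, and an edge threshold `tau` of
#' `0.4 * l` (computed from the read length when left `NULL`).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap per-base gap score (<= 0).
#' @param tau minimum combined similarity for a graph edge (> 0), or `NULL`
#'   to derive `0.4 * read length` at graph-build time.
#' @return an object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap = -3, tau = NULL) {
  stopifnot(match > 0, mismatch <= 0, gap <= 0)
  if (!is.null(tau) && tau <= 0) stop("tau must be positive")
  structure(list(match = match, mismatch = mismatch, gap = gap, tau = tau),
            class = "align_params")
}

#' Overlap alignment score with free end gaps
#'
#' The highest global alignment score between a suffix of one sequence and a
#' prefix of the other (both directions considered), with the empty overlap
#' scoring 0; leading and trailing gaps are therefore never penalised and the
#' score is always non-negative.
#'
#' @param a,b sequences (ACGTN strings); `N` scores as a mismatch against
#'   everything.
#' @param params an [align_params()].
#' @return the overlap alignment score.
#' @export
overlap_align_score <- function(a, b, params = align_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  .overlap_score_cpp(a, b, params$match, params$mismatch, params$gap)
}

#' Similarity between two read pairs
#'
#' Combines the overlap alignment of the anchor reads with the overlap
#' alignment of their mates, maximised over the two possible mate matchings
#' and over reverse-complementing pair `B` as a unit.  The score is symmetric
#' and invariant under jointly reverse-complementing both pairs.
#'
#' @param a1,a2 the two reads of pair A.
#' @param b1,b2 the two reads of pair B.
#' @param params an [align_params()].
#' @return the similarity score (>= 0).
#' @export
pair_similarity <- function(a1, a2, b1, b2, params = align_params()) {
  rb1 <- rc_chr(b1); rb2 <- rc_chr(b2)
  ov <- function(x, y) .overlap_score_cpp(x, y, params$match, params$mismatch, params$gap)
  max(ov(a1, b1) + ov(a2, b2),
      ov(a1, b2) + ov(a2, b1),
      ov(a1, rb1) + ov(a2, rb2),
      ov(a1, rb2) + ov(a2, rb1))
}

# candidate k-mers of one pair: canonical cluster-k k-mers from both mates,
# excluding windows that overlap a repetitive-pattern run in their read
candidate_kmers <- function(seq1, seq2, k, pattern) {
  one <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    w <- substring(s, 1:n, k:nchar(s))
    keep <- !grepl("[^ACGT]", w)
    runs <- pattern_runs(s, pattern)
    if (!is.null(runs)) {
      starts <- 1:n
      ends <- starts + k - 1L
      for (r in seq_len(nrow(runs)))
        keep <- keep & (ends < runs[r, "start"] | starts > runs[r, "end"])
    }
    w[keep]
  }
  w <- c(one(seq1), one(seq2))
  unique(pmin(w, rc_chr(w)))
}

#' Build the read-pair similarity graph
#'
#' Nodes are the ordinals of the extracted pairs.  To avoid an all-vs-all
#' quadratic comparison, alignment scores are only computed between pairs that
#' share at least one non-repeated k-mer: a k-mer whose dataset count is at
#' most `beta * C_k` (about the expected single-locus coverage) and that does
#' not overlap the repetitive-pattern run itself.  An edge is created when
#' [pair_similarity()] reaches `tau`, so the graph is generally very sparse.
#'
#' @param selected extracted `read_pairs` table.
#' @param counts a [count_kmers()] table built from the selected reads at the
#'   clustering k (computed here when `NULL`).
#' @param ck expected per-locus coverage `C_k`; when `NULL`, estimated as the
#'   median count of k-mers seen at least twice.
#' @param params an [align_params()]; a `NULL` `tau` becomes 0.4 x median read
#'   length.
#' @param pattern the [repetitive_pattern()] used for extraction.
#' @param cluster_k k-mer size for the shared-k-mer prefilter (default 15).
#' @param beta multiplier defining "about `C_k`" (default 2).
#' @return an [igraph::graph] with vertex attribute `name` = pair ordinal and
#'   edge attribute `weight` = similarity score.
#' @export
build_similarity_graph <- function(selected, counts = NULL, ck = NULL,
                                   params = align_params(),
                                   pattern = repetitive_pattern(),
                                   cluster_k = 15L, beta = 2) {
  stopifnot(inherits(selected, "read_pairs"))
  n <- nrow(selected)
  tau <- params$tau %||% (0.4 * median(nchar(c(selected$seq1, selected$seq2))))
  g_empty <- igraph::make_empty_graph(n = n, directed = FALSE)
  g_empty <- igraph::set_vertex_attr(g_empty, "name",
                                     value = as.character(selected$ordinal))
  if (n < 2L) return(g_empty)
  if (is.null(counts))
    counts <- count_kmers(c(selected$seq1, selected$seq2), cluster_k,
                          canonical = TRUE)
  stopifnot(inherits(counts, "kmer_counts"), counts$canonical)
  if (is.null(ck)) {
    reps <- counts$counts[counts$counts >= 2L]
    ck <- if (length(reps)) median(reps) else 1
  }
  if (ck <= 0) stop("parameter error: C_k must be positive")
  maxcount <- beta * ck

  # inverted index: eligible k-mer -> pair row indices
  cand <- lapply(seq_len(n), function(i) {
    km <- candidate_kmers(selected$seq1[i], selected$seq2[i], counts$k, pattern)
    km[counts$counts[km] <= maxcount & !is.na(counts$counts[km])]
  })
  idx <- split(rep(seq_len(n), lengths(cand)), unlist(cand, use.names = FALSE))
  pairs_seen <- new.env(hash = TRUE)
  edges <- list(); weights <- numeric(0)
  for (members in idx) {
    members <- unique(members)
    if (length(members) < 2L) next
    cmb <- utils::combn(members, 2L)
    for (ci in seq_len(ncol(cmb))) {
      i <- cmb[1L, ci]; j <- cmb[2L, ci]
      key <- paste0(i, "_", j)
      if (!is.null(pairs_seen[[key]])) next
      pairs_seen[[key]] <- TRUE
      s <- pair_similarity(selected$seq1[i], selected$seq2[i],
                           selected$seq1[j], selected$seq2[j], params)
      if (s >= tau) {
        edges[[length(edges) + 1L]] <- c(i, j)
        weights <- c(weights, s)
      }
    }
  }
  if (!length(edges)) return(g_empty)
  g <- igraph::add_edges(g_empty, as.vector(t(do.call(rbind, edges))))
  igraph::E(g)$weight <- weights
  g
}

#' Louvain community detection on a similarity graph
#'
#' Greedy weighted-modularity maximisation (multi-level/Louvain).  The vertex
#' visiting order is randomised from `seed`, so results are deterministic for
#' a given seed while different seeds probe the algorithm's intrinsic
#' instability.
#'
#' @param g an igraph similarity graph with edge `weight`s.
#' @param seed integer RNG seed.
#' @return `list(membership = named integer vector, modularity = numeric)`.
#' @export
louvain <- function(g, seed = 1L) {
  stopifnot(igraph::vcount(g) > 0)
  set.seed(seed)
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp,
                                weights = if (igraph::ecount(gp)) igraph::E(gp)$weight else NULL)
  memb <- igraph::membership(cl)[perm]  # back to original vertex order
  names(memb) <- igraph::V(g)$name
  mod <- igraph::modularity(g, memb,
                            weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL)
  list(membership = memb, modularity = mod)
}

#' Stable core communities across repeated Louvain runs
#'
#' Louvain is non-deterministic; to obtain robust clusters the partitioning is
#' repeated `n_runs` times with distinct seeds and two nodes are placed in the
#' same core iff they are co-clustered in at least `theta * n_runs` runs.
#' Cores are the connected components of that co-clustering relation.  A node
#' that stably meets the threshold with no other node is kept as a singleton
#' core only if it was a singleton community in at least `theta * n_runs`
#' runs (it stably clusters alone); otherwise it is unassigned.
#'
#' @param g an igraph similarity graph.
#' @param n_runs number of Louvain runs (default 20).
#' @param theta co-clustering threshold in (0, 1] (default 0.8).
#' @param seed master seed; per-run seeds are derived from it.
#' @return `list(cores = list of ordinal character vectors, unassigned =
#'   character vector, n_runs, theta)`.
#' @export
stable_cores <- function(g, n_runs = 20L, theta = 0.8, seed = 1L) {
  stopifnot(n_runs >= 1L, theta > 0, theta <= 1)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 0L) return(list(cores = list(), unassigned = character(0),
                           n_runs = n_runs, theta = theta))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  co <- matrix(0L, n, n)
  alone <- integer(n)
  for (r in seq_len(n_runs)) {
    memb <- louvain(g, seed = run_seeds[r])$membership
    ind <- outer(memb, memb, "==")
    co <- co + ind
    sizes <- table(memb)
    alone <- alone + (sizes[as.character(memb)] == 1L)
  }
  need <- theta * n_runs
  adj <- (co >= need)
  diag(adj) <- FALSE
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(cg)$membership
  cores <- split(nm, comp)
  keep <- vapply(cores, function(members) {
    if (length(members) > 1L) return(TRUE)
    alone[match(members, nm)] >= need
  }, logical(1))
  unassigned <- unlist(cores[!keep], use.names = FALSE)
  list(cores = unname(cores[keep]),
       unassigned = as.character(unassigned %||% character(0)),
       n_runs = n_runs, theta = theta)
}

#' Export similarity-graph edges or cluster assignments
#'
#' Debug helpers: tab-separated `node_a  node_b  weight`, and
#' `ordinal  cluster_id` (cluster 0 = unassigned).
#'
#' @param g an igraph similarity graph.
#' @param cores output of [stable_cores()].
#' @param path output file.
#' @export
export_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_edge_list
#' @export
export_cluster_map <- function(cores, path) {
  df <- data.frame(
    ordinal = c(unlist(cores$cores, use.names = FALSE), cores$unassigned),
    cluster_id = c(rep(seq_along(cores$cores), lengths(cores$cores)),
                   rep(0L, length(cores$unassigned))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
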