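#' Per-cluster de Bruijn graph
#'
#' Nodes are unitigs: maximal non-branching paths of canonical (strand-merged)
#' k-mers contracted into single sequences, each carrying its length in k-mers
#' and its average k-mer coverage.  Arcs join unitig ends that overlap by
#' exactly k-1 bases, as observed consecutively in the reads; the double
#' strand is represented by orienting every node as `+` (stored sequence) or
#' `-` (its reverse complement).  Requires odd `k` so no k-mer equals its own
#' reverse complement.
#'
#' @param reads character vector of read sequences.
#' @param k odd k-mer size (<= 26, <= min read length).
#' @return an object of class `dbg` with elements `k`, `counts` (canonical
#'   k-mer counts), `arcs_kmer`, `nodes` (data.frame `id`, `seq`, `len`,
#'   `avg_cov`), `node_arcs` (oriented unitig adjacency) and a k-mer position
#'   index.
#' @export
build_graph <- function(reads, k) {
  if (!length(reads)) stop("reads must be non-empty")
  if (k > min(nchar(reads))) stop("parameter error: k exceeds the read length")
  if (k %% 2L == 0L) stop("k must be odd (canonical double-strand graph)")
  if (k > 26L) stop("k must be <= 26")
  wlist <- lapply(reads, function(s) {
    n <- nchar(s) - k + 1L
    w <- substring(s, 1:n, k:nchar(s))
    w[grepl("[^ACGT]", w)] <- NA_character_
    w
  })
  w_all <- unlist(wlist, use.names = FALSE)
  w_all <- w_all[!is.na(w_all)]
  if (!length(w_all)) stop("no valid k-mers in input")
  canon <- pmin(w_all, rc_chr(w_all))
  tb <- table(canon)
  counts <- as.integer(tb)
  names(counts) <- names(tb)

  # oriented arcs from consecutive valid windows, plus their rc mirrors
  froms <- character(0); tos <- character(0)
  for (w in wlist) {
    if (length(w) < 2L) next
    a <- w[-length(w)]; b <- w[-1L]
    ok <- !is.na(a) & !is.na(b)
    froms <- c(froms, a[ok]); tos <- c(tos, b[ok])
  }
  if (length(froms)) {
    key <- paste(froms, tos)
    dup <- duplicated(key)
    froms <- froms[!dup]; tos <- tos[!dup]
    rf <- rc_chr(tos); rt <- rc_chr(froms)
    key2 <- paste(rf, rt)
    new <- !(key2 %in% paste(froms, tos))
    froms <- c(froms, rf[new]); tos <- c(tos, rt[new])
  }
  arcs <- data.frame(from = froms, to = tos, stringsAsFactors = FALSE)
  contract_kmers(counts, arcs, k)
}

# contract a canonical k-mer count table + oriented arc list into a dbg object
contract_kmers <- function(counts, arcs, k) {
  kms <- names(counts)
  universe <- unique(c(kms, rc_chr(kms)))
  rc_map <- setNames(c(rc_chr(kms), kms), c(kms, rc_chr(kms)))
  out_adj <- split(arcs$to, factor(arcs$from, levels = universe))
  in_deg_tb <- table(factor(arcs$to, levels = universe))
  in_deg <- setNames(as.integer(in_deg_tb), universe)
  out_deg <- setNames(lengths(out_adj), universe)

  single_pred <- rep(NA_character_, length(universe))
  names(single_pred) <- universe
  if (nrow(arcs)) {
    sel <- in_deg[arcs$to] == 1L
    single_pred[arcs$to[sel]] <- arcs$from[sel]
  }
  is_start <- in_deg != 1L |
    ifelse(is.na(single_pred), TRUE, out_deg[single_pred] != 1L)

  # Each unitig is discovered once, in one arbitrary orientation: visiting a
  # k-mer marks its reverse complement too, which also terminates walks that
  # would re-enter their own mirror (reverse-complement-palindromic unitigs).
  visited <- new.env(hash = TRUE, size = 2L * length(universe))
  walk <- function(v) {
    path <- character(64); path[1L] <- v; np <- 1L
    visited[[v]] <- TRUE; visited[[rc_map[[v]]]] <- TRUE
    cur <- v
    repeat {
      outs <- out_adj[[cur]]
      if (length(outs) != 1L) break
      w <- outs
      if (in_deg[[w]] != 1L) break
      if (!is.null(visited[[w]])) break  # cycle or mirror closure
      np <- np + 1L
      if (np > length(path)) path <- c(path, character(length(path)))
      path[np] <- w
      visited[[w]] <- TRUE; visited[[rc_map[[w]]]] <- TRUE
      cur <- w
    }
    path[seq_len(np)]
  }
  paths <- list()
  for (v in universe[is_start]) {
    if (is.null(visited[[v]])) paths[[length(paths) + 1L]] <- walk(v)
  }
  for (v in universe) {  # remaining: pure cycles
    if (is.null(visited[[v]])) paths[[length(paths) + 1L]] <- walk(v)
  }

  spell <- vapply(paths, function(p) {
    if (length(p) == 1L) return(p)
    paste0(p[1L], paste(substring(p[-1L], k, k), collapse = ""))
  }, character(1))
  seqs <- pmin(spell, rc_chr(spell))
  kpaths <- paths
  # per-node stats on canonical counts
  stats <- vapply(kpaths, function(p) {
    cc <- counts[pmin(p, rc_chr(p))]
    c(length(p), mean(cc))
  }, numeric(2))
  nodes <- data.frame(id = seq_along(seqs), seq = seqs,
                      len = as.integer(stats[1L, ]), avg_cov = stats[2L, ],
                      stringsAsFactors = FALSE)

  # oriented k-mer position index: kmer -> (id, strand, offset)
  index <- new.env(hash = TRUE, size = 2L * sum(nodes$len) + 1L)
  add_hits <- function(seq, id, strand) {
    n <- nchar(seq) - k + 1L
    w <- substring(seq, 1:n, k:nchar(seq))
    for (i in seq_len(n)) {
      key <- w[i]
      hit <- list(id = id, strand = strand, offset = i)
      cur <- index[[key]]
      index[[key]] <- if (is.null(cur)) list(hit) else c(cur, list(hit))
    }
  }
  for (i in seq_len(nrow(nodes))) {
    add_hits(nodes$seq[i], i, "+")
    rcs <- rc_chr(nodes$seq[i])
    if (rcs != nodes$seq[i]) add_hits(rcs, i, "-")
  }

  # unitig-level arcs: last k-mer of each oriented node -> first k-mer of next
  na_from <- integer(0); na_fs <- character(0)
  na_to <- integer(0); na_ts <- character(0)
  for (i in seq_len(nrow(nodes))) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") nodes$seq[i] else rc_chr(nodes$seq[i])
      last <- substring(s, nchar(s) - k + 1L, nchar(s))
      for (w in out_adj[[last]] %||% character(0)) {
        for (hit in index[[w]] %||% list()) {
          if (hit$offset == 1L) {
            na_from <- c(na_from, i); na_fs <- c(na_fs, strand)
            na_to <- c(na_to, hit$id); na_ts <- c(na_ts, hit$strand)
          }
        }
      }
    }
  }
  node_arcs <- unique(data.frame(from = na_from, from_strand = na_fs,
                                 to = na_to, to_strand = na_ts,
                                 stringsAsFactors = FALSE))
  structure(list(k = as.integer(k), counts = counts, arcs_kmer = arcs,
                 nodes = nodes, node_arcs = node_arcs, index = index),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k = %d, %d unitigs, %d arcs, %d k-mers (%d occurrences)\n",
              x$k, nrow(x$nodes), nrow(x$node_arcs), length(x$counts),
              sum(x$counts)))
  invisible(x)
}

oriented_seq <- function(g, id, strand) {
  if (strand == "+") g$nodes$seq[id] else rc_chr(g$nodes$seq[id])
}

# out-degree of the oriented node end reached by leaving (id, strand)
arcs_from <- function(g, id, strand) {
  sel <- g$node_arcs$from == id & g$node_arcs$from_strand == strand
  g$node_arcs[sel, , drop = FALSE]
}

#' Tip and bubble detection under a coverage cutoff
#'
#' Flags unitigs that are tips (one dead end with an attachment on the other
#' side) or low-coverage bubble branches (a single-node path parallel to a
#' higher-coverage single-node path joining the same two oriented node ends),
#' provided their length in k-mers is below `max_error_node_len` and their
#' average coverage is below `cutoff`.
#'
#' @param g a [build_graph()] object.
#' @param params a [clean_params()].
#' @return integer vector of flagged node ids (possibly empty).
#' @export
detect_erroneous_nodes <- function(g, params) {
  stopifnot(inherits(g, "dbg"), inherits(params, "clean_params"))
  n <- nrow(g$nodes)
  if (n == 0L) return(integer(0))
  deg_right <- integer(n); deg_left <- integer(n)
  if (nrow(g$node_arcs)) {
    tb_r <- table(factor(g$node_arcs$from[g$node_arcs$from_strand == "+"], levels = 1:n))
    tb_l <- table(factor(g$node_arcs$from[g$node_arcs$from_strand == "-"], levels = 1:n))
    deg_right <- as.integer(tb_r); deg_left <- as.integer(tb_l)
  }
  # A dead end is only an erroneous tip when the junction it hangs off offers
  # a strictly higher-coverage alternative branch; a dead end that merely
  # terminates a linear path (no competing sibling) is true sequence ending
  # where read coverage ends and must never be clipped.
  dead <- xor(deg_left == 0L, deg_right == 0L)
  tip <- logical(n)
  for (i in which(dead)) {
    att_strand <- if (deg_right[i] == 0L) "-" else "+"
    att <- arcs_from(g, i, att_strand)
    dominated <- FALSE
    for (a in seq_len(nrow(att))) {
      sib <- g$node_arcs$to == att$to[a] & g$node_arcs$to_strand == att$to_strand[a] &
        g$node_arcs$from != i
      if (any(sib) && max(g$nodes$avg_cov[g$node_arcs$from[sib]]) >= g$nodes$avg_cov[i])
        dominated <- TRUE
    }
    tip[i] <- dominated
  }

  # A bubble branch is a single-in/single-out node that converges, on both
  # sides, into junctions where a strictly higher-coverage sibling branch
  # also converges: a redundant parallel path dominated by the main path.
  # (The main path between the junctions may itself consist of several
  # nodes.)  Coverage ties are kept -- conservative.
  dominated_at <- function(i, strand) {
    att <- arcs_from(g, i, strand)
    for (a in seq_len(nrow(att))) {
      if (att$to[a] == i) return(FALSE)  # self-attached
      sib <- g$node_arcs$to == att$to[a] & g$node_arcs$to_strand == att$to_strand[a] &
        g$node_arcs$from != i
      if (any(sib) && max(g$nodes$avg_cov[g$node_arcs$from[sib]]) > g$nodes$avg_cov[i])
        return(TRUE)
    }
    FALSE
  }
  bubble <- logical(n)
  for (i in which(deg_left == 1L & deg_right == 1L)) {
    bubble[i] <- dominated_at(i, "-") && dominated_at(i, "+")
  }
  flagged <- (tip | bubble) &
    g$nodes$len < params$max_error_node_len &
    g$nodes$avg_cov < params$cutoff
  which(flagged)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Graph-cleaning parameters
#'
#' @param max_error_node_len maximum length (in k-mers) of a removable node;
#'   the pipeline sets it to `avgReadLen - k`.
#' @param cutoff coverage threshold below which flagged nodes are removed,
#'   typically from [fit_coverage_model()].
#' @param max_rounds maximum detect/remove/re-contract iterations (default 10).
#' @return an object of class `clean_params`.
#' @export
clean_params <- function(max_error_node_len, cutoff, max_rounds = 10L) {
  stopifnot(max_error_node_len >= 1)
  structure(list(max_error_node_len = max_error_node_len,
                 cutoff = cutoff, max_rounds = as.integer(max_rounds)),
            class = "clean_params")
}

#' Conservative multi-round graph cleaning
#'
#' Iterates [detect_erroneous_nodes()], removal and re-contraction until no
#' node is flagged or `max_rounds` is reached.  Only nodes passing both the
#' length and the coverage threshold are ever removed, so an error-free graph
#' is a fixpoint.
#'
#' @inheritParams detect_erroneous_nodes
#' @return a cleaned `dbg`, with attributes `rounds` and `removed` (number of
#'   unitigs removed).
#' @export
clean_graph <- function(g, params) {
  stopifnot(inherits(g, "dbg"))
  removed_total <- 0L
  rounds <- 0L
  while (rounds < params$max_rounds) {
    bad <- detect_erroneous_nodes(g, params)
    if (!length(bad)) break
    rounds <- rounds + 1L
    removed_total <- removed_total + length(bad)
    # drop all k-mers of the flagged unitigs, then re-contract
    bad_kmers <- unlist(lapply(bad, function(i) {
      s <- g$nodes$seq[i]
      n <- nchar(s) - g$k + 1L
      substring(s, 1:n, g$k:nchar(s))
    }), use.names = FALSE)
    bad_oriented <- unique(c(bad_kmers, rc_chr(bad_kmers)))
    counts <- g$counts[!(names(g$counts) %in% bad_oriented)]
    arcs <- g$arcs_kmer[!(g$arcs_kmer$from %in% bad_oriented |
                            g$arcs_kmer$to %in% bad_oriented), , drop = FALSE]
    if (!length(counts)) {
      g <- structure(list(k = g$k, counts = counts, arcs_kmer = arcs,
                          nodes = g$nodes[0, ], node_arcs = g$node_arcs[0, ],
                          index = new.env()), class = "dbg")
      break
    }
    g <- contract_kmers(counts, arcs, g$k)
  }
  attr(g, "rounds") <- rounds
  attr(g, "removed") <- removed_total
  g
}

#' Export a de Bruijn graph as GFA1
#'
#' Segments are unitigs with `LN`/`KC` tags (length, k-mer count), links are
#' the k-1 base overlaps.
#'
#' @param g a `dbg`.
#' @param path output file.
#' @export
export_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(g$nodes))) {
    writeLines(sprintf("S\t%d\t%s\tLN:i:%d\tKC:i:%d", i, g$nodes$seq[i],
                       nchar(g$nodes$seq[i]),
                       round(g$nodes$len[i] * g$nodes$avg_cov[i])), con)
  }
  if (nrow(g$node_arcs)) {
    a <- g$node_arcs
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                       a$from, a$from_strand, a$to, a$to_strand, g$k - 1L), con)
  }
  invisible(path)
}
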