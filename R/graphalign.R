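#' Parameters for read-to-graph correction
#'
#' @param match,mismatch,gap alignment scores for the flank extension search.
#' @param min_identity minimum identity (matches / alignment columns) between
#'   the read and its graph-spelled correction for the correction to be
#'   accepted; below it the read passes through unchanged (default 0.8).
#' @param max_branch maximum depth-first-search node visits per read side;
#'   on abort the read is left unchanged (default 1000).
#' @param repeat_cov_factor seeds inside unitigs whose coverage exceeds this
#'   multiple of the length-weighted median node coverage are rejected as
#'   repeat-derived (default 1.75).
#' @param flank_identity minimum identity over the aligned columns for a read
#'   flank to be replaced by its graph spelling (default 0.8); a flank below
#'   it passes through verbatim.
#' @param min_node_cov only nodes with at least this average coverage carry
#'   seeds or are traversed during extension, so a read cannot re-align to a
#'   surviving low-coverage copy of its own errors; the pipeline sets it to
#'   each cluster's fitted coverage cutoff (default 0 = no restriction).
#' @return an object of class `correct_params`.
#' @export
correct_params <- function(match = 1, mismatch = -1, gap = -3,
                           min_identity = 0.8, max_branch = 1000L,
                           repeat_cov_factor = 1.75, flank_identity = 0.8,
                           min_node_cov = 0) {
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 min_identity = min_identity, max_branch = as.integer(max_branch),
                 repeat_cov_factor = repeat_cov_factor,
                 flank_identity = flank_identity, min_node_cov = min_node_cov),
            class = "correct_params")
}

# occurrence-weighted median node coverage of a dbg: the coverage of the
# typical k-mer occurrence.  Weighting by len x avg_cov (not just length)
# keeps the estimate anchored on true nodes even when numerous coverage-1
# error unitigs rival the true path in total length.
weighted_median_cov <- function(g) {
  if (!nrow(g$nodes)) return(NA_real_)
  median(rep(g$nodes$avg_cov, pmax(1L, round(g$nodes$len * g$nodes$avg_cov))))
}

#' Find unique k-mer seeds of a read in a de Bruijn graph
#'
#' Each read k-mer that occurs at exactly one position in the graph (over both
#' strands) and whose unitig does not look repeat-derived (coverage above
#' `repeat_cov_factor` times the length-weighted median) yields a seed that
#' uniquely maps the read onto a node.
#'
#' @param read a read sequence.
#' @param g a cleaned [build_graph()] object.
#' @param repeat_cov_factor see [correct_params()].
#' @param min_node_cov see [correct_params()].
#' @return data.frame with 0-based `read_offset`, `node`, `node_offset`,
#'   `strand`; zero rows when the read has no unique k-mer.
#' @export
find_seeds <- function(read, g, repeat_cov_factor = 1.75, min_node_cov = 0) {
  empty <- data.frame(read_offset = integer(0), node = integer(0),
                      node_offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  k <- g$k
  n <- nchar(read) - k + 1L
  if (n < 1L || !nrow(g$nodes)) return(empty)
  w <- substring(read, 1:n, k:nchar(read))
  medcov <- weighted_median_cov(g)
  maxcov <- repeat_cov_factor * medcov
  ro <- integer(0); nd <- integer(0); no <- integer(0); st <- character(0)
  for (i in seq_len(n)) {
    if (grepl("[^ACGT]", w[i])) next
    hits <- g$index[[w[i]]]
    if (is.null(hits) || length(hits) != 1L) next
    h <- hits[[1L]]
    if (g$nodes$avg_cov[h$id] > maxcov) next
    if (g$nodes$avg_cov[h$id] < min_node_cov) next
    ro <- c(ro, i - 1L); nd <- c(nd, h$id)
    no <- c(no, h$offset - 1L); st <- c(st, h$strand)
  }
  data.frame(read_offset = ro, node = nd, node_offset = no, strand = st,
             stringsAsFactors = FALSE)
}

# depth-first seed-and-extend over unitigs with incremental fit alignment
# and branch-and-bound pruning; query start is anchored at the seed boundary,
# the graph end is free.
dfs_extend <- function(g, node, strand, remainder, query, params) {
  n <- nchar(query)
  if (n == 0L)
    return(list(seq = "", score = 0, path = list(), aborted = FALSE))
  env <- new.env()
  env$best <- n * params$gap       # all-gap completion (empty context)
  env$best_str <- ""
  env$best_path <- list()
  env$visits <- 0L
  env$aborted <- FALSE
  needed <- n + max(10L, ceiling(0.2 * n))

  # process one context segment: update the incumbent best completion and
  # return the new DP column plus an optimistic bound for any continuation
  step <- function(col, ctx_str, seg, path) {
    if (nchar(seg) == 0L)
      return(list(col = col, bound = max(col + params$match * (n:0))))
    res <- .extend_cols_cpp(col, query, seg,
                            params$match, params$mismatch, params$gap)
    comp <- res$complete
    jbest <- which.max(comp)
    if (length(jbest) && comp[jbest] > env$best) {
      env$best <- comp[jbest]
      env$best_str <- paste0(ctx_str, substr(seg, 1L, jbest))
      env$best_path <- path
    }
    list(col = res$col, bound = res$bound)
  }

  # best-bound-first depth-first search: each successor's segment is scored
  # before descending, children are explored in decreasing bound order, and
  # branches whose optimistic bound cannot beat the incumbent are pruned --
  # this finds the true path early so homopolymer self-loops prune quickly
  rec <- function(col, ctx_len, ctx_str, node, strand, path) {
    if (env$aborted || ctx_len >= needed) return(invisible(NULL))
    succ <- arcs_from(g, node, strand)
    succ <- succ[g$nodes$avg_cov[succ$to] >= params$min_node_cov, , drop = FALSE]
    if (!nrow(succ)) return(invisible(NULL))
    kids <- vector("list", nrow(succ))
    for (s in seq_len(nrow(succ))) {
      env$visits <- env$visits + 1L
      if (env$visits > params$max_branch) { env$aborted <- TRUE; return(invisible(NULL)) }
      nid <- succ$to[s]; nst <- succ$to_strand[s]
      seg2 <- substring(oriented_seq(g, nid, nst), g$k)
      p2 <- c(path, list(list(id = nid, strand = nst)))
      st <- step(col, ctx_str, seg2, p2)
      kids[[s]] <- list(col = st$col, bound = st$bound,
                        ctx_len = ctx_len + nchar(seg2),
                        ctx_str = paste0(ctx_str, seg2),
                        node = nid, strand = nst, path = p2)
    }
    for (kid in kids[order(-vapply(kids, `[[`, 0, "bound"))]) {
      if (env$aborted) break
      if (kid$bound <= env$best) next  # branch-and-bound prune
      rec(kid$col, kid$ctx_len, kid$ctx_str, kid$node, kid$strand, kid$path)
    }
    invisible(NULL)
  }
  st0 <- step((0:n) * params$gap, "", remainder, list())
  if (st0$bound > env$best && nchar(remainder) < needed)
    rec(st0$col, nchar(remainder), remainder, node, strand, list())
  list(seq = env$best_str, score = env$best, path = env$best_path,
       aborted = env$aborted)
}

#' Align a read to the graph around its seeds and spell the correction
#'
#' Collinear seeds (same node, strand and diagonal) are chained; the chain
#' with most seeds wins, ties going to the leftmost chain.  A depth-first
#' search then extends the alignment left and right of the chained region
#' across unitig arcs, scoring candidate graph paths against the read flanks
#' with free graph-side end gaps; branches whose optimistic score cannot beat
#' the current best are pruned, and the search aborts (leaving the read
#' unchanged) after `max_branch` node visits per side.
#'
#' @param read a read sequence.
#' @param seeds output of [find_seeds()] (non-empty).
#' @param g a cleaned `dbg`.
#' @param params a [correct_params()].
#' @return an object of class `alignment_result`: `path` (data.frame `id`,
#'   `strand`), `corrected_seq`, `score`, `identity`, `status`
#'   (`corrected`/`unchanged`) and `transcript` (edit ops read -> correction).
#' @export
extend_alignment <- function(read, seeds, g, params = correct_params()) {
  stopifnot(nrow(seeds) > 0L)
  k <- g$k
  seeds$diag <- seeds$node_offset - seeds$read_offset
  key <- paste(seeds$node, seeds$strand, seeds$diag)
  sizes <- table(key)
  starts <- tapply(seeds$read_offset, key, min)
  ord <- order(-as.integer(sizes[names(starts)]), starts)
  chain_key <- names(starts)[ord[1L]]
  ch <- seeds[key == chain_key, , drop = FALSE]
  id <- ch$node[1L]; strand <- ch$strand[1L]
  ro0 <- min(ch$read_offset)
  alen <- max(ch$read_offset) + k - ro0
  no0 <- min(ch$node_offset)
  s <- oriented_seq(g, id, strand)

  anchor <- substr(s, no0 + 1L, no0 + alen)
  # rightward extension
  q_right <- substring(read, ro0 + alen + 1L)
  right <- dfs_extend(g, id, strand, substring(s, no0 + alen + 1L),
                      q_right, params)
  # leftward extension == rightward extension of the reverse complement
  q_left <- if (ro0 > 0L) rc_chr(substr(read, 1L, ro0)) else ""
  fs <- flip_strand(strand)
  rs <- oriented_seq(g, id, fs)
  rem_left <- if (no0 > 0L) substring(rs, nchar(rs) - no0 + 1L) else ""
  left <- dfs_extend(g, id, fs, rem_left, q_left, params)

  if (left$aborted || right$aborted) {
    return(structure(list(path = NULL, corrected_seq = read, score = NA_real_,
                          identity = NA_real_, status = "unchanged",
                          transcript = NULL),
                     class = "alignment_result"))
  }
  # A flank is replaced by its graph spelling only where the graph genuinely
  # explains it.  Over the aligned columns (excluding a trailing unaligned
  # read tail, which is kept verbatim past a graph dead end) the alignment
  # score must be positive and the identity at least 0.7 -- loose enough to
  # accept true context under dense read errors, strict enough to reject a
  # wrong graph path, whose identity hovers near the random ~0.5.  The
  # whole-read min_identity check still gates the final status.
  settle_flank <- function(query, ctx) {
    if (!nchar(query)) return(list(seq = ctx, graph_len = nchar(ctx)))
    if (!nchar(ctx)) return(list(seq = query, graph_len = 0L))
    ga <- .global_align_cpp(query, ctx, params$match, params$mismatch, params$gap)
    t <- nchar(sub(".*?(I*)$", "\\1", ga$transcript))
    cols <- ga$columns - t
    aligned <- substr(ga$transcript, 1L, cols)
    nm <- nchar(gsub("[^M]", "", aligned))
    nx <- nchar(gsub("[^X]", "", aligned))
    ng <- cols - nm - nx
    score <- nm * params$match + nx * params$mismatch + ng * params$gap
    if (cols <= 0L || score <= 0 || nm / cols < params$flank_identity)
      return(list(seq = query, graph_len = 0L))
    tail_seq <- if (t > 0L) substring(query, nchar(query) - t + 1L) else ""
    list(seq = paste0(ctx, tail_seq), graph_len = nchar(ctx))
  }
  right <- modifyList(right, settle_flank(q_right, right$seq))
  left <- modifyList(left, settle_flank(q_left, left$seq))
  corrected <- paste0(if (nchar(left$seq)) rc_chr(left$seq) else "",
                      anchor, right$seq)
  ga <- .global_align_cpp(read, corrected,
                          params$match, params$mismatch, params$gap)
  identity <- if (ga$columns > 0) ga$matches / ga$columns else 0
  lp <- rev(lapply(left$path, function(x) list(id = x$id, strand = flip_strand(x$strand))))
  path <- do.call(rbind, lapply(c(lp, list(list(id = id, strand = strand)), right$path),
                                as.data.frame))
  score <- left$score + right$score + alen * params$match
  status <- if (identity >= params$min_identity) "corrected" else "unchanged"
  # positions of corrected_seq spelled by the graph path (read overhangs kept
  # verbatim beyond graph dead ends lie outside this span)
  span <- c(nchar(left$seq) - left$graph_len + 1L,
            nchar(left$seq) + alen + right$graph_len)
  structure(list(path = path,
                 corrected_seq = if (status == "corrected") corrected else read,
                 score = score, identity = identity, status = status,
                 graph_span = span,
                 transcript = if (status == "corrected") ga$transcript else NULL),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("read-to-graph alignment: status %s, identity %.3f, score %s\n",
              x$status, x$identity %||% NA,
              format(x$score)))
  invisible(x)
}

# correct one read, recursing into flank regions that the primary chain's
# graph neighbourhood could not reach but that carry their own seeds (cluster
# graphs are often coverage archipelagos: an anchor island plus mate islands)
correct_read <- function(read, g, params, depth = 0L) {
  seeds <- find_seeds(read, g, params$repeat_cov_factor, params$min_node_cov)
  if (!nrow(seeds)) {
    return(structure(list(path = NULL, corrected_seq = read, score = NA_real_,
                          identity = NA_real_, status = "unaligned",
                          transcript = NULL),
                     class = "alignment_result"))
  }
  res <- extend_alignment(read, seeds, g, params)
  if (is.null(res$graph_span) || depth >= 4L) return(res)
  corr <- res$corrected_seq
  if (res$status != "corrected") return(res)
  sp <- res$graph_span
  # out-of-span flanks are verbatim read substrings; retry them on their own
  lv <- sp[1L] - 1L                      # verbatim read prefix length
  rv <- nchar(corr) - sp[2L]             # verbatim read suffix length
  changed <- FALSE
  if (lv >= g$k + 5L) {
    sub <- substr(read, 1L, lv)
    subres <- correct_read(sub, g, params, depth + 1L)
    if (subres$status == "corrected" && subres$corrected_seq != sub) {
      corr <- paste0(subres$corrected_seq, substring(corr, lv + 1L))
      changed <- TRUE
    }
  }
  if (rv >= g$k + 5L) {
    sub <- substring(read, nchar(read) - rv + 1L)
    subres <- correct_read(sub, g, params, depth + 1L)
    if (subres$status == "corrected" && subres$corrected_seq != sub) {
      corr <- paste0(substr(corr, 1L, nchar(corr) - rv),
                     subres$corrected_seq)
      changed <- TRUE
    }
  }
  if (changed) {
    ga <- .global_align_cpp(read, corr, params$match, params$mismatch, params$gap)
    identity <- if (ga$columns > 0) ga$matches / ga$columns else 0
    if (identity >= params$min_identity) {
      res$corrected_seq <- corr
      res$identity <- identity
      res$transcript <- ga$transcript
      res$graph_span <- NULL  # spliced from several islands
    }
  }
  res
}

#' Correct every read of a cluster against its cleaned graph
#'
#' Reads with no unique seed are reported `unaligned`; reads whose best graph
#' spelling falls below `min_identity` stay `unchanged`; the rest are replaced
#' by the graph-spelled sequence (`corrected`).  Read regions beyond a graph
#' dead end are re-seeded and corrected piecewise when they carry their own
#' unique k-mers.  No read is ever dropped.
#'
#' @param reads character vector of read sequences.
#' @param g the cluster's cleaned `dbg`.
#' @param params a [correct_params()].
#' @return list of `alignment_result`, one per read, in input order.
#' @export
correct_cluster <- function(reads, g, params = correct_params()) {
  lapply(reads, correct_read, g = g, params = params)
}

# spell the sequence of a node path (for validation): consecutive oriented
# node sequences overlap by k-1 bases
spell_path <- function(g, path) {
  if (is.null(path) || !nrow(path)) return("")
  segs <- vapply(seq_len(nrow(path)), function(i)
    oriented_seq(g, path$id[i], path$strand[i]), character(1))
  out <- segs[1L]
  for (i in seq_len(nrow(path))[-1L]) out <- paste0(out, substring(segs[i], g$k))
  out
}
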