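#' Pipeline configuration
#'
#' Bundles the stage parameters with their defaults: poly(A/T) 15-mer
#' extraction, clustering and graph k of 15, 20 stabilised Louvain runs with
#' co-clustering threshold 0.8, minimum cluster size 5 pairs, and conservative
#' correction acceptance at 80% identity.
#'
#' @param pattern a [repetitive_pattern()].
#' @param cluster_k k for the shared-k-mer prefilter (default 15).
#' @param dbg_k k for the per-cluster de Bruijn graph (default 15).
#' @param align an [align_params()] for pair similarity.
#' @param n_runs,theta stable-core parameters (defaults 20, 0.8).
#' @param min_cluster_size clusters with fewer pairs pass through uncorrected
#'   (default 5).
#' @param beta prefilter multiplier defining "about C_k" (default 2).
#' @param coverage,error_rate optional dataset coverage and error rate; when
#'   given, `C_k` for the prefilter is computed by [expected_kmer_coverage()]
#'   instead of being estimated from the extracted k-mer counts.
#' @param correct a [correct_params()].
#' @param max_rounds graph-cleaning rounds (default 10).
#' @param fallback_cutoff coverage cutoff used when the cluster is too small
#'   or too thin for the mixture model to resolve two components; `NULL`
#'   (default) uses `max(1.5, weighted median node coverage / 4)`, i.e. the
#'   classic drop-singletons rule (an erroneous node is typically supported
#'   by a single read).
#' @param seed master seed driving every randomised stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(pattern = repetitive_pattern("polyAT", 15L),
                            cluster_k = 15L, dbg_k = 15L,
                            align = align_params(),
                            n_runs = 20L, theta = 0.8,
                            min_cluster_size = 5L, beta = 2,
                            coverage = NULL, error_rate = NULL,
                            correct = correct_params(),
                            max_rounds = 10L, fallback_cutoff = NULL,
                            seed = 1L) {
  structure(list(pattern = pattern, cluster_k = as.integer(cluster_k),
                 dbg_k = as.integer(dbg_k), align = align, n_runs = as.integer(n_runs),
                 theta = theta, min_cluster_size = as.integer(min_cluster_size),
                 beta = beta, coverage = coverage, error_rate = error_rate,
                 correct = correct, max_rounds = as.integer(max_rounds),
                 fallback_cutoff = fallback_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

# map a corrected sequence's qualities from the original read:
# matched/mismatched columns keep the original base quality, bases inserted by
# the correction get '#' (phred 2), deleted bases drop their quality
map_quality <- function(transcript, orig_qual) {
  ops <- strsplit(transcript, "")[[1]]
  oq <- strsplit(orig_qual, "")[[1]]
  out <- character(0)
  i <- 0L
  for (op in ops) {
    if (op == "M" || op == "X") { i <- i + 1L; out <- c(out, oq[i]) }
    else if (op == "I") i <- i + 1L          # base removed from the read
    else out <- c(out, "#")                  # base introduced by correction
  }
  paste(out, collapse = "")
}

# correct the pairs of one cluster; returns read_pairs of pairs that changed
correct_one_cluster <- function(cluster_pairs, cfg) {
  reads <- c(rbind(cluster_pairs$seq1, cluster_pairs$seq2))
  g <- build_graph(reads, cfg$dbg_k)
  # The mixture separates erroneous from correct *single-copy* nodes; repeat
  # hubs (the homopolymer node above all) sit far above single-copy coverage
  # and would capture the correct component on small clusters, so nodes above
  # 5x the length-weighted median coverage are excluded from the fit.
  medcov <- weighted_median_cov(g)
  infit <- g$nodes$avg_cov <= 5 * medcov
  cutoff <- tryCatch(
    fit_coverage_model(g$nodes$avg_cov[infit], weight = g$nodes$len[infit])$cutoff,
    error = function(e) cfg$fallback_cutoff %||% max(1.5, medcov / 4))
  cp <- clean_params(max_error_node_len = max(1L, round(mean(nchar(reads))) - cfg$dbg_k),
                     cutoff = cutoff, max_rounds = cfg$max_rounds)
  gc_ <- clean_graph(g, cp)
  if (!nrow(gc_$nodes)) {
    return(list(corrected = cluster_pairs[0, ], status = rep("unaligned", length(reads))))
  }
  # Reads are aligned to the trusted part of the cleaned graph: surviving
  # nodes supported by a single read (the typical footprint of that read's
  # own errors) must not attract its alignment, while genuinely covered
  # low-coverage segments stay traversable.  Hence min(cutoff, 2).
  cpar <- cfg$correct
  if (cpar$min_node_cov == 0) cpar$min_node_cov <- min(cutoff, 2)
  res <- correct_cluster(reads, gc_, cpar)
  status <- vapply(res, `[[`, character(1), "status")
  n <- nrow(cluster_pairs)
  out <- cluster_pairs
  changed <- logical(n)
  for (p in seq_len(n)) {
    r1 <- res[[2L * p - 1L]]; r2 <- res[[2L * p]]
    if (r1$status == "corrected" && r1$corrected_seq != out$seq1[p]) {
      out$qual1[p] <- map_quality(r1$transcript, out$qual1[p])
      out$seq1[p] <- r1$corrected_seq
      changed[p] <- TRUE
    }
    if (r2$status == "corrected" && r2$corrected_seq != out$seq2[p]) {
      out$qual2[p] <- map_quality(r2$transcript, out$qual2[p])
      out$seq2[p] <- r2$corrected_seq
      changed[p] <- TRUE
    }
  }
  list(corrected = out[changed, , drop = FALSE], status = status)
}

#' Run the full targeted correction pipeline
#'
#' extract -> cluster -> per-cluster correct -> merge.  Reads whose pair does
#' not contain the repetitive pattern are never modified; output FASTQ files
#' preserve the input record count and order, and reruns with the same seed
#' are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param in1,in2 input FASTQ paths (mate 1 / mate 2).
#' @param out1,out2 output FASTQ paths.
#' @param pairs alternatively, a pre-loaded [read_pairs()] table (then
#'   `in1`/`in2` are ignored; with `NULL` `out1`, nothing is written).
#' @param debug_dir optional directory for per-stage dumps (extracted pairs,
#'   edge list, cluster map, per-cluster GFA).
#' @return an object of class `ec_report` (counts per stage, cluster sizes,
#'   per-read statuses, timing); with `pairs` input the report carries the
#'   merged table as `$result`.
#' @export
run_correct <- function(cfg, in1 = NULL, in2 = NULL, out1 = NULL, out2 = NULL,
                        pairs = NULL, debug_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(pairs)) pairs <- read_paired_fastq(in1, in2)
  ex <- extract_pairs(pairs, cfg$pattern)
  sel <- ex$selected
  timing <- c(extract = as.numeric(Sys.time() - t0, units = "secs"))
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    write_paired_fastq(sel, file.path(debug_dir, "extracted_1.fastq"),
                       file.path(debug_dir, "extracted_2.fastq"))
  }

  cores <- list(cores = list(), unassigned = character(0))
  if (nrow(sel) >= 2L) {
    ck <- NULL
    if (!is.null(cfg$coverage)) {
      l <- median(nchar(c(sel$seq1, sel$seq2)))
      ck <- expected_kmer_coverage(cfg$coverage, l, cfg$cluster_k,
                                   cfg$error_rate %||% 0)
    }
    t1 <- Sys.time()
    g <- build_similarity_graph(sel, ck = ck, params = cfg$align,
                                pattern = cfg$pattern,
                                cluster_k = cfg$cluster_k, beta = cfg$beta)
    cores <- stable_cores(g, n_runs = cfg$n_runs, theta = cfg$theta,
                          seed = cfg$seed)
    timing["cluster"] <- as.numeric(Sys.time() - t1, units = "secs")
    if (!is.null(debug_dir)) {
      export_edge_list(g, file.path(debug_dir, "edges.tsv"))
      export_cluster_map(cores, file.path(debug_dir, "clusters.tsv"))
    }
  } else if (nrow(sel) == 1L) {
    cores$unassigned <- as.character(sel$ordinal)
  }

  big <- cores$cores[lengths(cores$cores) >= cfg$min_cluster_size]
  small <- unlist(cores$cores[lengths(cores$cores) < cfg$min_cluster_size],
                  use.names = FALSE)
  t2 <- Sys.time()
  corrected_list <- list()
  statuses <- character(0)
  for (ci in seq_along(big)) {
    cl_pairs <- sel[match(as.integer(big[[ci]]), sel$ordinal), , drop = FALSE]
    res <- correct_one_cluster(cl_pairs, cfg)
    corrected_list[[length(corrected_list) + 1L]] <- res$corrected
    statuses <- c(statuses, res$status)
    if (!is.null(debug_dir)) {
      g_cl <- build_graph(c(rbind(cl_pairs$seq1, cl_pairs$seq2)), cfg$dbg_k)
      export_gfa(g_cl, file.path(debug_dir, sprintf("cluster_%03d.gfa", ci)))
    }
  }
  timing["correct"] <- as.numeric(Sys.time() - t2, units = "secs")
  corrected <- if (length(corrected_list)) {
    cc <- do.call(rbind, corrected_list)
    class(cc) <- c("read_pairs", "data.frame")
    cc
  } else empty_read_pairs()

  merged <- merge_corrected(pairs, corrected)
  if (!is.null(out1)) write_paired_fastq(merged, out1, out2)

  report <- structure(list(
    total_pairs = nrow(pairs),
    extracted_pairs = nrow(sel),
    clusters = length(big),
    cluster_sizes = lengths(big),
    core_pairs = sum(lengths(big)),
    unassigned_pairs = length(cores$unassigned) + length(small),
    reads_corrected = sum(statuses == "corrected"),
    reads_unchanged = sum(statuses == "unchanged"),
    reads_unaligned = sum(statuses == "unaligned"),
    modified_pairs = nrow(corrected),
    fraction_modified = nrow(corrected) / max(1L, nrow(pairs)),
    corrected_ordinals = corrected$ordinal,
    extracted_ordinals = sel$ordinal,
    core_ordinals = lapply(big, as.integer),
    timing = timing,
    result = merged), class = "ec_report")
  report
}

#' @export
print.ec_report <- function(x, ...) {
  cat("targeted error-correction report\n")
  cat(sprintf("  pairs: %d total, %d extracted (%.2f%%), %d modified (%.2f%%)\n",
              x$total_pairs, x$extracted_pairs,
              100 * x$extracted_pairs / max(1, x$total_pairs),
              x$modified_pairs, 100 * x$fraction_modified))
  cat(sprintf("  clusters: %d (sizes %s), %d pairs unassigned/too small\n",
              x$clusters, paste(x$cluster_sizes, collapse = ","),
              x$unassigned_pairs))
  cat(sprintf("  reads: %d corrected, %d unchanged, %d unaligned\n",
              x$reads_corrected, x$reads_unchanged, x$reads_unaligned))
  cat(sprintf("  timing (s): %s\n",
              paste(sprintf("%s %.1f", names(x$timing), x$timing), collapse = ", ")))
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' @param report an `ec_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  r$result <- NULL
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
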