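#' Correction quality against simulated truth
#'
#' Each read, before and after correction, is compared to its error-free
#' origin substring by unit-cost edit distance.  Per read with `b` errors
#' before and `a` after, TP (errors removed) accrues `max(b - a, 0)`, FP (new
#' errors introduced) `max(a - b, 0)`, and FN (errors remaining) `b - max(b -
#' a, 0)`; the summary scalar is `gain = (TP - FP) / (TP + FN)`, the fraction
#' of pre-existing errors removed net of damage (gain = 1 iff perfect, <= 0
#' when correction does not help).
#'
#' @param before,after `read_pairs` tables aligned by ordinal.
#' @param sim a [simulate_reads()] object supplying truth and genome.
#' @param ordinals optional subset of pair ordinals to score (e.g. only the
#'   extracted pairs).
#' @return an object of class `correction_stats`: `list(TP, FP, FN, gain,
#'   n_reads)`.
#' @export
correction_stats <- function(before, after, sim, ordinals = NULL) {
  stopifnot(inherits(before, "read_pairs"), inherits(after, "read_pairs"),
            inherits(sim, "sim_reads"))
  if (nrow(before) != nrow(after) || !all(before$ordinal == after$ordinal))
    stop("consistency error: before/after read sets differ in ordinals")
  truth <- sim$truth
  gseq <- sim$genome$sequence
  if (is.null(ordinals)) ordinals <- before$ordinal
  idx <- match(ordinals, before$ordinal)
  if (anyNA(idx)) stop("consistency error: unknown ordinal requested")
  TP <- 0; FP <- 0; FN <- 0
  for (i in idx) {
    o <- before$ordinal[i]
    for (mate in 1:2) {
      trow <- truth[truth$ordinal == o & truth$mate == mate, ]
      if (nrow(trow) != 1L)
        stop("consistency error: truth row missing for ordinal ", o)
      ref <- true_origin(trow, gseq)
      bseq <- if (mate == 1L) before$seq1[i] else before$seq2[i]
      aseq <- if (mate == 1L) after$seq1[i] else after$seq2[i]
      b <- adist(bseq, ref)[1L, 1L]
      a <- adist(aseq, ref)[1L, 1L]
      tp <- max(b - a, 0)
      TP <- TP + tp
      FP <- FP + max(a - b, 0)
      FN <- FN + (b - tp)
    }
  }
  gain <- if (TP + FN > 0) (TP - FP) / (TP + FN) else NA_real_
  structure(list(TP = TP, FP = FP, FN = FN, gain = gain,
                 n_reads = 2L * length(idx)),
            class = "correction_stats")
}

#' @export
print.correction_stats <- function(x, ...) {
  cat(sprintf("correction stats over %d reads: TP=%d FP=%d FN=%d gain=%.3f\n",
              x$n_reads, x$TP, x$FP, x$FN, x$gain))
  invisible(x)
}

#' Assembly contiguity tables (NGA50 per correction condition)
#'
#' Tab-separated grid with a header of dataset ids (D1..D9) and a first
#' column of condition names; one grid per panel (contig, scaffold).  The
#' packaged copies under `extdata` transcribe the published benchmark of six
#' Illumina and three hybrid Illumina+PacBio assemblies.
#'
#' @param path a table file; or use [nga50_tables()] for the packaged grids.
#' @return data.frame with rownames = conditions.
#' @export
read_nga50_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  if (!"uncorrected" %in% tolower(rownames(df)))
    stop("NGA50 table must contain an 'Uncorrected' row")
  if (any(df <= 0)) stop("NGA50 values must be positive")
  df
}

#' @rdname read_nga50_table
#' @return `nga50_tables()`: `list(contig = , scaffold = )` data.frames.
#' @export
nga50_tables <- function() {
  dir <- system.file("extdata", package = "targetec")
  list(contig = read_nga50_table(file.path(dir, "nga50_contig.tsv")),
       scaffold = read_nga50_table(file.path(dir, "nga50_scaffold.tsv")))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Mean NGA50 improvement of a tool over uncorrected data
#'
#' Arithmetic mean over datasets of the per-dataset percent change
#' `100 * (NGA50_tool - NGA50_uncorrected) / NGA50_uncorrected`, rounded half
#' away from zero to the nearest integer percent (set `round = FALSE` for the
#' raw mean).
#'
#' @param tab an NGA50 grid from [read_nga50_table()] / [nga50_tables()].
#' @param tool condition (row) name.
#' @param round round to integer percent? (default `TRUE`)
#' @return the mean improvement in percent.
#' @export
mean_improvement <- function(tab, tool, round = TRUE) {
  if (!tool %in% rownames(tab)) stop("unknown condition: ", tool)
  unc <- as.numeric(tab["Uncorrected", ])
  if (any(unc == 0)) stop("domain error: zero uncorrected NGA50")
  v <- as.numeric(tab[tool, ])
  m <- mean(100 * (v - unc) / unc)
  if (round) round_half_away(m) else m
}

#' Best-condition counts across datasets and panels
#'
#' For every dataset x panel cell, the condition with the highest NGA50 is
#' counted (ties counted for all tied conditions and flagged via the `ties`
#' attribute).  `top3_count()` counts the dataset x panel cases in which a
#' condition ranks among the three highest values.
#'
#' @param tables `list(contig = , scaffold = )` NGA50 grids (e.g.
#'   [nga50_tables()]).
#' @param conditions rows to compare; defaults to all rows of the contig grid.
#' @return named integer vector of win counts per condition.
#' @export
count_best <- function(tables, conditions = rownames(tables$contig)) {
  wins <- setNames(integer(length(conditions)), conditions)
  ties <- 0L
  for (panel in tables) {
    sub <- panel[conditions, , drop = FALSE]
    for (d in seq_len(ncol(sub))) {
      v <- setNames(sub[, d], rownames(sub))
      top <- which(v == max(v))
      if (length(top) > 1L) ties <- ties + 1L
      wins[top] <- wins[top] + 1L
    }
  }
  attr(wins, "ties") <- ties
  wins
}

#' @rdname count_best
#' @param condition condition for `top3_count()`.
#' @return `top3_count()`: number of dataset x panel cases in the top 3.
#' @export
top3_count <- function(tables, condition, conditions = rownames(tables$contig)) {
  n <- 0L
  for (panel in tables) {
    sub <- panel[conditions, , drop = FALSE]
    for (d in seq_len(ncol(sub))) {
      v <- setNames(sub[, d], rownames(sub))
      thresh <- sort(v, decreasing = TRUE)[min(3L, length(v))]
      if (v[condition] >= thresh) n <- n + 1L
    }
  }
  n
}
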