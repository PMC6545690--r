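#' Simulate a genome with planted homopolymer loci
#'
#' Generates a uniform random ACGT background, breaks any accidental
#' single-base run of 8 or more bases (so planted runs are the only
#' repetitive-pattern loci), and plants `n_loci` homopolymer runs of the
#' requested base class at well-separated positions.  Deterministic per seed.
#'
#' @param length genome length in bp.
#' @param n_loci number of planted homopolymer loci.
#' @param run_len_range inclusive range of planted run lengths (default
#'   15-25).
#' @param base_choices bases to draw each run from (default A/T).
#' @param margin minimum distance between loci and from the genome ends;
#'   should be at least twice the intended read length (default 300).
#' @param seed RNG seed.
#' @return an object of class `sim_genome`: `list(sequence, loci, seed)`
#'   where `loci` is a data.frame with `pos` (1-based start), `base`, `len`.
#' @export
simulate_genome <- function(length = 10000L, n_loci = 5L,
                            run_len_range = c(15L, 25L),
                            base_choices = c("A", "T"),
                            margin = 300L, seed = 1L) {
  length <- as.integer(length); n_loci <- as.integer(n_loci)
  if (n_loci > 0L && length < n_loci * (max(run_len_range) + 2L * margin %/% 2L))
    stop("parameter error: genome too short to pack the requested loci")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, length, replace = TRUE)
  # break accidental runs >= 8 so planted runs are the only pattern loci
  repeat {
    r <- rle(g)
    long <- which(r$lengths >= 8L)
    if (!base::length(long)) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      pos <- ends[i] - r$lengths[i] + 1L + 7L  # 8th base of the run
      g[pos] <- sample(setdiff(bases, g[pos]), 1L)
    }
  }
  loci <- data.frame(pos = integer(0), base = character(0), len = integer(0),
                     stringsAsFactors = FALSE)
  if (n_loci > 0L) {
    # one locus per equal-width bin, jittered, keeping margins clear
    binw <- (length - 2L * margin) %/% n_loci
    if (binw < max(run_len_range) + margin %/% 2L)
      stop("parameter error: genome too short to pack the requested loci")
    pos <- integer(n_loci); b <- character(n_loci); len <- integer(n_loci)
    for (i in seq_len(n_loci)) {
      len[i] <- sample(run_len_range[1L]:run_len_range[2L], 1L)
      lo <- margin + (i - 1L) * binw + 1L
      hi <- margin + i * binw - len[i] - margin %/% 2L
      pos[i] <- sample(lo:max(lo, hi), 1L)
      b[i] <- sample(base_choices, 1L)
      g[pos[i]:(pos[i] + len[i] - 1L)] <- b[i]
      # ensure the run is maximal (flanking bases differ)
      if (pos[i] > 1L && g[pos[i] - 1L] == b[i])
        g[pos[i] - 1L] <- sample(setdiff(bases, b[i]), 1L)
      j <- pos[i] + len[i]
      if (j <= length && g[j] == b[i]) g[j] <- sample(setdiff(bases, b[i]), 1L)
    }
    loci <- data.frame(pos = pos, base = b, len = len, stringsAsFactors = FALSE)
  }
  structure(list(sequence = paste(g, collapse = ""), loci = loci, seed = seed),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("simulated genome: %d bp, %d planted homopolymer loci (seed %d)\n",
              nchar(x$sequence), nrow(x$loci), x$seed))
  invisible(x)
}

# apply recorded ops to a pristine substring; ops applied in recorded order,
# positions refer to the read as it stands when the op is applied
apply_ops <- function(seq, ops) {
  if (!nrow(ops)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(ops))) {
    p <- ops$pos[i]
    if (ops$type[i] == "sub") {
      ch[p] <- ops$base[i]
    } else if (ops$type[i] == "ins") {
      ch <- append(ch, strsplit(ops$base[i], "")[[1]], after = p - 1L)
    } else {  # del
      nd <- nchar(ops$base[i])
      ch <- ch[-(p:(p + nd - 1L))]
    }
  }
  paste(ch, collapse = "")
}

#' Simulate paired-end reads with homopolymer error hotspots
#'
#' Pairs are drawn uniformly over the genome with Gaussian insert sizes; one
#' mate is the forward strand of the fragment start, the other the reverse
#' complement of the fragment end (labels swapped at random).  Substitution
#' errors occur at rate `e` genome-wide and at rate `e * m` in reads whose
#' origin overlaps a planted homopolymer run; those reads additionally suffer
#' length-1-2 homopolymer insertions/deletions inside the run (event
#' probability `e * m` per overlapped run, geometric(0.5) length).  Truth is
#' recorded per mate: origin interval, strand, and the exact edit operations,
#' so each read can be reproduced by replaying the ops on its origin
#' substring.  Quality strings are constant phred 31 for regular reads and
#' phred 20 for hotspot reads (annotation only; never used in correction).
#'
#' @param genome a [simulate_genome()] object.
#' @param coverage mean per-base coverage `C` (default 30).
#' @param read_len read length `l` (default 100).
#' @param insert_mean,insert_sd fragment size distribution (defaults 250, 15).
#' @param error_rate per-base substitution rate `e` (default 0.01).
#' @param hotspot_mult error multiplier `m` inside homopolymer-overlapping
#'   reads (default 10).
#' @param seed RNG seed.
#' @return an object of class `sim_reads`: `list(pairs, truth, genome,
#'   params)`; `pairs` is a [read_pairs()] table, `truth` a data.frame with
#'   one row per mate (`ordinal`, `mate`, `start`, `end`, `strand`,
#'   `hotspot`, `locus`, `has_pattern`, `n_err`, `ops`).
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 100L,
                           insert_mean = 250, insert_sd = 15,
                           error_rate = 0.01, hotspot_mult = 10, seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"))
  if (read_len >= insert_mean) stop("read length must be below the insert mean")
  if (error_rate * hotspot_mult >= 0.5) stop("hotspot error rate must stay below 0.5")
  set.seed(seed)
  G <- nchar(genome$sequence)
  n_pairs <- round(coverage * G / (2 * read_len))
  loci <- genome$loci
  run_start <- loci$pos; run_end <- loci$pos + loci$len - 1L
  bases <- c("A", "C", "G", "T")

  ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)), read_len), G)
  frag_start <- floor(runif(n_pairs, 1, G - ins + 1 + 1))
  fwd_first <- runif(n_pairs) < 0.5

  seqs <- character(2L * n_pairs); quals <- character(2L * n_pairs)
  tr <- vector("list", 2L * n_pairs)
  q31 <- strrep(rawToChar(as.raw(31L + 33L)), read_len)
  for (p in seq_len(n_pairs)) {
    s1 <- frag_start[p]; e1 <- s1 + read_len - 1L
    e2 <- s1 + ins[p] - 1L; s2 <- e2 - read_len + 1L
    ends <- list(list(start = s1, end = e1, strand = "+"),
                 list(start = s2, end = e2, strand = "-"))
    if (!fwd_first[p]) ends <- rev(ends)
    for (mate in 1:2) {
      em <- ends[[mate]]
      raw <- substr(genome$sequence, em$start, em$end)
      if (em$strand == "-") raw <- rc_chr(raw)
      ov <- which(run_start <= em$end & run_end >= em$start)
      hot <- length(ov) > 0L
      rate <- if (hot) error_rate * hotspot_mult else error_rate
      ops <- data.frame(pos = integer(0), type = character(0),
                        base = character(0), stringsAsFactors = FALSE)
      # substitutions on the raw read
      ch <- strsplit(raw, "")[[1]]
      hitpos <- which(runif(read_len) < rate)
      for (h in hitpos) {
        nb <- sample(setdiff(bases, ch[h]), 1L)
        ops <- rbind(ops, data.frame(pos = h, type = "sub", base = nb,
                                     stringsAsFactors = FALSE))
      }
      # homopolymer indels inside each overlapped run
      if (hot) {
        for (l in ov) {
          if (runif(1) >= rate) next
          # run coordinates within the read (before indels, after subs)
          g0 <- max(run_start[l], em$start); g1 <- min(run_end[l], em$end)
          if (em$strand == "+") { r0 <- g0 - em$start + 1L; r1 <- g1 - em$start + 1L }
          else { r0 <- em$end - g1 + 1L; r1 <- em$end - g0 + 1L }
          width <- min(rgeom(1, 0.5) + 1L, 2L)
          at <- sample(r0:r1, 1L)
          if (runif(1) < 0.5) {
            b <- if (em$strand == "+") loci$base[l] else rc_chr(loci$base[l])
            ops <- rbind(ops, data.frame(pos = at, type = "ins",
                                         base = strrep(b, width),
                                         stringsAsFactors = FALSE))
          } else {
            width <- min(width, r1 - at + 1L)
            ops <- rbind(ops, data.frame(pos = at, type = "del",
                                         base = substr(raw, at, at + width - 1L),
                                         stringsAsFactors = FALSE))
          }
        }
      }
      out <- apply_ops(raw, ops)
      i <- 2L * (p - 1L) + mate
      seqs[i] <- out
      quals[i] <- if (hot) strrep(rawToChar(as.raw(20L + 33L)), nchar(out))
                  else substr(q31, 1L, nchar(out)) # same length as out
      if (nchar(quals[i]) < nchar(out))
        quals[i] <- strrep(rawToChar(as.raw(31L + 33L)), nchar(out))
      tr[[i]] <- data.frame(
        ordinal = p - 1L, mate = mate, start = em$start, end = em$end,
        strand = em$strand, hotspot = hot,
        locus = if (hot) ov[1L] else NA_integer_,
        n_err = nrow(ops),
        ops = paste(sprintf("%d:%s:%s", ops$pos, ops$type, ops$base),
                    collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, tr)
  truth$has_pattern <- grepl("A{15}|T{15}|C{15}|G{15}", seqs)
  i1 <- 2L * seq_len(n_pairs) - 1L; i2 <- i1 + 1L
  ids <- sprintf("sim_%06d", seq_len(n_pairs) - 1L)
  pairs <- read_pairs(paste0(ids, "/1"), seqs[i1], quals[i1],
                      paste0(ids, "/2"), seqs[i2], quals[i2])
  structure(list(pairs = pairs, truth = truth, genome = genome,
                 params = list(coverage = coverage, read_len = read_len,
                               insert_mean = insert_mean, insert_sd = insert_sd,
                               error_rate = error_rate,
                               hotspot_mult = hotspot_mult, seed = seed)),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("simulated read set: %d pairs of %d bp (C=%g, e=%g, hotspot x%g)\n",
              nrow(x$pairs), x$params$read_len, x$params$coverage,
              x$params$error_rate, x$params$hotspot_mult))
  cat(sprintf("  %d hotspot reads over %d loci\n", sum(x$truth$hotspot),
              nrow(x$genome$loci)))
  invisible(x)
}

#' Write / read a simulation truth table
#'
#' Tab-separated: pair ordinal, mate, origin start/end, strand, hotspot flag,
#' locus, error count and the encoded error-operation list.
#'
#' @param truth the `truth` data.frame of a [simulate_reads()] object.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", quote = "", comment.char = "")
}

# reconstruct the error-free origin sequence for one truth row
true_origin <- function(truth_row, genome_seq) {
  s <- substr(genome_seq, truth_row$start, truth_row$end)
  if (truth_row$strand == "-") s <- rc_chr(s)
  s
}
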