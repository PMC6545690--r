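#' Construct a paired-read table
#'
#' A `read_pairs` object is a plain `data.frame` with one row per read pair
#' and columns `ordinal` (0-based position in the input), `id1`, `seq1`,
#' `qual1`, `id2`, `seq2`, `qual2`.  Pairing is positional: record i of file 1
#' mates record i of file 2, regardless of any "/1"/"/2" id suffixes.
#'
#' @param id1,seq1,qual1 identifier, sequence and phred+33 quality of mate 1.
#' @param id2,seq2,qual2 same for mate 2.
#' @param ordinal 0-based ordinals; defaults to input order.
#' @return a `read_pairs` data.frame.
#' @export
read_pairs <- function(id1, seq1, qual1, id2, seq2, qual2,
                       ordinal = seq_along(seq1) - 1L) {
  n <- length(seq1)
  stopifnot(length(seq2) == n, length(qual1) == n, length(qual2) == n)
  if (any(nchar(qual1) != nchar(seq1)) || any(nchar(qual2) != nchar(seq2)))
    stop("FASTQ format error: sequence and quality lengths differ")
  if (any(nchar(seq1) == 0L) || any(nchar(seq2) == 0L))
    stop("FASTQ format error: empty sequence")
  if (anyDuplicated(ordinal)) stop("ordinals must be unique")
  df <- data.frame(ordinal = as.integer(ordinal),
                   id1 = as.character(id1), seq1 = as.character(seq1),
                   qual1 = as.character(qual1),
                   id2 = as.character(id2), seq2 = as.character(seq2),
                   qual2 = as.character(qual2),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_pairs", "data.frame")
  df
}

empty_read_pairs <- function() {
  read_pairs(character(), character(), character(),
             character(), character(), character(), ordinal = integer())
}

read_fastq_one <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(seqs),
       seq = unname(as.character(seqs)),
       qual = unname(as.character(S4Vectors::mcols(seqs)$qualities)))
}

#' Read paired-end FASTQ files
#'
#' Reads two parallel FASTQ files (plain or gzip, Sanger phred+33), or one
#' interleaved file, into a [read_pairs()] table.  Pairing is positional.
#'
#' @param path1 FASTQ file with first mates (or the interleaved file).
#' @param path2 FASTQ file with second mates; ignored when `interleaved`.
#' @param interleaved if `TRUE`, `path1` holds r1,r2,r1,r2,...
#' @return a `read_pairs` data.frame ordered as in the input.
#' @export
read_paired_fastq <- function(path1, path2 = NULL, interleaved = FALSE) {
  if (interleaved) {
    all <- read_fastq_one(path1)
    n <- length(all$seq)
    if (n %% 2L != 0L)
      stop("pairing error: interleaved file has an odd number of records")
    i1 <- seq(1L, n, by = 2L); i2 <- seq(2L, n, by = 2L)
    return(read_pairs(all$id[i1], all$seq[i1], all$qual[i1],
                      all$id[i2], all$seq[i2], all$qual[i2]))
  }
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (length(r1$seq) != length(r2$seq))
    stop(sprintf("pairing error: %d records in '%s' but %d in '%s'",
                 length(r1$seq), path1, length(r2$seq), path2))
  read_pairs(r1$id, r1$seq, r1$qual, r2$id, r2$seq, r2$qual)
}

write_fastq_one <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(NULL)
}

#' Write paired-end FASTQ files
#'
#' Writes a [read_pairs()] table back to two FASTQ files preserving order and
#' record count, so that read/write round-trips are the identity.
#'
#' @param pairs a `read_pairs` data.frame, ordered by ordinal.
#' @param path1,path2 output paths (".gz" suffix enables compression).
#' @export
write_paired_fastq <- function(pairs, path1, path2) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (is.unsorted(pairs$ordinal)) pairs <- pairs[order(pairs$ordinal), ]
  write_fastq_one(pairs$id1, pairs$seq1, pairs$qual1, path1)
  write_fastq_one(pairs$id2, pairs$seq2, pairs$qual2, path2)
  invisible(NULL)
}

#' Substitute corrected pairs into the original read set
#'
#' Pairs that were not corrected are returned bit-identical to the input;
#' corrected pairs replace the originals in place.  Record number and order
#' never change.
#'
#' @param original full `read_pairs` table.
#' @param corrected `read_pairs` table holding only corrected pairs, addressed
#'   by `ordinal`.
#' @return a `read_pairs` table of the same dimension and order as `original`.
#' @export
merge_corrected <- function(original, corrected) {
  stopifnot(inherits(original, "read_pairs"), inherits(corrected, "read_pairs"))
  if (nrow(corrected) == 0L) return(original)
  idx <- match(corrected$ordinal, original$ordinal)
  if (anyNA(idx))
    stop("consistency error: corrected ordinal not present in original set")
  out <- original
  cols <- c("id1", "seq1", "qual1", "id2", "seq2", "qual2")
  out[idx, cols] <- corrected[, cols]
  out
}
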