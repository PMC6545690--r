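#' Encode a k-mer as a 2-bit-per-base integer
#'
#' A=00, C=01, G=10, T=11, concatenated most-significant-base first, so the
#' numeric order of codes equals the lexicographic order of the strings.
#' Codes are returned as doubles; they are exact for k <= 26 (52 bits), which
#' is the supported range.
#'
#' @param s character vector of ACGT strings, all of the same length k.
#' @return numeric vector of codes in `[0, 4^k)`.
#' @export
encode_kmer <- function(s) {
  k <- unique(nchar(s))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k < 1L || k > 26L) stop("k must be between 1 and 26")
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  pow <- 4^((k - 1):0)
  vapply(s, function(x) {
    v <- lut[utf8ToInt(x) + 1L]
    if (anyNA(v)) stop("encoding error: non-ACGT character in k-mer '", x, "'")
    sum(v * pow)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decode a 2-bit k-mer code back to its string
#'
#' @param code numeric vector of codes as produced by [encode_kmer()].
#' @param k k-mer length.
#' @return character vector of ACGT strings.
#' @export
decode_kmer <- function(code, k) {
  if (k < 1L || k > 26L) stop("k must be between 1 and 26")
  bases <- c("A", "C", "G", "T")
  vapply(code, function(x) {
    out <- character(k)
    for (i in k:1) {
      out[i] <- bases[(x %% 4) + 1]
      x <- x %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Describe a repetitive low-complexity pattern
#'
#' The default pattern is a poly(A/T) run of at least `k` bases, the
#' low-complexity 15-mer that dominates assembly breakpoints; `polyCG` is the
#' C/G analogue, and `explicit` matches an exact k-mer or its reverse
#' complement.
#'
#' @param kind one of `"polyAT"`, `"polyCG"`, `"explicit"`.
#' @param k minimum run length / k-mer size (default 15).
#' @param explicit_seq the exact k-mer when `kind = "explicit"`.
#' @return an object of class `rep_pattern`.
#' @export
repetitive_pattern <- function(kind = c("polyAT", "polyCG", "explicit"),
                               k = 15L, explicit_seq = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (k < 1L) stop("pattern k must be >= 1")
  if (kind == "explicit") {
    if (is.null(explicit_seq) || nchar(explicit_seq) != k)
      stop("explicit pattern requires explicit_seq of length k")
    explicit_seq <- toupper(explicit_seq)
  }
  structure(list(kind = kind, k = k, explicit_seq = explicit_seq),
            class = "rep_pattern")
}

pattern_regex <- function(pattern) {
  k <- pattern$k
  switch(pattern$kind,
         polyAT = sprintf("A{%d}|T{%d}", k, k),
         polyCG = sprintf("C{%d}|G{%d}", k, k),
         explicit = sprintf("%s|%s",
                            pattern$explicit_seq, rc_chr(pattern$explicit_seq)))
}

#' Does a read contain the repetitive pattern?
#'
#' For homopolymer kinds, `TRUE` iff the sequence contains a run of at least
#' `k` identical bases of the pattern alphabet (reverse-complement symmetry is
#' automatic); for explicit patterns, iff the k-mer or its reverse complement
#' occurs.  Vectorised over sequences; `N` bases never match.
#'
#' @param seq character vector of read sequences.
#' @param pattern a [repetitive_pattern()].
#' @return logical vector.
#' @export
matches_pattern <- function(seq, pattern) {
  stopifnot(inherits(pattern, "rep_pattern"))
  grepl(pattern_regex(pattern), seq)
}

# 1-based [start, end] intervals of maximal pattern runs within one sequence
pattern_runs <- function(seq, pattern) {
  m <- gregexpr(pattern_regex(pattern), seq)[[1]]
  if (m[1] == -1L) return(NULL)
  st <- as.integer(m)
  len <- attr(m, "match.length")
  # extend homopolymer matches to maximal runs (regex returns leftmost k)
  if (pattern$kind != "explicit") {
    ch <- strsplit(seq, "")[[1]]
    for (i in seq_along(st)) {
      b <- ch[st[i]]
      e <- st[i] + len[i] - 1L
      while (e < length(ch) && ch[e + 1L] == b) e <- e + 1L
      s <- st[i]
      while (s > 1L && ch[s - 1L] == b) s <- s - 1L
      st[i] <- s; len[i] <- e - s + 1L
    }
  }
  cbind(start = st, end = st + len - 1L)
}

#' Extract read pairs that contain a repetitive pattern
#'
#' A pair is selected when either mate matches the pattern; reads are always
#' extracted (and later corrected) in pairs.  The two outputs partition the
#' input and both preserve input order.
#'
#' @param pairs a [read_pairs()] table.
#' @param pattern a [repetitive_pattern()].
#' @return `list(selected = , passthrough = )`, both `read_pairs`.
#' @export
extract_pairs <- function(pairs, pattern) {
  stopifnot(inherits(pairs, "read_pairs"))
  hit <- matches_pattern(pairs$seq1, pattern) | matches_pattern(pairs$seq2, pattern)
  list(selected = pairs[hit, , drop = FALSE],
       passthrough = pairs[!hit, , drop = FALSE])
}

#' Expected coverage of extracted reads over a k-mer locus
#'
#' The expected number of error-free reads fully covering one genomic
#' occurrence of a k-mer is \deqn{C_k = \frac{l-k+1}{l}\, C\, (1-e)^k,} with
#' `C` the mean per-base coverage, `l` the read length and `e` the per-base
#' error rate.  `C_k` is the expected size of one read cluster.
#'
#' @param C mean per-base read coverage (> 0).
#' @param l read length.
#' @param k k-mer size (1 <= k <= l).
#' @param e per-base error rate in [0, 1).
#' @return the expected extracted coverage, a single number.
#' @export
expected_kmer_coverage <- function(C, l, k, e = 0) {
  if (C <= 0) stop("coverage C must be positive")
  if (k > l) stop("domain error: k must not exceed the read length")
  if (k < 1) stop("k must be >= 1")
  if (e < 0 || e >= 1) stop("error rate e must lie in [0, 1)")
  (l - k + 1) / l * C * (1 - e)^k
}

#' Count k-mers in a set of reads
#'
#' Every window consisting solely of A/C/G/T is counted once; windows
#' containing `N` are skipped.  With `canonical = TRUE` a k-mer and its
#' reverse complement are merged under the lexicographically smaller of the
#' two.
#'
#' @param reads character vector of read sequences.
#' @param k k-mer length.
#' @param canonical merge reverse complements? (default `TRUE`)
#' @return an object of class `kmer_counts`: `list(k, canonical, counts)`
#'   where `counts` is a named integer vector.
#' @export
count_kmers <- function(reads, k, canonical = TRUE) {
  if (k > 26L) stop("k must be <= 26")
  w <- kmer_windows(reads, k)
  if (length(w) == 0L) {
    counts <- integer(0)
  } else {
    if (canonical) w <- pmin(w, rc_chr(w))
    tb <- table(w)
    counts <- as.integer(tb)
    names(counts) <- names(tb)
  }
  structure(list(k = as.integer(k), canonical = canonical, counts = counts),
            class = "kmer_counts")
}

# all ACGT-only windows of length k across reads (forward orientation),
# in read order; reads shorter than k contribute nothing
kmer_windows <- function(reads, k) {
  out <- lapply(reads, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    w <- substring(s, 1:n, k:nchar(s))
    w[!grepl("[^ACGT]", w)]
  })
  unlist(out, use.names = FALSE)
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("k-mer count table: k = %d, %s, %d distinct k-mers, %d total\n",
              x$k, if (x$canonical) "canonical" else "stranded",
              length(x$counts), sum(x$counts)))
  invisible(x)
}
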