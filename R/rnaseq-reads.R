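#' Filter and quality-trim paired FASTQ reads
#'
#' Applies, in order: (1) removal of read pairs in which either mate has
#' `max_n` (default 7) or more undetermined nucleotides; (2) quality
#' trimming — scanning 5-base windows left to right, each read is truncated
#' at the first base of the first window containing at least 3 bases with
#' base-call quality below Q20; (3) removal of pairs in which either mate is
#' shorter than `min_length` (default 41 nt) after trimming. Mate pairing is
#' preserved throughout: if one mate fails, the pair is dropped.
#'
#' @param fastq_1,fastq_2 Paths to the mate FASTQ files (Phred+33).
#'   `fastq_2 = NULL` for single-end data.
#' @param out_1,out_2 Optional output paths; when given, surviving reads are
#'   written there (uncompressed FASTQ).
#' @param max_n Drop reads with at least this many N bases.
#' @param q_threshold Quality threshold of the trimming window (default 20).
#' @param window,min_low Window width (5) and the number of sub-threshold
#'   bases within it (3) that trigger truncation.
#' @param min_length Minimum read length after trimming (default 41).
#' @return A tibble of surviving fragments (`id`, `length_1`, `length_2`)
#'   with a per-rule `"report"` attribute (see [filter_report()]).
#' @export
filter_and_trim_reads <- function(fastq_1, fastq_2 = NULL,
                                  out_1 = NULL, out_2 = NULL,
                                  max_n = 7L, q_threshold = 20L,
                                  window = 5L, min_low = 3L,
                                  min_length = 41L) {
  fq1 <- ShortRead::readFastq(fastq_1)
  fq2 <- if (!is.null(fastq_2)) ShortRead::readFastq(fastq_2) else NULL
  check_fq <- function(fq, path) {
    wq <- BiocGenerics::width(Biostrings::quality(fq))
    ws <- BiocGenerics::width(ShortRead::sread(fq))
    if (any(wq != ws)) {
      bad <- as.character(ShortRead::id(fq))[which(wq != ws)[1]]
      abort(sprintf("Sequence/quality length mismatch in %s (read %s).", path, bad))
    }
  }
  check_fq(fq1, fastq_1)
  if (!is.null(fq2)) {
    check_fq(fq2, fastq_2)
    if (length(fq1) != length(fq2)) abort("Mate FASTQ files differ in read count.")
  }
  n_input <- length(fq1)

  n_count <- function(fq) {
    as.integer(Biostrings::letterFrequency(ShortRead::sread(fq), "N"))
  }
  many_n <- n_count(fq1) >= max_n
  if (!is.null(fq2)) many_n <- many_n | (n_count(fq2) >= max_n)
  fq1 <- fq1[!many_n]
  if (!is.null(fq2)) fq2 <- fq2[!many_n]

  trim_lengths <- function(fq) {
    qm <- as(Biostrings::quality(fq), "matrix")
    lens <- BiocGenerics::width(fq)
    vapply(seq_along(lens), function(i) {
      L <- lens[i]
      if (L < window) return(L)
      low <- qm[i, seq_len(L)] < q_threshold
      cs <- cumsum(low)
      wins <- cs[window:L] - c(0, cs[seq_len(L - window)])
      hit <- which(wins >= min_low)
      if (length(hit)) hit[1] - 1L else L
    }, integer(1))
  }

  kept1_len <- if (length(fq1)) trim_lengths(fq1) else integer(0)
  kept2_len <- if (!is.null(fq2) && length(fq2)) trim_lengths(fq2) else NULL
  n_trimmed <- sum(kept1_len < BiocGenerics::width(fq1)) +
    if (!is.null(kept2_len)) sum(kept2_len < BiocGenerics::width(fq2)) else 0L

  short <- kept1_len < min_length
  if (!is.null(kept2_len)) short <- short | (kept2_len < min_length)

  trim1 <- IRanges::narrow(fq1[!short], start = 1L, end = kept1_len[!short])
  trim2 <- if (!is.null(fq2)) {
    IRanges::narrow(fq2[!short], start = 1L, end = kept2_len[!short])
  } else NULL

  if (!is.null(out_1)) ShortRead::writeFastq(trim1, out_1, compress = FALSE, mode = "w")
  if (!is.null(out_2) && !is.null(trim2)) {
    ShortRead::writeFastq(trim2, out_2, compress = FALSE, mode = "w")
  }

  out <- tibble(
    id = sub(" .*", "", as.character(ShortRead::id(trim1))),
    length_1 = BiocGenerics::width(trim1),
    length_2 = if (!is.null(trim2)) BiocGenerics::width(trim2) else NA_integer_
  )
  attr(out, "report") <- tibble(
    n_input = n_input,
    n_dropped_n = sum(many_n),
    n_trimmed = as.integer(n_trimmed),
    n_dropped_short = sum(short),
    n_kept = nrow(out)
  )
  out
}
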