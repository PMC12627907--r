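#' Positional C-to-T substitution profile at read ends
#'
#' Post-mortem deamination converts cytosine to uracil, read as thymine, with
#' rates concentrated at fragment ends. For each offset i from the read's 5'
#' end (1-based, up to `max_pos`), the rate is the fraction of reads carrying
#' T where the reference has C, among reads whose reference base at that
#' offset is C. Reads are oriented before counting: a minus-strand alignment
#' contributes reference G-to-read A on the plus strand as a C-to-T
#' observation. Positions with zero reference-C observations get NA, not 0.
#' Run this on untrimmed reads (the 5 bp end trim comes after profiling);
#' gapped alignments are skipped.
#'
#' @param reads reads data.frame (sequences stored plus-strand, as in SAM).
#' @param reference [Biostrings::DNAStringSet] or FASTA path.
#' @param max_pos largest 5' offset profiled (default 25).
#' @param end profile the 5' (default) or 3' read end.
#' @param dedup exclude duplicate-flagged reads (default TRUE).
#' @return A `damage_profile` data.frame: position, n_ref_c, n_ct, ct_rate;
#'   attribute `first_base_rate` holds the headline position-1 rate.
#' @export
ct_profile <- function(reads, reference, max_pos = 25L, end = c("5p", "3p"),
                       dedup = TRUE) {
  end <- match.arg(end)
  assert_count(max_pos, "max_pos", min = 1)
  validate_reads(reads)
  if (is.character(reference) && length(reference) == 1L)
    reference <- readDNAStringSet(reference)
  use <- reads$mapped & (!dedup | !reads$duplicate) &
    nchar(reads$seq) == (reads$end - reads$start + 1L)  # ungapped only
  r <- reads[use, , drop = FALSE]
  n_ref_c <- integer(max_pos)
  n_ct <- integer(max_pos)
  if (nrow(r) > 0L) {
    gr <- GRanges(r$chrom, IRanges(r$start, r$end))
    refseq <- as.character(extract_ref_seqs(gr, reference))
    readseq <- r$seq
    # orient both to the read's own 5'->3' direction
    minus <- r$strand == "-"
    refseq[minus] <- revcomp_chr(refseq[minus])
    readseq[minus] <- revcomp_chr(readseq[minus])
    if (end == "3p") {
      refseq <- revstr(refseq)
      readseq <- revstr(readseq)
    }
    len <- nchar(readseq)
    for (i in seq_len(max_pos)) {
      ok <- len >= i
      rb <- substr(refseq[ok], i, i)
      qb <- substr(readseq[ok], i, i)
      is_c <- rb == "C"
      n_ref_c[i] <- sum(is_c)
      n_ct[i] <- sum(is_c & qb == "T")
    }
  }
  out <- data.frame(
    position = seq_len(max_pos),
    n_ref_c = n_ref_c,
    n_ct = n_ct,
    ct_rate = ifelse(n_ref_c > 0, n_ct / n_ref_c, NA_real_)
  )
  attr(out, "first_base_rate") <- out$ct_rate[1L]
  attr(out, "end") <- end
  class(out) <- c("damage_profile", "data.frame")
  out
}

revstr <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Fit an exponential decay to a damage profile
#'
#' Maximum-likelihood fit of `rate(i) = d0 * exp(-lambda * (i - 1))` via a
#' binomial GLM with a log link on the positional substitution counts;
#' positions with zero reference-C observations are dropped (zero-substitution
#' positions are informative and kept).
#'
#' @param profile a `damage_profile` from [ct_profile()].
#' @return list with `d0` and `lambda` estimates.
#' @export
fit_damage_decay <- function(profile) {
  ok <- profile$n_ref_c > 0
  if (sum(ok) < 2L) stop2("need at least two informative positions to fit")
  x <- profile$position[ok] - 1
  k <- profile$n_ct[ok]
  n <- profile$n_ref_c[ok]
  # moment start: intercept from the first informative rate, slope from the
  # decay over the profiled range
  rate <- (k + 0.5) / (n + 1)
  s0 <- log(rate[1L])
  s1 <- if (length(x) > 1L) {
    min((log(rate[length(rate)]) - log(rate[1L])) / (x[length(x)] - x[1L]), 0)
  } else -0.1
  fit <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ x,
               family = stats::binomial(link = "log"), start = c(s0, s1))
  )
  list(d0 = unname(exp(coef(fit)[1])), lambda = unname(-coef(fit)[2]))
}

#' Read length summaries
#'
#' Mean, median and a histogram of aligned read lengths over mapped reads.
#'
#' @param reads reads data.frame.
#' @param dedup exclude duplicate-flagged reads.
#' @return list with `n`, `mean`, `median` and `histogram` (a table of
#'   lengths).
#' @export
read_length_stats <- function(reads, dedup = FALSE) {
  validate_reads(reads)
  use <- reads$mapped & (!dedup | !reads$duplicate)
  len <- reads$end[use] - reads$start[use] + 1L
  list(
    n = length(len),
    mean = if (length(len)) mean(len) else NA_real_,
    median = if (length(len)) stats::median(len) else NA_real_,
    histogram = table(len)
  )
}
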