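#' Tile target intervals into fixed-width GC windows
#'
#' Each target interval is tiled end-to-end with non-overlapping windows of
#' `window` bp starting at the interval start; partial trailing windows are
#' dropped. Every window is assigned an integer GC bin
#' `round(100 * GC fraction)` computed over A/C/G/T (N ignored); all-N
#' windows are excluded and counted.
#'
#' @param targets GRanges of target intervals (e.g. the `comparable` set of a
#'   [comparable_partition()]).
#' @param reference [Biostrings::DNAStringSet] or FASTA path.
#' @param window window width in bp (default 80).
#' @return list with `windows` (GRanges carrying a `bin` metadata column) and
#'   `n_excluded` (all-N windows removed).
#' @export
window_gc_bins <- function(targets, reference, window = 80L) {
  assert_count(window, "window", min = 1)
  if (is(targets, "comparable_partition")) targets <- targets$comparable
  n_win <- width(targets) %/% window
  keep <- n_win > 0L
  targets <- targets[keep]
  n_win <- n_win[keep]
  if (length(targets) == 0L)
    return(list(windows = GRanges(), n_excluded = 0L))
  starts <- unlist(lapply(seq_along(targets), function(i) {
    start(targets)[i] + window * (seq_len(n_win[i]) - 1L)
  }))
  chroms <- rep(as.character(seqnames(targets)), n_win)
  win <- GRanges(chroms, IRanges(starts, width = window))
  bins <- gc_bins_of(win, reference)
  mcols(win)$bin <- bins
  list(windows = win[!is.na(bins)], n_excluded = sum(is.na(bins)))
}

#' Per-GC-bin window and read counts
#'
#' Credits each mapped read to the window containing its crediting position —
#' by default the 5' alignment start (leftmost base for plus-strand reads,
#' rightmost for minus-strand), optionally the alignment midpoint — and
#' tabulates windows and reads per GC bin. Reads whose crediting position
#' falls in no window are ignored and counted.
#'
#' @param reads reads data.frame (mapped reads are used; pass on-target reads
#'   for a Picard-style target GC profile).
#' @param windows window GRanges from [window_gc_bins()] (or the list it
#'   returns).
#' @param credit crediting rule, `"start"` (5' end) or `"midpoint"`.
#' @return A `gc_bin_table` data.frame with columns bin (0..100), n_windows,
#'   read_count, pct_windows, pct_reads, normalized_coverage, plus attributes
#'   `n_outside` (reads outside all windows) and `empty` (no usable reads:
#'   normalized coverage undefined, all NA).
#' @export
gc_bin_read_counts <- function(reads, windows, credit = c("start", "midpoint")) {
  credit <- match.arg(credit)
  if (is.list(windows) && !is(windows, "GRanges")) windows <- windows$windows
  validate_reads(reads)
  m <- reads[reads$mapped, , drop = FALSE]
  pos <- switch(credit,
    start = ifelse(m$strand == "-", m$end, m$start),
    midpoint = (m$start + m$end) %/% 2L
  )
  tab <- data.frame(bin = 0:100,
                    n_windows = tabulate2(mcols(windows)$bin, 0:100),
                    read_count = 0)
  n_outside <- 0L
  if (nrow(m) > 0L && length(windows) > 0L) {
    p <- GRanges(m$chrom, IRanges(pos, pos))
    hits <- findOverlaps(p, windows, select = "first")
    n_outside <- sum(is.na(hits))
    hit_bins <- mcols(windows)$bin[hits[!is.na(hits)]]
    tab$read_count <- tabulate2(hit_bins, 0:100)
  } else {
    n_outside <- nrow(m)
  }
  finish_gc_table(tab, n_outside)
}

tabulate2 <- function(x, levels) {
  as.numeric(table(factor(x, levels = levels)))
}

# canonical integer GC bin: round(100 * (G+C) / (A+C+G+T)), from integer
# counts (all-N sequences give NA)
gc_bins_of <- function(gr, reference) {
  seqs <- extract_ref_seqs(gr, reference)
  counts <- letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(counts)
  gc <- counts[, "C"] + counts[, "G"]
  ifelse(acgt == 0, NA_integer_, as.integer(round(100 * gc / acgt)))
}

finish_gc_table <- function(tab, n_outside = 0L) {
  tot_w <- sum(tab$n_windows)
  tot_r <- sum(tab$read_count)
  tab$pct_windows <- if (tot_w > 0) 100 * tab$n_windows / tot_w else NA_real_
  tab$pct_reads <- if (tot_r > 0) 100 * tab$read_count / tot_r else NA_real_
  tab$normalized_coverage <- if (tot_w > 0 && tot_r > 0) {
    ifelse(tab$n_windows > 0,
           (tab$read_count / tab$n_windows) / (tot_r / tot_w),
           NA_real_)
  } else NA_real_
  attr(tab, "n_outside") <- n_outside
  attr(tab, "empty") <- !(tot_w > 0 && tot_r > 0)
  class(tab) <- c("gc_bin_table", "data.frame")
  tab
}

#' Normalized coverage per GC bin
#'
#' Ratio of each bin's coverage (reads per window) to the mean coverage over
#' all bins (total reads / total windows); 1 represents the mean. Provided
#' for tables built elsewhere; [gc_bin_read_counts()] already fills the
#' column.
#'
#' @param table a `gc_bin_table` (or data.frame with bin, n_windows,
#'   read_count).
#' @return the table with pct_windows, pct_reads and normalized_coverage
#'   recomputed.
#' @export
normalized_coverage <- function(table) {
  finish_gc_table(table[c("bin", "n_windows", "read_count")],
                  attr(table, "n_outside") %||% 0L)
}

#' AT and GC dropout
#'
#' AT dropout is the sum of positive differences between the percentage of
#' reference windows and the percentage of mapped reads over GC bins 0..50;
#' GC dropout is the same sum over bins 50..100. Bin 50 belongs to both
#' ranges by default (`split_bin_50 = FALSE`); the exclusive alternative
#' assigns bin 50 to the AT side only.
#'
#' @param table a `gc_bin_table`.
#' @param split_bin_50 if TRUE, bin 50 is counted only in the AT sum.
#' @return named numeric vector `c(at_dropout =, gc_dropout =)`, in percent.
#' @export
gc_dropout_metrics <- function(table, split_bin_50 = FALSE) {
  if (isTRUE(attr(table, "empty")) || anyNA(table$pct_windows) ||
      anyNA(table$pct_reads))
    return(c(at_dropout = NA_real_, gc_dropout = NA_real_))
  diffs <- pmax(0, table$pct_windows - table$pct_reads)
  at_bins <- table$bin <= 50
  gc_bins <- if (split_bin_50) table$bin > 50 else table$bin >= 50
  c(at_dropout = sum(diffs[at_bins]), gc_dropout = sum(diffs[gc_bins]))
}

#' @rdname gc_dropout_metrics
#' @export
at_dropout <- function(table, split_bin_50 = FALSE) {
  unname(gc_dropout_metrics(table, split_bin_50)["at_dropout"])
}

#' @rdname gc_dropout_metrics
#' @export
gc_dropout <- function(table, split_bin_50 = FALSE) {
  unname(gc_dropout_metrics(table, split_bin_50)["gc_dropout"])
}
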