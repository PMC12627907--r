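# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Reverse-complement a character vector of DNA sequences
#' @noRd
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# phred qualities encoded with the Sanger +33 offset
qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

assert_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1)
    stop2(sprintf("'%s' must be a single value in %s", name,
                  if (allow_zero) "[0, 1]" else "(0, 1]"))
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop2(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(x)
}

# empty reads data.frame with the canonical column set (SAM-like, 1-based)
empty_reads <- function() {
  data.frame(
    qname = character(), mapped = logical(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    mapq = integer(), seq = character(), qual = character(),
    duplicate = logical(), stringsAsFactors = FALSE
  )
}

validate_reads <- function(reads) {
  needed <- names(empty_reads())
  miss <- setdiff(needed, names(reads))
  if (length(miss))
    stop2("reads table is missing columns: ", paste(miss, collapse = ", "))
  m <- reads$mapped
  if (any(m & (is.na(reads$chrom) | reads$start > reads$end)))
    stop2("mapped reads must carry chrom and start <= end")
  invisible(reads)
}

reads_granges <- function(reads) {
  m <- reads[reads$mapped, , drop = FALSE]
  GRanges(m$chrom, IRanges(m$start, m$end), strand = m$strand)
}
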