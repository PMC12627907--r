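# shared in-code fixtures: toy reads, panels and references built per test run

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

mk_read <- function(qname, chrom = "chr1", start = 1L, seq = "ACGT",
                    strand = "+", mapq = 37L, dup = FALSE, qual = NULL,
                    mapped = TRUE) {
  len <- nchar(seq)
  if (is.null(qual)) qual <- strrep("I", len)  # Q40
  data.frame(
    qname = qname, mapped = mapped,
    chrom = if (mapped) chrom else NA_character_,
    start = if (mapped) as.integer(start) else NA_integer_,
    end = if (mapped) as.integer(start + len - 1L) else NA_integer_,
    strand = if (mapped) strand else NA_character_,
    mapq = as.integer(mapq), seq = seq, qual = qual, duplicate = dup,
    stringsAsFactors = FALSE
  )
}

mk_reads <- function(...) do.call(rbind, list(...))

# two-panel fixture: myBaits-style 121 bp and Twist-style 80 bp footprints
# around shared SNPs at the given positions (1-based), plus optional sites
# unique to panel B
toy_panels <- function(shared_pos = c(1000L, 3000L), b_only_pos = integer(),
                       chrom = "chr1") {
  mk_sites <- function(pos, prefix, start_i = 1L) {
    data.frame(chrom = chrom, pos = pos,
               allele1 = "A", allele2 = "G",
               snp_id = sprintf("%s%03d", prefix, seq_along(pos) + start_i - 1L),
               stringsAsFactors = FALSE)
  }
  sa <- mk_sites(shared_pos, "s")
  sb <- rbind(sa, if (length(b_only_pos)) mk_sites(b_only_pos, "b"))
  list(
    a = derive_target_intervals(sa, design_mybaits()),
    b = derive_target_intervals(sb, design_twist())
  )
}

toy_partition <- function(...) {
  p <- toy_panels(...)
  comparable_partition(p$a, p$b)
}

# reference with a fixed repeating pattern, as a named DNAStringSet
toy_reference <- function(len = 5000L, chroms = "chr1", pattern = "ACGT") {
  s <- strrep(pattern, ceiling(len / nchar(pattern)))
  ref <- Biostrings::DNAStringSet(rep(substr(s, 1L, len), length(chroms)))
  names(ref) <- chroms
  ref
}

# plain-R reverse complement, independent of Biostrings (oracle helper)
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
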