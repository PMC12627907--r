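#' Read an alignment file into a reads table
#'
#' Accepts SAM or BAM (SAM is converted on the fly with Rsamtools). Returns a
#' plain data.frame, one row per record, with 1-based inclusive coordinates,
#' the sequence and qualities as stored (reference plus strand), and the SAM
#' duplicate flag.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns qname, mapped, chrom, start, end, strand,
#'   mapq, seq, qual, duplicate.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(asBam(path, destination = dest,
                                  overwrite = TRUE, indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "qwidth", "mapq", "cigar",
            "strand", "seq", "qual")
  res <- scanBam(bam, param = ScanBamParam(what = what))[[1]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  n <- length(flag)
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  width <- cigar_ref_width(res$cigar, nchar(seqs))
  out <- data.frame(
    qname = res$qname,
    mapped = mapped,
    chrom = ifelse(mapped, as.character(res$rname), NA_character_),
    start = ifelse(mapped, res$pos, NA_integer_),
    end = ifelse(mapped, res$pos + width - 1L, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    mapq = res$mapq,
    seq = seqs,
    qual = quals,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    stringsAsFactors = FALSE
  )
  validate_reads(out)
}

# reference span consumed by a cigar; M/D/N/=/X consume reference
cigar_ref_width <- function(cigar, fallback) {
  w <- fallback
  has <- !is.na(cigar) & cigar != "*"
  if (any(has)) {
    ops <- regmatches(cigar[has], gregexpr("[0-9]+[MIDNSHP=X]", cigar[has]))
    w[has] <- vapply(ops, function(o) {
      len <- as.integer(sub("[MIDNSHP=X]", "", o))
      op <- sub("[0-9]+", "", o)
      sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  w
}

#' Write a reads table as SAM
#'
#' Emits a minimal, valid single-end SAM with ungapped CIGARs; unmapped reads
#' get flag 4, minus-strand reads flag 16, duplicates flag 1024.
#'
#' @param reads reads data.frame (see [read_alignments()]).
#' @param path output `.sam` path.
#' @param seqlengths named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, seqlengths) {
  validate_reads(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  flag <- ifelse(reads$mapped, 0L, 4L)
  flag <- flag + ifelse(reads$mapped & reads$strand == "-", 16L, 0L)
  flag <- flag + ifelse(reads$duplicate, 1024L, 0L)
  body <- paste(
    reads$qname, flag,
    ifelse(reads$mapped, reads$chrom, "*"),
    ifelse(reads$mapped, reads$start, 0L),
    ifelse(reads$mapped, reads$mapq, 0L),
    ifelse(reads$mapped, paste0(nchar(reads$seq), "M"), "*"),
    "*", 0L, 0L, reads$seq, reads$qual,
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify reads against a comparable partition
#'
#' Each read gets exactly one class: `unmapped`; `mito` (aligned to a
#' mitochondrial contig); `on_comparable` (>= `min_overlap` bp overlap with a
#' comparable interval); `on_noncomparable` (same against either
#' noncomparable set); otherwise `off_target`. Precedence is
#' mito > comparable > noncomparable > off-target, so a read spanning both a
#' comparable and a noncomparable interval counts once, as comparable.
#'
#' @param reads reads data.frame.
#' @param partition a `comparable_partition`.
#' @param mito_names character vector of mitochondrial contig names.
#' @param min_overlap minimum overlap in bp to call a read on-target
#'   (default 1).
#' @param known_contigs optional character vector of valid contig names;
#'   mapped reads on other contigs raise an error.
#' @return factor of classes, one per read, levels
#'   c("unmapped","mito","on_comparable","on_noncomparable","off_target").
#' @export
classify_reads <- function(reads, partition, mito_names = "chrM",
                           min_overlap = 1L, known_contigs = NULL) {
  validate_reads(reads)
  stopifnot(is(partition, "comparable_partition"))
  lv <- c("unmapped", "mito", "on_comparable", "on_noncomparable", "off_target")
  cls <- factor(rep("off_target", nrow(reads)), levels = lv)
  if (nrow(reads) == 0L) return(cls)
  cls[!reads$mapped] <- "unmapped"
  m <- which(reads$mapped)
  if (!is.null(known_contigs)) {
    bad <- setdiff(unique(reads$chrom[m]), known_contigs)
    if (length(bad))
      stop2("reads aligned to contigs absent from the reference naming map: ",
            paste(bad, collapse = ", "))
  }
  if (length(m) == 0L) return(cls)
  gr <- GRanges(reads$chrom[m], IRanges(reads$start[m], reads$end[m]))
  is_mito <- as.character(seqnames(gr)) %in% mito_names
  hit_comp <- overlapsAny(gr, partition$comparable, minoverlap = min_overlap)
  noncomp <- c(granges(partition$noncomparable_a),
               granges(partition$noncomparable_b))
  hit_non <- overlapsAny(gr, noncomp, minoverlap = min_overlap)
  k <- ifelse(is_mito, "mito",
              ifelse(hit_comp, "on_comparable",
                     ifelse(hit_non, "on_noncomparable", "off_target")))
  cls[m] <- k
  cls
}

#' Mark PCR duplicates by alignment coordinates
#'
#' Among mapped reads sharing (chrom, start, end, strand), the first record
#' in file order is kept as the unique molecule and the rest are flagged.
#' Unmapped reads are never flagged.
#'
#' @param reads reads data.frame.
#' @return the reads table with the `duplicate` column rewritten.
#' @export
mark_duplicates <- function(reads) {
  validate_reads(reads)
  reads$duplicate <- FALSE
  m <- which(reads$mapped)
  if (length(m)) {
    key <- paste(reads$chrom[m], reads$start[m], reads$end[m], reads$strand[m])
    reads$duplicate[m] <- duplicated(key)
  }
  reads
}

#' Tally a sample's reads into the counts feeding all ratio metrics
#'
#' @param reads reads data.frame.
#' @param partition a `comparable_partition`.
#' @param mito_names mitochondrial contig names.
#' @param total_raw total raw (sequenced) reads, including unmapped and
#'   adapter-only reads; cannot be recovered from a mapped-only alignment
#'   file, so it must be supplied (use the simulator truth or the FASTQ read
#'   count). Defaults to `nrow(reads)` when the table contains unmapped
#'   records too.
#' @param min_overlap see [classify_reads()].
#' @param redetect_duplicates if TRUE, ignore existing duplicate flags and
#'   re-mark by coordinates ([mark_duplicates()]); by default flags present
#'   in the input are trusted.
#' @return A `sample_counts` list: total_raw, total_mapped, mapped_dedup,
#'   on_comparable, on_comparable_dedup, on_noncomparable, mito, off_target.
#'   The class conservation identity
#'   on_comparable + on_noncomparable + mito + off_target == total_mapped
#'   holds exactly.
#' @export
tally_sample <- function(reads, partition, mito_names = "chrM",
                         total_raw = nrow(reads), min_overlap = 1L,
                         redetect_duplicates = FALSE) {
  validate_reads(reads)
  if (redetect_duplicates) reads <- mark_duplicates(reads)
  cls <- classify_reads(reads, partition, mito_names, min_overlap)
  total_mapped <- sum(reads$mapped)
  if (total_raw < total_mapped)
    stop2("total_raw (", total_raw, ") < total mapped reads (", total_mapped, ")")
  dup <- reads$duplicate
  counts <- list(
    total_raw = as.numeric(total_raw),
    total_mapped = as.numeric(total_mapped),
    mapped_dedup = as.numeric(sum(reads$mapped & !dup)),
    on_comparable = as.numeric(sum(cls == "on_comparable")),
    on_comparable_dedup = as.numeric(sum(cls == "on_comparable" & !dup)),
    on_noncomparable = as.numeric(sum(cls == "on_noncomparable")),
    on_noncomparable_dedup = as.numeric(sum(cls == "on_noncomparable" & !dup)),
    mito = as.numeric(sum(cls == "mito")),
    off_target = as.numeric(sum(cls == "off_target"))
  )
  structure(counts, class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("sample_counts:\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Trim bases from both ends of mapped reads
#'
#' Shortens sequence, qualities and alignment span by `n_bases` at each end
#' (the standard pre-genotyping step for damaged libraries; damage profiling
#' runs on untrimmed reads). Reads with length <= 2 * n_bases are dropped and
#' counted.
#'
#' @param reads reads data.frame.
#' @param n_bases bases to remove from each end (default 5).
#' @return list with `reads` (trimmed table) and `n_dropped`.
#' @export
trim_read_ends <- function(reads, n_bases = 5L) {
  validate_reads(reads)
  assert_count(n_bases, "n_bases", min = 0)
  if (n_bases == 0L) return(list(reads = reads, n_dropped = 0L))
  len <- nchar(reads$seq)
  keep <- !reads$mapped | len > 2L * n_bases
  out <- reads[keep, , drop = FALSE]
  m <- out$mapped
  out$seq[m] <- substr(out$seq[m], n_bases + 1L, nchar(out$seq[m]) - n_bases)
  out$qual[m] <- substr(out$qual[m], n_bases + 1L, nchar(out$qual[m]) - n_bases)
  out$start[m] <- out$start[m] + n_bases
  out$end[m] <- out$end[m] - n_bases
  list(reads = out, n_dropped = sum(!keep))
}
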