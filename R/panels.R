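#' Probe design geometry
#'
#' Describes how one commercial probe set tiles a SNP: the probe length, the
#' total footprint covered per SNP, the number of probes (tiling) and the
#' 1-based position of the SNP within the footprint. Two canned geometries are
#' provided: [design_mybaits()] (four 60 bp ssRNA probes covering 121 bp, SNP
#' centred at offset 61) and [design_twist()] (a single 80 bp dsDNA probe
#' covering 80 bp, SNP at offset 41; the even footprint forces the asymmetry).
#'
#' @param name design label.
#' @param probe_length probe length in bp.
#' @param footprint_length total covered span per SNP in bp.
#' @param tiling number of probes per SNP.
#' @param snp_offset 1-based position of the SNP within the footprint.
#' @return An object of class `probe_design`.
#' @export
probe_design <- function(name, probe_length, footprint_length, tiling = 1L,
                         snp_offset = NULL) {
  assert_count(probe_length, "probe_length", min = 1)
  assert_count(footprint_length, "footprint_length", min = 1)
  assert_count(tiling, "tiling", min = 1)
  if (footprint_length < probe_length)
    stop2("footprint_length must be >= probe_length")
  if (is.null(snp_offset)) snp_offset <- (footprint_length + 1L) %/% 2L
  assert_count(snp_offset, "snp_offset", min = 1)
  if (snp_offset > footprint_length)
    stop2("snp_offset must lie within the footprint")
  structure(
    list(name = name, probe_length = as.integer(probe_length),
         footprint_length = as.integer(footprint_length),
         tiling = as.integer(tiling), snp_offset = as.integer(snp_offset)),
    class = "probe_design"
  )
}

#' @rdname probe_design
#' @export
design_mybaits <- function() {
  probe_design("myBaits", probe_length = 60L, footprint_length = 121L,
               tiling = 4L, snp_offset = 61L)
}

#' @rdname probe_design
#' @export
design_twist <- function() {
  probe_design("Twist", probe_length = 80L, footprint_length = 80L,
               tiling = 1L, snp_offset = 41L)
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("probe_design '%s': %d x %d bp probes, %d bp footprint, SNP at offset %d\n",
              x$name, x$tiling, x$probe_length, x$footprint_length, x$snp_offset))
  invisible(x)
}

#' Validate a table of SNP sites
#'
#' @param df data.frame with columns `chrom`, `pos` (1-based), `allele1`,
#'   `allele2`, `snp_id`.
#' @return The validated data.frame, sorted by (chrom, pos).
#' @export
snp_sites <- function(df) {
  needed <- c("chrom", "pos", "allele1", "allele2", "snp_id")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop2("SNP table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[needed]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (col in c("allele1", "allele2"))
    df[[col]] <- toupper(as.character(df[[col]]))
  df$snp_id <- as.character(df$snp_id)
  if (nrow(df) == 0L) {
    warning("SNP site table is empty")
    return(df)
  }
  bad <- !(df$allele1 %in% DNA_BASES) | !(df$allele2 %in% DNA_BASES)
  if (any(bad))
    stop2("alleles must be A/C/G/T (rows: ", paste(which(bad), collapse = ", "), ")")
  if (any(df$allele1 == df$allele2))
    stop2("allele1 and allele2 must differ (rows: ",
          paste(which(df$allele1 == df$allele2), collapse = ", "), ")")
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop2("pos must be a 1-based positive coordinate")
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop2("duplicate sites at: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop2("duplicate snp_id values")
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Read SNP sites from a tab-separated file
#'
#' Expected columns: chrom, pos (1-based), allele1, allele2, snp_id. A header
#' line is detected automatically.
#'
#' @param path file path.
#' @return data.frame of validated sites (see [snp_sites()]).
#' @export
load_snp_sites <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("chrom", first, fixed = TRUE)
  if (length(first) == 0L) {
    warning("SNP site file '", path, "' is empty")
    return(suppressWarnings(
      snp_sites(data.frame(chrom = character(), pos = integer(),
                           allele1 = character(), allele2 = character(),
                           snp_id = character()))))
  }
  df <- tryCatch(
    read.delim(path, header = has_header, stringsAsFactors = FALSE),
    error = function(e) stop2("failed to parse '", path, "': ", conditionMessage(e))
  )
  if (nrow(df) == 0L) {
    warning("SNP site file '", path, "' is empty")
    return(suppressWarnings(
      snp_sites(data.frame(chrom = character(), pos = integer(),
                           allele1 = character(), allele2 = character(),
                           snp_id = character()))))
  }
  if (!has_header) {
    if (ncol(df) < 5L)
      stop2("'", path, "' must have 5 columns: chrom pos allele1 allele2 snp_id")
    names(df)[1:5] <- c("chrom", "pos", "allele1", "allele2", "snp_id")
  }
  pos_num <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos_num))
    stop2("malformed pos field at line ",
          which(is.na(pos_num))[1L] + has_header, " of '", path, "'")
  df$pos <- pos_num
  snp_sites(df)
}

#' Derive per-SNP target intervals for a probe design
#'
#' For a SNP at 1-based position p, a footprint of length F with the SNP at
#' offset k covers the 1-based interval \[p - k + 1, p - k + F\] (equivalently
#' \[p - k, p - k + F) in BED coordinates). Intervals running past the start
#' or end of a contig are clipped and flagged.
#'
#' @param sites validated SNP table (see [snp_sites()]).
#' @param design a [probe_design()].
#' @param seqlengths optional named vector of contig lengths used for clipping
#'   at the right edge.
#' @param name panel name; defaults to the design name.
#' @return A `probe_panel`: list with `name`, `design`, `sites` and
#'   `intervals` (a [GenomicRanges::GRanges] with `snp_id` and `clipped`
#'   metadata columns, sorted by position, one interval per site).
#' @export
derive_target_intervals <- function(sites, design, seqlengths = NULL,
                                    name = design$name) {
  stopifnot(is(design, "probe_design"))
  sites <- snp_sites(sites)
  if (nrow(sites) == 0L) {
    gr <- GRanges()
    mcols(gr)$snp_id <- character()
    mcols(gr)$clipped <- logical()
    return(structure(list(name = name, design = design, sites = sites,
                          intervals = gr), class = "probe_panel"))
  }
  start1 <- sites$pos - design$snp_offset + 1L
  end1 <- start1 + design$footprint_length - 1L
  clipped <- start1 < 1L
  start1 <- pmax(start1, 1L)
  if (!is.null(seqlengths)) {
    lens <- seqlengths[sites$chrom]
    over <- !is.na(lens) & end1 > lens
    clipped <- clipped | over
    end1 <- ifelse(over, lens, end1)
  }
  if (any(clipped))
    warning(sum(clipped), " footprint(s) clipped at contig boundaries")
  gr <- GRanges(sites$chrom, IRanges(as.integer(start1), as.integer(end1)))
  if (!is.null(seqlengths)) {
    sl <- seqlengths[seqlevels(gr)]
    if (!anyNA(sl)) seqlengths(gr) <- sl
  }
  mcols(gr)$snp_id <- sites$snp_id
  mcols(gr)$clipped <- clipped
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  structure(list(name = name, design = design, sites = sites, intervals = gr),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel '%s': %d SNPs, %d bp footprints\n",
              x$name, nrow(x$sites), x$design$footprint_length))
  invisible(x)
}

#' Partition two panels into comparable and noncomparable targets
#'
#' SNPs shared by both panels contribute their footprints' geometric
#' intersection to the comparable set; SNPs unique to one panel contribute
#' that panel's interval to its noncomparable set. Shared snp_ids must agree
#' on chrom and position.
#'
#' @param panel_a,panel_b `probe_panel` objects on the same reference naming.
#' @return A `comparable_partition`: list of GRanges `comparable`,
#'   `noncomparable_a`, `noncomparable_b`, plus the two panel names.
#' @export
comparable_partition <- function(panel_a, panel_b) {
  stopifnot(is(panel_a, "probe_panel"), is(panel_b, "probe_panel"))
  sa <- panel_a$sites; sb <- panel_b$sites
  shared <- intersect(sa$snp_id, sb$snp_id)
  if (length(shared)) {
    ka <- sa[match(shared, sa$snp_id), ]
    kb <- sb[match(shared, sb$snp_id), ]
    bad <- ka$chrom != kb$chrom | ka$pos != kb$pos
    if (any(bad))
      stop2("shared snp_id with inconsistent coordinates: ",
            paste(shared[bad], collapse = ", "))
  }
  ia <- panel_a$intervals; ib <- panel_b$intervals
  a_shared <- ia[mcols(ia)$snp_id %in% shared]
  b_shared <- ib[match(mcols(a_shared)$snp_id, mcols(ib)$snp_id)]
  comparable <- if (length(a_shared)) {
    gr <- pintersect(granges(a_shared), granges(b_shared))
    mcols(gr)$snp_id <- mcols(a_shared)$snp_id
    gr[width(gr) > 0L]
  } else {
    gr <- GRanges(); mcols(gr)$snp_id <- character(); gr
  }
  non_a <- ia[!(mcols(ia)$snp_id %in% shared)]
  non_b <- ib[!(mcols(ib)$snp_id %in% shared)]
  structure(
    list(comparable = comparable,
         noncomparable_a = non_a, noncomparable_b = non_b,
         panel_a = panel_a$name, panel_b = panel_b$name),
    class = "comparable_partition"
  )
}

#' @export
print.comparable_partition <- function(x, ...) {
  cat(sprintf("comparable_partition: %d comparable, %d only-%s, %d only-%s\n",
              length(x$comparable), length(x$noncomparable_a), x$panel_a,
              length(x$noncomparable_b), x$panel_b))
  invisible(x)
}

#' Build a single-panel partition
#'
#' Treats one panel's full footprints as the comparable set with empty
#' noncomparable sets, the mode used to report per-original-panel efficiency.
#'
#' @param panel a `probe_panel`.
#' @return A `comparable_partition`.
#' @export
single_panel_partition <- function(panel) {
  stopifnot(is(panel, "probe_panel"))
  empty <- GRanges(); mcols(empty)$snp_id <- character()
  structure(
    list(comparable = panel$intervals, noncomparable_a = empty,
         noncomparable_b = empty, panel_a = panel$name, panel_b = panel$name),
    class = "comparable_partition"
  )
}

#' GC content of panel target intervals
#'
#' GC fraction per interval computed as (G+C)/(A+C+G+T), ignoring N; the panel
#' mean (in percent) excludes all-N intervals.
#'
#' @param panel a `probe_panel` or a GRanges of intervals.
#' @param reference a [Biostrings::DNAStringSet] (names matching contigs).
#' @return list with `per_interval` (fraction, NA for all-N), `mean_gc_pct`
#'   and `n_excluded`.
#' @export
panel_gc_content <- function(panel, reference) {
  gr <- if (is(panel, "probe_panel")) panel$intervals else panel
  if (length(gr) == 0L)
    return(list(per_interval = numeric(), mean_gc_pct = NA_real_, n_excluded = 0L))
  seqs <- extract_ref_seqs(gr, reference)
  counts <- letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(counts)
  gc <- (counts[, "C"] + counts[, "G"]) / ifelse(acgt == 0, NA_real_, acgt)
  list(per_interval = as.numeric(gc),
       mean_gc_pct = 100 * mean(gc, na.rm = TRUE),
       n_excluded = sum(is.na(gc)))
}

# subsequences of `reference` covered by GRanges `gr`
extract_ref_seqs <- function(gr, reference) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- readDNAStringSet(reference)
  chr <- as.character(seqnames(gr))
  missing_chr <- setdiff(unique(chr), names(reference))
  if (length(missing_chr))
    stop2("contigs absent from reference: ", paste(missing_chr, collapse = ", "))
  out <- DNAStringSet(rep("", length(gr)))
  for (ct in unique(chr)) {
    i <- which(chr == ct)
    out[i] <- DNAStringSet(reference[[ct]],
                           start = start(gr)[i], end = end(gr)[i])
  }
  out
}

#' Write and read panel intervals as BED
#'
#' BED is 0-based half-open; interval coordinates round-trip exactly. The
#' `snp_id` is stored in the BED name column.
#'
#' @param gr GRanges with an `snp_id` metadata column (or a `probe_panel`).
#' @param path output path.
#' @return `write_panel_bed` returns `path` invisibly; `read_panel_bed`
#'   returns a GRanges with `snp_id`.
#' @export
write_panel_bed <- function(gr, path) {
  if (is(gr, "probe_panel")) gr <- gr$intervals
  out <- granges(gr)
  mcols(out)$name <- mcols(gr)$snp_id
  mcols(out)$score <- 0L
  export(out, path, format = "BED")
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path) {
  gr <- import(path, format = "BED")
  out <- granges(gr)
  mcols(out)$snp_id <- mcols(gr)$name
  out
}
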