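#' On-target rate
#'
#' Percentage of reads mapped to comparable targets (duplicates included)
#' relative to all raw reads, after excluding reads mapped to noncomparable
#' targets from the denominator:
#' `100 * on_comparable / (total_raw - on_noncomparable)`.
#'
#' @param counts a `sample_counts` (see [tally_sample()]) or a list with the
#'   needed fields.
#' @return percentage, or NA when the denominator is zero.
#' @export
on_target_rate <- function(counts) {
  den <- counts$total_raw - counts$on_noncomparable
  if (!isTRUE(den > 0)) return(NA_real_)
  100 * counts$on_comparable / den
}

#' Target efficiency
#'
#' Percentage of reads mapped to comparable targets relative to all reads
#' mapped to the reference, after excluding noncomparable-target reads:
#' `100 * on_comparable / (total_mapped - on_noncomparable)`. With
#' `dedup = TRUE` both numerator and denominator use duplicate-removed
#' counts.
#'
#' @inheritParams on_target_rate
#' @param dedup use duplicate-removed counts.
#' @return percentage, or NA when the denominator is zero.
#' @export
target_efficiency <- function(counts, dedup = FALSE) {
  if (dedup) {
    num <- counts$on_comparable_dedup
    den <- counts$mapped_dedup - (counts$on_noncomparable_dedup %||%
                                    counts$on_noncomparable)
  } else {
    num <- counts$on_comparable
    den <- counts$total_mapped - counts$on_noncomparable
  }
  if (!isTRUE(den > 0)) return(NA_real_)
  100 * num / den
}

#' Fold enrichment of capture over shotgun sequencing
#'
#' Ratio of the target efficiency after enrichment to the target efficiency
#' of the corresponding shotgun library.
#'
#' @param te_captured,te_shotgun target efficiencies in percent.
#' @return the ratio, or NA (with a warning) when the shotgun efficiency is
#'   zero or missing.
#' @export
fold_enrichment <- function(te_captured, te_shotgun) {
  if (is.na(te_captured) || is.na(te_shotgun)) return(NA_real_)
  if (te_shotgun <= 0) {
    warning("shotgun target efficiency is zero; fold enrichment undefined")
    return(NA_real_)
  }
  te_captured / te_shotgun
}

#' Scenario-adjusted target efficiency
#'
#' Recomputes target efficiency after scaling the off-target read count and
#' multiplying the on-target read count, the what-if adjustment used to model
#' larger panels (more off-target capture) or denser probe tiling (more
#' on-target capture).
#'
#' @param counts a `sample_counts`; the noncomparable-excluded denominator is
#'   used, i.e. off-target reads are `total_mapped - on_noncomparable -
#'   on_comparable`.
#' @param off_target_scale multiplicative factor on off-target reads (> 0).
#' @param on_target_multiplier multiplicative factor on on-target reads (> 0).
#' @return adjusted efficiency in percent.
#' @export
scenario_adjusted_efficiency <- function(counts, off_target_scale = 1,
                                         on_target_multiplier = 1) {
  if (off_target_scale <= 0 || on_target_multiplier <= 0)
    stop2("scenario factors must be > 0")
  on <- counts$on_comparable * on_target_multiplier
  off <- (counts$total_mapped - counts$on_noncomparable -
            counts$on_comparable) * off_target_scale
  den <- on + off
  if (!isTRUE(den > 0)) return(NA_real_)
  100 * on / den
}

#' Expected genomic coverage of a library
#'
#' Indirect estimate of the coverage a library could yield if sequenced
#' exhaustively: the qPCR-quantified number of library molecules, scaled by
#' the endogenous (mappable) fraction and the mean mapped read length,
#' divided by the genome length, times the fraction of the library volume
#' actually used in the capture reaction:
#' `qpcr_mol * (mapped_reads / total_reads) * mean_read_length /
#' genome_length * volume_fraction`.
#'
#' @param qpcr_mol total library molecules by qPCR.
#' @param mapped_reads,total_reads read counts from shallow shotgun QC.
#' @param mean_read_length mean mapped read length (bp).
#' @param genome_length genome size in bp (default 1.12e9, the hooded crow
#'   genome).
#' @param volume_fraction fraction of the 50 uL library eluate used (7/50 for
#'   a 7 uL input, 5/50 for 5 uL; default 1).
#' @return expected fold coverage.
#' @export
expected_coverage <- function(qpcr_mol, mapped_reads, total_reads,
                              mean_read_length, genome_length = 1.12e9,
                              volume_fraction = 1) {
  if (total_reads <= 0 || qpcr_mol <= 0 || mean_read_length <= 0 ||
      genome_length <= 0)
    stop2("qpcr_mol, total_reads, mean_read_length and genome_length must be > 0")
  if (mapped_reads < 0 || mapped_reads > total_reads)
    stop2("mapped_reads must be in [0, total_reads]")
  assert_fraction(volume_fraction, "volume_fraction")
  qpcr_mol * (mapped_reads / total_reads) * mean_read_length /
    genome_length * volume_fraction
}

#' Per-SNP depth at the exact SNP base
#'
#' Depth is the number of (optionally deduplicated) mapped reads whose
#' alignment span covers the SNP coordinate. Sites covered by no read get
#' depth 0.
#'
#' @param reads reads data.frame.
#' @param sites validated SNP table.
#' @param dedup exclude duplicate-flagged reads.
#' @return integer vector of depths, one per site, named by snp_id.
#' @export
snp_site_depths <- function(reads, sites, dedup = FALSE) {
  validate_reads(reads)
  sites <- snp_sites(sites)
  use <- reads$mapped & (!dedup | !reads$duplicate)
  r <- reads[use, , drop = FALSE]
  if (nrow(sites) == 0L) return(setNames(integer(), character()))
  pos <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  if (nrow(r) == 0L) return(setNames(integer(nrow(sites)), sites$snp_id))
  gr <- GRanges(r$chrom, IRanges(r$start, r$end))
  setNames(countOverlaps(pos, gr), sites$snp_id)
}

#' Mean SNP-site coverage
#'
#' Arithmetic mean of per-site depth at the exact SNP base (absent sites
#' count as zero).
#'
#' @param depths numeric vector of per-SNP depths.
#' @return mean depth.
#' @export
snp_site_coverage <- function(depths) {
  if (length(depths) == 0L) return(NA_real_)
  mean(depths)
}

#' Coverage evenness across panel SNPs
#'
#' Percentage of SNPs reaching each minimum depth threshold, plus a flag per
#' threshold for whether at least `sample_flag_cut` percent of SNPs meet it.
#'
#' @param depths per-SNP depth vector.
#' @param thresholds integer depth thresholds (default 1:5).
#' @param sample_flag_cut flag percentage cut-off (default 80).
#' @return data.frame with columns threshold, pct_snps, flag.
#' @export
evenness <- function(depths, thresholds = 1:5, sample_flag_cut = 80) {
  if (any(thresholds < 1) || any(thresholds != floor(thresholds)))
    stop2("thresholds must be positive integers")
  pct <- vapply(thresholds, function(t) 100 * mean(depths >= t), numeric(1))
  data.frame(threshold = as.integer(thresholds), pct_snps = pct,
             flag = pct >= sample_flag_cut)
}

#' Mitochondrial read fraction
#'
#' Percentage of mitochondrial reads among all mapped reads.
#'
#' @inheritParams on_target_rate
#' @return percentage, or NA when no reads mapped.
#' @export
mito_fraction <- function(counts) {
  if (!isTRUE(counts$total_mapped > 0)) return(NA_real_)
  100 * counts$mito / counts$total_mapped
}

#' Assemble the per-sample metrics row
#'
#' Convenience wrapper computing all headline ratio metrics from a
#' `sample_counts` and (optionally) per-SNP depths and library metadata.
#'
#' @param sample sample label.
#' @param counts a `sample_counts`.
#' @param depths optional per-SNP depth vector (duplicates included).
#' @param depths_dedup optional duplicate-removed depth vector.
#' @param te_shotgun optional shotgun target efficiency (%), enabling fold
#'   enrichment.
#' @param qpcr_mol,volume_fraction,mean_read_length,genome_length optional
#'   library metadata enabling expected coverage (see [expected_coverage()]).
#' @return one-row data.frame.
#' @export
metrics_row <- function(sample, counts, depths = NULL, depths_dedup = NULL,
                        te_shotgun = NA_real_, qpcr_mol = NA_real_,
                        volume_fraction = NA_real_,
                        mean_read_length = NA_real_,
                        genome_length = 1.12e9) {
  te <- target_efficiency(counts)
  exp_cov <- NA_real_
  if (!is.na(qpcr_mol) && !is.na(volume_fraction) && !is.na(mean_read_length))
    exp_cov <- expected_coverage(qpcr_mol, counts$total_mapped,
                                 counts$total_raw, mean_read_length,
                                 genome_length, volume_fraction)
  data.frame(
    sample = sample,
    on_target_rate = on_target_rate(counts),
    target_efficiency = te,
    target_efficiency_dedup = target_efficiency(counts, dedup = TRUE),
    fold_enrichment = if (is.na(te_shotgun)) NA_real_
                      else fold_enrichment(te, te_shotgun),
    mito_fraction = mito_fraction(counts),
    expected_coverage = exp_cov,
    mean_snp_coverage = if (is.null(depths)) NA_real_ else snp_site_coverage(depths),
    mean_snp_coverage_dedup = if (is.null(depths_dedup)) NA_real_
                              else snp_site_coverage(depths_dedup),
    stringsAsFactors = FALSE
  )
}
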