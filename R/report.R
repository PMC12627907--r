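#' Run the full capture-QC pipeline for a set of samples
#'
#' Orchestrates every stage for each sample of one enrichment run:
#' classification and tally against the comparable partition, ratio metrics,
#' SNP coverage and evenness, the GC-bias table and dropout summary, the 5'
#' C-to-T damage profile, and the per-class allelic-bias test on sites the
#' sample's own (threshold) genotyper calls heterozygous. Writes one TSV per
#' stage plus a JSON summary mirroring the metrics table. Outputs are
#' deterministic for deterministic inputs; missing values are written as
#' ".".
#'
#' @param samples data.frame with columns `sample`, `alignment` (SAM/BAM
#'   path), `total_raw`; optional `qpcr_mol`, `volume_fraction`,
#'   `mean_read_length`, `te_shotgun`.
#' @param partition a [comparable_partition()] (or [single_panel_partition()]).
#' @param sites SNP table used for coverage and genotyping (typically the
#'   shared panel's sites).
#' @param reference [Biostrings::DNAStringSet] or FASTA path.
#' @param out_dir report directory (created if needed).
#' @param mito_names mitochondrial contig names.
#' @param min_overlap on-target overlap rule (bp).
#' @param trim_bases end-trim applied before genotyping pileups (default 5).
#' @param genome_length genome size for expected coverage.
#' @param gc_window GC window width (bp).
#' @return invisibly, a list of the per-stage data.frames and the output
#'   paths.
#' @export
run_capture_qc <- function(samples, partition, sites, reference, out_dir,
                           mito_names = "chrM", min_overlap = 1L,
                           trim_bases = 5L, genome_length = 1.12e9,
                           gc_window = 80L) {
  needed <- c("sample", "alignment", "total_raw")
  miss <- setdiff(needed, names(samples))
  if (length(miss))
    stop2("sample table is missing columns: ", paste(miss, collapse = ", "))
  absent <- !file.exists(samples$alignment)
  if (any(absent))
    stop2("alignment file not found for sample(s): ",
          paste(samples$sample[absent], collapse = ", "))
  if (is.character(reference) && length(reference) == 1L)
    reference <- readDNAStringSet(reference)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- snp_sites(sites)
  windows <- window_gc_bins(partition, reference, window = gc_window)
  metrics <- NULL; even <- NULL; gc_tab <- NULL; dmg <- NULL; bias <- NULL
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    reads <- read_alignments(s$alignment)
    counts <- tally_sample(reads, partition, mito_names,
                           total_raw = s$total_raw,
                           min_overlap = min_overlap)
    depths <- snp_site_depths(reads, sites)
    depths_dd <- snp_site_depths(reads, sites, dedup = TRUE)
    ev <- evenness(depths)
    even <- rbind(even, cbind(sample = s$sample, ev))
    cls <- classify_reads(reads, partition, mito_names, min_overlap)
    on_target <- reads[cls == "on_comparable", , drop = FALSE]
    gt <- gc_bin_read_counts(on_target, windows)
    drop <- gc_dropout_metrics(gt)
    gc_tab <- rbind(gc_tab, cbind(sample = s$sample, as.data.frame(gt)))
    prof <- ct_profile(on_target, reference)
    dmg <- rbind(dmg, cbind(sample = s$sample, as.data.frame(prof)))
    trimmed <- trim_read_ends(reads, trim_bases)$reads
    pile <- pileup_allele_counts(trimmed, sites)
    calls <- call_genotype(pile)
    het <- calls$snp_id[calls$called & grepl("/", calls$alleles, fixed = TRUE)]
    bt <- allele_bias_table(pile, het)
    if (nrow(bt))
      bias <- rbind(bias, cbind(sample = s$sample, bt))
    row <- metrics_row(
      s$sample, counts, depths, depths_dd,
      te_shotgun = s$te_shotgun %||% NA_real_,
      qpcr_mol = s$qpcr_mol %||% NA_real_,
      volume_fraction = s$volume_fraction %||% NA_real_,
      mean_read_length = s$mean_read_length %||%
        read_length_stats(reads)$mean,
      genome_length = genome_length
    )
    row$at_dropout <- drop[["at_dropout"]]
    row$gc_dropout <- drop[["gc_dropout"]]
    metrics <- rbind(metrics, row)
  }
  paths <- list(
    metrics = file.path(out_dir, "metrics.tsv"),
    evenness = file.path(out_dir, "evenness.tsv"),
    gc = file.path(out_dir, "gc.tsv"),
    damage = file.path(out_dir, "damage.tsv"),
    allele_bias = file.path(out_dir, "allele_bias.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_tsv_dot <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
  }
  write_tsv_dot(metrics, paths$metrics)
  write_tsv_dot(even, paths$evenness)
  write_tsv_dot(gc_tab, paths$gc)
  write_tsv_dot(dmg, paths$damage)
  write_tsv_dot(bias %||% data.frame(), paths$allele_bias)
  write_json(metrics, paths$summary, dataframe = "rows", na = "null",
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, evenness = even, gc = gc_tab,
                 damage = dmg, allele_bias = bias, paths = paths))
}

#' Paired per-sample comparison of two kits
#'
#' Joins two metrics tables by sample and reports, for every shared numeric
#' metric, the per-sample difference (a - b) and ratio (a / b), plus column
#' means. A metric missing in either table yields a missing delta while the
#' others are still computed.
#'
#' @param metrics_a,metrics_b metrics data.frames from [run_capture_qc()]
#'   (or [metrics_row()]), same sample ids.
#' @return list with `per_sample` (sample, metric, value_a, value_b, delta,
#'   ratio) and `means` (metric, mean_a, mean_b, mean_delta, mean_ratio).
#' @export
compare_kits <- function(metrics_a, metrics_b) {
  if (!setequal(metrics_a$sample, metrics_b$sample))
    stop2("sample sets differ: ",
          paste(c(setdiff(metrics_a$sample, metrics_b$sample),
                  setdiff(metrics_b$sample, metrics_a$sample)),
                collapse = ", "))
  b <- metrics_b[match(metrics_a$sample, metrics_b$sample), , drop = FALSE]
  num_cols <- intersect(names(metrics_a)[vapply(metrics_a, is.numeric,
                                                logical(1))],
                        names(b)[vapply(b, is.numeric, logical(1))])
  rows <- lapply(num_cols, function(cl) {
    data.frame(sample = metrics_a$sample, metric = cl,
               value_a = metrics_a[[cl]], value_b = b[[cl]],
               delta = metrics_a[[cl]] - b[[cl]],
               ratio = metrics_a[[cl]] / b[[cl]],
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(num_cols, function(cl) {
    sel <- per_sample[per_sample$metric == cl, ]
    data.frame(metric = cl,
               mean_a = mean(sel$value_a, na.rm = TRUE),
               mean_b = mean(sel$value_b, na.rm = TRUE),
               mean_delta = mean(sel$delta, na.rm = TRUE),
               mean_ratio = mean(sel$ratio, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, means = means)
}
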