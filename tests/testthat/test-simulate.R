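small_cfg <- function(...) {
  defaults <- list(seed = 3, genome_length = 1e5, n_snps_a = 15L,
                   n_snps_b = 30L, n_reads = 2000L,
                   endogenous_fraction = 0.5, enrichment_factor = 10,
                   duplication_rate = 0.2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("genome generation honours GC blocks and the seed", {
  cfg <- sim_config(seed = 8, genome_length = 1e5,
                    gc_blocks = list(c(5e4, 1.0), c(5e4, 0.40)),
                    n_snps_a = 5L, n_snps_b = 10L)
  g <- make_genome(cfg)
  expect_equal(names(g), c("chr1", "chrM"))
  expect_equal(Biostrings::width(g)[1], 1e5)
  block1 <- as.character(Biostrings::subseq(g[[1]], 1, 5e4))
  expect_false(grepl("[AT]", block1))  # 100% GC block
  block2 <- strsplit(as.character(Biostrings::subseq(g[[1]], 5e4 + 1, 1e5)),
                     "")[[1]]
  gc_obs <- mean(block2 %in% c("G", "C"))
  expect_equal(gc_obs, 0.40, tolerance = 0.02)  # ~±3 binomial sd at 5e4
  # same config, same bytes
  expect_identical(as.character(make_genome(cfg)),
                   as.character(make_genome(cfg)))
  expect_error(sim_config(genome_length = 10, gc_blocks = list(c(5, 0.5))),
               "sum to genome_length")
})

test_that("panels nest, respect spacing and hit the ts:tv ratio", {
  cfg <- sim_config(seed = 9, genome_length = 3e6, n_snps_a = 2000L,
                    n_snps_b = 8000L)
  g <- make_genome(cfg)
  p <- make_panels(cfg, g)
  expect_true(all(p$panel_a$sites$snp_id %in% p$panel_b$sites$snp_id))
  expect_equal(nrow(p$panel_a$sites), 2000L)
  # allele1 is the reference base at the site
  chr <- as.character(g[[1]])
  idx <- sample(nrow(p$panel_b$sites), 200)
  expect_equal(substring(chr, p$panel_b$sites$pos[idx],
                         p$panel_b$sites$pos[idx]),
               p$panel_b$sites$allele1[idx])
  # footprints never collide (sorted starts gap at least footprint width)
  iv <- p$panel_b$intervals
  expect_true(all(diff(start(iv)) > width(iv)[-length(iv)]))
  # transitions appear at ts/(ts+tv) = 2/3 of sites
  vc <- classify_variant(p$panel_b$sites$allele1, p$panel_b$sites$allele2)
  expect_equal(mean(vc$transition), 2 / 3, tolerance = 0.02)
  expect_error(make_panels(sim_config(genome_length = 1e4, n_snps_b = 500L),
                           g), "too small")
})

test_that("simulated reads are deterministic and degenerate configs behave", {
  cfg <- small_cfg()
  s1 <- simulate_dataset(cfg, panel = "a")
  s2 <- simulate_dataset(cfg, panel = "a")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$reads), 2000L)
  # no endogenous DNA -> nothing maps
  s0 <- simulate_dataset(small_cfg(endogenous_fraction = 1e-9), panel = "a")
  expect_equal(sum(s0$reads$mapped), 0L)
  # no damage -> no deaminated positions recorded
  sd0 <- simulate_dataset(small_cfg(d0 = 0), panel = "a")
  expect_true(all(sd0$truth$n_deaminated == 0L))
  # no duplication -> no duplicate flags
  sdup <- simulate_dataset(small_cfg(duplication_rate = 0), panel = "a")
  expect_false(any(sdup$reads$duplicate))
})

test_that("truth labels agree with the emitted alignments", {
  sim <- simulate_dataset(small_cfg(), panel = "a")
  expect_identical(sim$truth$qname, sim$reads$qname)
  expect_identical(sim$truth$endogenous, sim$reads$mapped)
  expect_identical(sim$truth$duplicate, sim$reads$duplicate)
  # every on-target truth read overlaps a panel-A footprint
  iv <- sim$panels$panel_a$intervals
  on <- sim$truth[sim$truth$on_target & !is.na(sim$truth$chrom), ]
  hits <- countOverlaps(GRanges(on$chrom, IRanges(on$start, on$end)), iv)
  expect_true(all(hits >= 1L))
  # deaminated positions are T in the read-oriented sequence where the
  # reference held C
  chr <- as.character(sim$genome[[1]])
  dam <- utils::head(which(sim$truth$n_deaminated > 0 &
                             sim$truth$chrom == "chr1"), 20)
  for (j in dam) {
    tr <- sim$truth[j, ]
    refs <- substr(chr, tr$start, tr$end)
    qs <- sim$reads$seq[j]
    if (tr$strand == "-") { refs <- rc_chr(refs); qs <- rc_chr(qs) }
    for (p in as.integer(strsplit(tr$deaminated_pos, ",")[[1]])) {
      expect_equal(substr(refs, p, p), "C")
      expect_equal(substr(qs, p, p), "T")
    }
  }
})

test_that("calibrated enrichment yields the requested on-target raw fraction", {
  cfg <- small_cfg(duplication_rate = 0, n_reads = 30000L)
  genome <- make_genome(cfg)
  panels <- make_panels(cfg, genome)
  w <- calibrate_enrichment(cfg, panels$panel_a, 0.25)
  cfg2 <- small_cfg(duplication_rate = 0, n_reads = 30000L,
                    enrichment_factor = w)
  sim <- simulate_reads(cfg2, genome, panels, panel = "a")
  frac <- mean(sim$truth$on_target)
  se <- sqrt(0.25 * 0.75 / 30000)
  expect_equal(frac, 0.25, tolerance = 4 * se / 0.25)
})

test_that("simulated allele counts respect ratio, leakage and the seed", {
  sites <- data.frame(
    chrom = "chr1", pos = seq(50L, by = 100L, length.out = 400L),
    allele1 = rep(c("C", "A"), 200), allele2 = rep(c("T", "G"), 200),
    snp_id = sprintf("s%04d", 1:400)
  )
  null <- simulate_allele_counts(sites, mean_depth = 20, seed = 2)
  expect_identical(null, simulate_allele_counts(sites, mean_depth = 20,
                                                seed = 2))
  ratio <- sum(null$C[sites$allele1 == "C"]) /
    sum(null$total_depth[sites$allele1 == "C"])
  expect_equal(ratio, 0.5, tolerance = 0.05)
  # damage leakage at hom-CC sites drives the CT ratio above 0.5
  ct_ids <- sites$snp_id[sites$allele1 == "C"]
  leak <- simulate_allele_counts(sites, mean_depth = 20,
                                 hom_cc_sites = ct_ids, damage_leak = 0.1,
                                 seed = 3)
  ratio_ct <- sum(leak$C[sites$allele1 == "C"]) /
    sum(leak$total_depth[sites$allele1 == "C"])
  expect_gt(ratio_ct, 0.8)
})

test_that("dataset writer emits coherent text artifacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(n_reads = 500L), panel = "a",
                          out_dir = dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  # SAM read-back equals the in-memory reads
  back <- read_alignments(sim$paths$sam)
  back <- back[match(sim$reads$qname, back$qname), ]
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$start, sim$reads$start)
  expect_equal(back$duplicate, sim$reads$duplicate)
  # truth TSV round-trips
  truth <- read.delim(sim$paths$truth, stringsAsFactors = FALSE)
  expect_equal(nrow(truth), 500L)
  expect_equal(truth$qname, sim$truth$qname)
  # FASTA matches the in-memory genome
  ref <- Biostrings::readDNAStringSet(sim$paths$fasta)
  expect_equal(as.character(ref), as.character(sim$genome),
               ignore_attr = TRUE)
  # BED round-trip of panel A
  bed <- read_panel_bed(sim$paths$bed_a)
  expect_equal(start(bed), start(sim$panels$panel_a$intervals))
  # FASTQ has one record per read
  fq <- readLines(sim$paths$fastq)
  expect_equal(length(fq), 4L * 500L)
})
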