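test_that("SNP site loading parses, validates and sorts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\tA\tG\ts1", "chr1\t500\tC\tT\ts2"), f)
  sites <- load_snp_sites(f)
  expect_equal(sites$pos, c(500L, 1000L))
  expect_equal(sites$snp_id, c("s2", "s1"))
  expect_equal(sites$allele1[2], "A")

  writeLines("chr1\t1000\tA\tA\ts1", f)
  expect_error(load_snp_sites(f), "allele1 and allele2 must differ")

  writeLines(c("chr1\t1000\tA\tG\ts1", "chr1\t1000\tC\tT\ts2"), f)
  expect_error(load_snp_sites(f), "duplicate sites")

  writeLines("chr1\tnotanumber\tA\tG\ts1", f)
  expect_error(load_snp_sites(f), "malformed pos")

  writeLines(character(), f)
  expect_warning(empty <- load_snp_sites(f), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("target intervals follow the footprint geometry in BED coordinates", {
  sites <- data.frame(chrom = "chr1", pos = 1000L, allele1 = "A",
                      allele2 = "G", snp_id = "s1")
  # myBaits-style: 121 bp footprint, SNP centred -> BED [939, 1060)
  pa <- derive_target_intervals(sites, design_mybaits())
  expect_equal(start(pa$intervals) - 1L, 939L)  # BED start
  expect_equal(end(pa$intervals), 1060L)        # BED end (exclusive)
  expect_equal(width(pa$intervals), 121L)
  # Twist-style: 80 bp footprint, SNP at offset 41 -> BED [959, 1039)
  pb <- derive_target_intervals(sites, design_twist())
  expect_equal(start(pb$intervals) - 1L, 959L)
  expect_equal(end(pb$intervals), 1039L)
  expect_equal(width(pb$intervals), 80L)
})

test_that("footprints are clipped and flagged at contig boundaries", {
  sites <- data.frame(chrom = "chr1", pos = 30L, allele1 = "A",
                      allele2 = "G", snp_id = "s1")
  expect_warning(p <- derive_target_intervals(sites, design_mybaits()),
                 "clipped")
  expect_equal(start(p$intervals) - 1L, 0L)  # BED [0, 90)
  expect_equal(end(p$intervals), 90L)
  expect_true(mcols(p$intervals)$clipped)

  # right-edge clip needs seqlengths
  sites2 <- data.frame(chrom = "chr1", pos = 980L, allele1 = "A",
                       allele2 = "G", snp_id = "s2")
  expect_warning(
    p2 <- derive_target_intervals(sites2, design_twist(), c(chr1 = 1000L)),
    "clipped")
  expect_equal(end(p2$intervals), 1000L)
})

test_that("comparable partition intersects shared SNPs and routes unique ones", {
  part <- toy_partition(shared_pos = 1000L, b_only_pos = 5000L)
  expect_equal(length(part$comparable), 1L)
  expect_equal(width(part$comparable), 80L)  # 80 bp inside the 121 bp footprint
  expect_equal(start(part$comparable) - 1L, 959L)
  expect_equal(length(part$noncomparable_a), 0L)
  expect_equal(length(part$noncomparable_b), 1L)
  expect_equal(mcols(part$noncomparable_b)$snp_id, "b001")
})

test_that("partition handles disjoint panels, inconsistency and idempotence", {
  # disjoint SNP id sets -> empty comparable
  sa <- data.frame(chrom = "chr1", pos = 1000L, allele1 = "A", allele2 = "G",
                   snp_id = "x1")
  sb <- data.frame(chrom = "chr1", pos = 3000L, allele1 = "A", allele2 = "G",
                   snp_id = "y1")
  pa <- derive_target_intervals(sa, design_mybaits())
  pb <- derive_target_intervals(sb, design_twist())
  part <- comparable_partition(pa, pb)
  expect_equal(length(part$comparable), 0L)
  expect_equal(length(part$noncomparable_a), 1L)
  expect_equal(length(part$noncomparable_b), 1L)

  # shared id, different coordinates -> consistency error
  sb2 <- sa; sb2$pos <- 2000L
  pb2 <- derive_target_intervals(sb2, design_twist())
  expect_error(comparable_partition(pa, pb2), "inconsistent coordinates")

  # self-intersection returns the panel itself, no noncomparable leftovers
  self <- comparable_partition(pa, pa)
  expect_equal(granges(self$comparable), granges(pa$intervals))
  expect_equal(length(self$noncomparable_a), 0L)
  expect_equal(length(self$noncomparable_b), 0L)
})

test_that("partition completeness holds for generated panel pairs", {
  for (seed in 1:3) {
    set.seed(seed)
    n_b <- 40L
    pos <- sort(sample(seq(500L, 200000L, by = 400L), n_b))
    sb <- data.frame(chrom = "chr1", pos = pos, allele1 = "A", allele2 = "G",
                     snp_id = sprintf("s%03d", seq_len(n_b)))
    sa <- sb[sort(sample(n_b, 25L)), ]
    pa <- derive_target_intervals(sa, design_mybaits())
    pb <- derive_target_intervals(sb, design_twist())
    part <- comparable_partition(pa, pb)
    # every panel-A SNP lands in exactly one output set
    expect_equal(length(part$comparable) + length(part$noncomparable_a),
                 nrow(sa))
    expect_equal(length(part$comparable) + length(part$noncomparable_b),
                 nrow(sb))
    expect_length(
      intersect(mcols(part$comparable)$snp_id,
                c(mcols(part$noncomparable_a)$snp_id,
                  mcols(part$noncomparable_b)$snp_id)), 0L)
  }
})

test_that("panel GC content matches direct counting", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("ATGC", 20),        # 1..80: 50% GC
    strrep("A", 80),           # 81..160: 0% GC
    strrep("G", 80)            # 161..240: 100% GC
  )))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 81L, 161L), end = c(80L, 160L, 240L)))
  gc <- panel_gc_content(gr, ref)
  expect_equal(gc$per_interval, c(0.5, 0, 1))
  expect_equal(gc$mean_gc_pct, 50)
  expect_equal(gc$n_excluded, 0L)
})

test_that("intervals round-trip through BED exactly", {
  p <- toy_panels(shared_pos = c(1000L, 3000L), b_only_pos = 6000L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_panel_bed(p$b, f)
  back <- read_panel_bed(f)
  expect_equal(start(back), start(p$b$intervals))
  expect_equal(end(back), end(p$b$intervals))
  expect_equal(as.character(seqnames(back)),
               as.character(seqnames(p$b$intervals)))
  expect_equal(mcols(back)$snp_id, mcols(p$b$intervals)$snp_id)
})
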