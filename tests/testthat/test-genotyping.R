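site1 <- data.frame(chrom = "chr1", pos = 100L, allele1 = "A",
                    allele2 = "G", snp_id = "s1")

test_that("pileup counts bases at the SNP coordinate with quality filters", {
  reads <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk_read(paste0("a", i), start = 90L, seq = strrep("A", 20)))),
    do.call(rbind, lapply(1:3, function(i)
      mk_read(paste0("g", i), start = 95L, seq = strrep("G", 20)))),
    mk_read("lowbq", start = 96L, seq = strrep("T", 20),
            qual = strrep(rawToChar(as.raw(10L + 33L)), 20)),  # baseq 10
    mk_read("lowmq", start = 96L, seq = strrep("T", 20), mapq = 5L),
    mk_read("dup", start = 97L, seq = strrep("T", 20), dup = TRUE),
    mk_read("away", start = 300L, seq = strrep("T", 20))
  )
  pile <- pileup_allele_counts(reads, site1)
  expect_equal(pile$A, 5L)
  expect_equal(pile$G, 3L)
  expect_equal(pile$T, 0L)
  expect_equal(pile$total_depth, 8L)
  # uncovered site is present with zero counts
  s2 <- rbind(site1, data.frame(chrom = "chr1", pos = 5000L, allele1 = "C",
                                allele2 = "T", snp_id = "s2"))
  pile2 <- pileup_allele_counts(reads, s2)
  expect_equal(nrow(pile2), 2L)
  expect_equal(pile2$total_depth[pile2$snp_id == "s2"], 0L)
})

test_that("pileup agrees with a per-site loop on simulated reads", {
  cfg <- sim_config(seed = 5, genome_length = 1e5, n_snps_a = 20L,
                    n_snps_b = 40L, n_reads = 3000L,
                    endogenous_fraction = 0.8, enrichment_factor = 10,
                    duplication_rate = 0.2, d0 = 0.2)
  sim <- simulate_dataset(cfg, panel = "a")
  sites <- sim$panels$panel_a$sites
  trimmed <- trim_read_ends(sim$reads, 5L)$reads
  pile <- pileup_allele_counts(trimmed, sites)
  # independent recount with plain vector scans
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]
    sel <- trimmed$mapped & !trimmed$duplicate & trimmed$mapq >= 20 &
      !is.na(trimmed$chrom) & trimmed$chrom == sites$chrom[i] &
      trimmed$start <= pos & trimmed$end >= pos
    bases <- substr(trimmed$seq[sel], pos - trimmed$start[sel] + 1L,
                    pos - trimmed$start[sel] + 1L)
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    expect_equal(unlist(pile[i, c("A", "C", "G", "T")], use.names = FALSE),
                 as.integer(tab))
  }
})

test_that("threshold genotyper applies depth and allele filters", {
  mk_counts <- function(A = 0L, C = 0L, G = 0L, T = 0L) {
    data.frame(snp_id = "s", chrom = "chr1", pos = 1L, allele1 = "A",
               allele2 = "G", A = A, C = C, G = G, T = T,
               total_depth = A + C + G + T)
  }
  het <- call_genotype(mk_counts(A = 5L, G = 3L))
  expect_true(het$called)
  expect_equal(het$alleles, "A/G")
  # below min_depth: absent
  low <- call_genotype(mk_counts(A = 2L))
  expect_false(low$called)
  expect_true(is.na(low$alleles))
  # minor allele failing reads/fraction thresholds: homozygous call
  hom <- call_genotype(mk_counts(A = 9L, G = 1L))
  expect_equal(hom$alleles, "A")
  # three qualifying bases: top two kept, flagged multiallelic
  multi <- call_genotype(mk_counts(A = 10L, C = 6L, G = 4L))
  expect_true(multi$multiallelic)
  expect_equal(multi$alleles, "A/C")
})

test_that("concordance uses the shared-allele match rule", {
  calls <- function(ids, alleles) {
    data.frame(snp_id = ids, called = !is.na(alleles), alleles = alleles,
               depth = 10L, multiallelic = FALSE, stringsAsFactors = FALSE)
  }
  base <- calls(c("s1", "s2", "s3", "s4"), c("A/G", "C", "T", NA))
  enr <- calls(c("s1", "s2", "s3", "s4"), c("A", "A/G", "T", "C"))
  res <- concordance(base, enr)
  expect_equal(res$n_overlap, 3L)  # s4 uncalled in baseline
  expect_equal(res$n_match, 2L)    # s1 matches, s2 mismatches, s3 matches
  expect_equal(res$pct_match, 100 * 2 / 3)
  expect_warning(res0 <- concordance(calls("a", "A"), calls("b", "A")),
                 "no overlapping")
  expect_true(is.na(res0$pct_match))
})

test_that("concordance recovers a programmed discordance rate", {
  set.seed(14)
  n <- 10000
  ids <- sprintf("s%05d", 1:n)
  wrong <- runif(n) < 0.05
  base <- data.frame(snp_id = ids, called = TRUE, alleles = "A/G",
                     depth = 10L, multiallelic = FALSE)
  enr <- base
  enr$alleles <- ifelse(wrong, "C", "A")
  res <- concordance(base, enr)
  expect_equal(res$pct_match, 95, tolerance = 0.011)  # ~1% absolute
})

test_that("variant classes canonicalise allele order", {
  v <- classify_variant(c("G", "C", "G", "T"), c("A", "T", "T", "A"))
  expect_equal(v$class, c("AG", "CT", "GT", "AT"))
  expect_equal(v$first_allele, c("A", "C", "G", "A"))
  expect_equal(v$transition, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(classify_variant("A", "G"), classify_variant("G", "A"))
  expect_error(classify_variant("A", "A"), "distinct")
})

test_that("quasibinomial test handles the symmetric null and boundaries", {
  res <- quasibinomial_bias_test(c(5, 6, 4), c(10, 12, 8))
  expect_equal(res$est_ad_ratio, 0.5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # k = n everywhere: boundary flagged
  bnd <- quasibinomial_bias_test(c(10, 8), c(10, 8))
  expect_true(bnd$boundary)
  expect_equal(bnd$est_ad_ratio, 1)
  expect_true(is.finite(bnd$p_value) && bnd$p_value < 1)
  # single site: dispersion pinned at 1 with a flag
  one <- quasibinomial_bias_test(7, 10)
  expect_true(one$dispersion_fixed)
  expect_equal(one$dispersion, 1)
  expect_error(quasibinomial_bias_test(c(5, 11), c(10, 10)), "k <= n")
})

test_that("quasibinomial test equals the stats::glm fit", {
  set.seed(21)
  for (i in 1:50) {
    m <- sample(3:40, 1)
    n <- sample(3:30, m, replace = TRUE)
    k <- rbinom(m, n, runif(1, 0.2, 0.8))
    if (sum(k) == 0 || sum(k) == sum(n)) next
    res <- quasibinomial_bias_test(k, n)
    fit <- suppressWarnings(
      glm(cbind(k, n - k) ~ 1, family = quasibinomial()))
    sm <- summary(fit)$coefficients
    expect_equal(res$est_ad_ratio, unname(plogis(coef(fit)[1])),
                 tolerance = 1e-6)
    expect_equal(res$dispersion, summary(fit)$dispersion, tolerance = 1e-4)
    expect_equal(res$statistic, unname(sm[1, "t value"]), tolerance = 1e-4)
    expect_equal(res$p_value, unname(sm[1, "Pr(>|t|)"]), tolerance = 1e-4)
  }
})

test_that("with dispersion fixed at 1 the test reduces to the binomial Wald test", {
  set.seed(22)
  for (i in 1:50) {
    m <- sample(2:30, 1)
    n <- sample(3:30, m, replace = TRUE)
    k <- rbinom(m, n, 0.5)
    if (sum(k) == 0 || sum(k) == sum(n)) next
    res <- quasibinomial_bias_test(k, n, dispersion = 1)
    fit <- suppressWarnings(glm(cbind(k, n - k) ~ 1, family = binomial()))
    sm <- summary(fit)$coefficients
    expect_equal(res$statistic, unname(sm[1, "z value"]), tolerance = 1e-4)
    expect_equal(res$p_value, unname(sm[1, "Pr(>|z|)"]), tolerance = 1e-3)
  }
})

test_that("allele depth ratio is permutation-invariant and reflects under swap", {
  set.seed(23)
  n <- sample(3:30, 20, replace = TRUE)
  k <- rbinom(20, n, 0.6)
  a <- quasibinomial_bias_test(k, n)
  perm <- sample(20)
  b <- quasibinomial_bias_test(k[perm], n[perm])
  expect_equal(a$est_ad_ratio, b$est_ad_ratio)
  expect_equal(a$p_value, b$p_value)
  sw <- quasibinomial_bias_test(n - k, n)
  expect_equal(sw$est_ad_ratio, 1 - a$est_ad_ratio)
  expect_equal(sw$p_value, a$p_value, tolerance = 1e-12)
})

test_that("Bonferroni adjustment uses the within-sample family size", {
  adj <- bonferroni_adjust(c(0.004, 0.002, 0.2))
  expect_equal(attr(adj, "threshold"), 0.05 / 18)
  expect_equal(round(attr(adj, "threshold"), 7), 0.0027778)
  expect_equal(adj$significant_raw, c(TRUE, TRUE, FALSE))
  expect_equal(adj$significant_bonferroni, c(FALSE, TRUE, FALSE))
  one <- bonferroni_adjust(0.04, n_tests = 1L)
  expect_equal(attr(one, "threshold"), 0.05)
  expect_true(one$significant_raw & one$significant_bonferroni)
})

test_that("allele bias table groups sites by class and corrects per family", {
  set.seed(24)
  sites <- data.frame(
    chrom = "chr1", pos = seq(100L, by = 200L, length.out = 60L),
    allele1 = rep(c("A", "C", "G"), each = 20),
    allele2 = rep(c("G", "T", "T"), each = 20),
    snp_id = sprintf("s%03d", 1:60)
  )
  pile <- simulate_allele_counts(sites, mean_depth = 20, true_ratio = 0.5,
                                 seed = 24)
  tab <- allele_bias_table(pile, sites$snp_id)
  expect_setequal(tab$class, c("AG", "CT", "GT"))
  expect_true(all(tab$est_ad_ratio >= 0 & tab$est_ad_ratio <= 1))
  # bonferroni significance implies raw significance
  expect_true(all(!tab$significant_bonferroni | tab$significant_raw))
})
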