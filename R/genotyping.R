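#' Per-base allele counts at panel SNP sites
#'
#' Pileup restricted to the exact SNP coordinate: reads must be mapped,
#' non-duplicate, ungapped over the site, with mapping quality and base
#' quality at or above the cut-offs. Sites covered by no qualifying read get
#' zero counts (present, not missing). Trim read ends first
#' ([trim_read_ends()]) when counting for genotyping of damaged libraries.
#'
#' @param reads reads data.frame.
#' @param sites validated SNP table (see [snp_sites()]).
#' @param min_mapq,min_baseq quality cut-offs (default 20/20).
#' @param dedup exclude duplicate-flagged reads (default TRUE).
#' @return data.frame: snp_id, chrom, pos, allele1, allele2, A, C, G, T,
#'   total_depth.
#' @export
pileup_allele_counts <- function(reads, sites, min_mapq = 20L,
                                 min_baseq = 20L, dedup = TRUE) {
  validate_reads(reads)
  sites <- snp_sites(sites)
  out <- sites[c("snp_id", "chrom", "pos", "allele1", "allele2")]
  for (b in DNA_BASES) out[[b]] <- 0L
  if (nrow(sites) == 0L) {
    out$total_depth <- integer(0)
    return(out)
  }
  use <- reads$mapped & (!dedup | !reads$duplicate) & reads$mapq >= min_mapq &
    nchar(reads$seq) == (reads$end - reads$start + 1L)
  r <- reads[use, , drop = FALSE]
  if (nrow(r) > 0L) {
    site_gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
    read_gr <- GRanges(r$chrom, IRanges(r$start, r$end))
    hits <- findOverlaps(site_gr, read_gr)
    if (length(hits)) {
      si <- queryHits(hits); ri <- subjectHits(hits)
      off <- sites$pos[si] - r$start[ri] + 1L
      base <- substr(r$seq[ri], off, off)
      bq <- as.integer(charToRaw(paste(substr(r$qual[ri], off, off),
                                       collapse = ""))) - 33L
      keep <- bq >= min_baseq & base %in% DNA_BASES
      if (any(keep)) {
        tab <- table(factor(sites$snp_id[si][keep], levels = sites$snp_id),
                     factor(base[keep], levels = DNA_BASES))
        for (b in DNA_BASES) out[[b]] <- as.integer(tab[, b])
      }
    }
  }
  out$total_depth <- out$A + out$C + out$G + out$T
  out
}

#' Threshold genotype caller
#'
#' A simple counting genotyper (not a genotype-likelihood model): no call
#' below `min_depth`; alleles are the bases with at least `min_allele_reads`
#' reads and at least `min_allele_frac` of the site depth, truncated to the
#' two deepest (ties broken alphabetically); more than two qualifying bases
#' flags the site multiallelic.
#'
#' @param counts pileup table from [pileup_allele_counts()].
#' @param min_depth minimum site depth to call (default 3).
#' @param min_allele_reads minimum reads supporting an allele (default 2).
#' @param min_allele_frac minimum fraction of site depth (default 0.2).
#' @return data.frame: snp_id, called, alleles (slash-separated string, NA if
#'   absent), depth, multiallelic.
#' @export
call_genotype <- function(counts, min_depth = 3L, min_allele_reads = 2L,
                          min_allele_frac = 0.2) {
  n <- nrow(counts)
  alleles <- character(n); called <- logical(n); multi <- logical(n)
  mat <- as.matrix(counts[DNA_BASES])
  depth <- counts$total_depth
  for (i in seq_len(n)) {
    if (depth[i] < min_depth) { alleles[i] <- NA_character_; next }
    d <- mat[i, ]
    qual <- d >= min_allele_reads & d >= min_allele_frac * depth[i]
    bs <- DNA_BASES[qual]
    if (length(bs) == 0L) { alleles[i] <- NA_character_; next }
    if (length(bs) > 2L) {
      multi[i] <- TRUE
      bs <- bs[order(-d[qual], bs)][1:2]
    }
    called[i] <- TRUE
    alleles[i] <- paste(sort(bs), collapse = "/")
  }
  data.frame(snp_id = counts$snp_id, called = called, alleles = alleles,
             depth = depth, multiallelic = multi, stringsAsFactors = FALSE)
}

#' Genotype concordance against a baseline
#'
#' Restricted to sites called in both sets, an enriched genotype matches when
#' at least one of its alleles is present in the baseline call (a rule robust
#' to low-coverage baselines missing the alternative allele by chance).
#'
#' @param baseline_calls,enriched_calls call tables from [call_genotype()].
#' @return list with `n_overlap`, `n_match` and `pct_match` (NA with a
#'   warning when no sites overlap).
#' @export
concordance <- function(baseline_calls, enriched_calls) {
  b <- baseline_calls[baseline_calls$called, ]
  e <- enriched_calls[enriched_calls$called, ]
  shared <- intersect(b$snp_id, e$snp_id)
  if (length(shared) == 0L) {
    warning("no overlapping called sites between baseline and enriched sets")
    return(list(n_overlap = 0L, n_match = 0L, pct_match = NA_real_))
  }
  ba <- strsplit(b$alleles[match(shared, b$snp_id)], "/", fixed = TRUE)
  ea <- strsplit(e$alleles[match(shared, e$snp_id)], "/", fixed = TRUE)
  match_i <- mapply(function(x, y) length(intersect(x, y)) > 0L, ba, ea)
  list(n_overlap = length(shared), n_match = sum(match_i),
       pct_match = 100 * mean(match_i))
}

#' Canonical biallelic variant class
#'
#' The six biallelic classes are AG, CT, AC, AT, CG and GT, written with the
#' alleles in alphabetical order, so (G, A) and (A, G) classify identically;
#' the first allele of a class is the alphabetically first base. AG and CT
#' are transitions.
#'
#' @param allele1,allele2 character vectors of bases (recycled).
#' @return data.frame: class, first_allele, transition.
#' @export
classify_variant <- function(allele1, allele2) {
  allele1 <- toupper(allele1); allele2 <- toupper(allele2)
  if (any(!(allele1 %in% DNA_BASES)) || any(!(allele2 %in% DNA_BASES)))
    stop2("alleles must be A/C/G/T")
  if (any(allele1 == allele2))
    stop2("variant class requires two distinct alleles")
  first <- pmin(allele1, allele2)
  second <- pmax(allele1, allele2)
  cls <- paste0(first, second)
  data.frame(class = cls, first_allele = first,
             transition = cls %in% c("AG", "CT"), stringsAsFactors = FALSE)
}

#' Quasibinomial test for allelic bias within one variant class
#'
#' Pools the heterozygous sites of one variant class: with k_i reads for the
#' class's first allele out of n_i at site i, fits the intercept-only
#' quasibinomial model. The estimated allele depth ratio is
#' p_hat = sum(k) / sum(n); overdispersion is the Pearson statistic over its
#' m - 1 degrees of freedom,
#' phi_hat = sum((k_i - n_i p_hat)^2 / (n_i p_hat (1 - p_hat))) / (m - 1);
#' and the two-sided Wald test compares logit(p_hat) with logit(p0) using the
#' dispersion-inflated variance phi_hat / sum(n_i p_hat (1 - p_hat)) and a t
#' reference distribution with m - 1 degrees of freedom (standard
#' quasibinomial GLM behaviour; identical to `summary(glm(..,
#' quasibinomial))` when p0 = 0.5). Dispersion below 1 is kept as estimated.
#' A p_hat of exactly 0 or 1 is flagged `boundary` and the estimate is
#' continuity-corrected to (sum(k) + 0.5) / (sum(n) + 1) for the test; with
#' fewer than two sites phi_hat is fixed at 1 and flagged.
#'
#' @param k integer vector, per-site depth of the class's first allele.
#' @param n integer vector, per-site total depth (k <= n, n > 0).
#' @param p0 null allele depth ratio (default 0.5).
#' @param class optional class label carried into the result.
#' @param dispersion NULL (default) to estimate the Pearson dispersion and
#'   use the t reference with m - 1 df, or a fixed numeric value (e.g. 1 for
#'   the ordinary binomial Wald test, which uses the normal reference).
#' @return A `bias_test` list: class, n_sites, est_ad_ratio, dispersion,
#'   statistic, df, p_value, boundary, dispersion_fixed.
#' @export
quasibinomial_bias_test <- function(k, n, p0 = 0.5, class = NA_character_,
                                    dispersion = NULL) {
  if (length(k) != length(n)) stop2("k and n must have equal length")
  if (any(n <= 0) || any(k < 0) || any(k > n))
    stop2("need 0 <= k <= n and n > 0 at every site")
  m <- length(k)
  if (m < 1L) stop2("at least one site is required")
  p_hat <- sum(k) / sum(n)
  boundary <- p_hat %in% c(0, 1)
  p_test <- if (boundary) (sum(k) + 0.5) / (sum(n) + 1) else p_hat
  dispersion_fixed <- !is.null(dispersion) || m < 2L
  phi <- if (!is.null(dispersion)) dispersion
         else if (m < 2L) 1
         else sum((k - n * p_test)^2 / (n * p_test * (1 - p_test))) / (m - 1)
  se <- sqrt(phi / sum(n * p_test * (1 - p_test)))
  diff <- stats::qlogis(p_test) - stats::qlogis(p0)
  # a zero difference is exactly null regardless of the (possibly zero) se
  stat <- if (diff == 0) 0 else diff / se
  df <- max(m - 1L, 1L)
  p_value <- if (dispersion_fixed) 2 * stats::pnorm(-abs(stat))
             else 2 * pt(-abs(stat), df = df)
  structure(
    list(class = class, n_sites = m, est_ad_ratio = p_hat, dispersion = phi,
         statistic = stat, df = df, p_value = p_value, boundary = boundary,
         dispersion_fixed = dispersion_fixed),
    class = "bias_test"
  )
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf(
    "quasibinomial bias test%s: m=%d sites, est AD ratio=%.4f, phi=%.3f, t=%.3f (df=%d), p=%.4g%s\n",
    if (is.na(x$class)) "" else paste0(" [", x$class, "]"),
    x$n_sites, x$est_ad_ratio, x$dispersion, x$statistic, x$df, x$p_value,
    if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Bonferroni threshold and per-test significance
#'
#' Within-sample correction over the tested class/dataset combinations; the
#' default 18 corresponds to 6 variant classes in each of 3 datasets
#' (shotgun plus two enrichment methods).
#'
#' @param p_values numeric vector of raw p values.
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests in the family (default 18).
#' @return data.frame: p_value, significant_raw, significant_bonferroni;
#'   attribute `threshold` = alpha / n_tests.
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05, n_tests = 18L) {
  assert_count(n_tests, "n_tests", min = 1)
  thr <- alpha / n_tests
  out <- data.frame(
    p_value = p_values,
    significant_raw = p_values < alpha,
    significant_bonferroni = p_values < thr
  )
  attr(out, "threshold") <- thr
  out
}

#' Per-class allele-bias table for one dataset
#'
#' Restricts a pileup to biallelic heterozygous sites (per the supplied call
#' set or a logical mask), groups them into the six variant classes, counts
#' the class's first allele as k and the two panel alleles' depths as n at
#' each site, and runs [quasibinomial_bias_test()] per class, with Bonferroni
#' correction across the family.
#'
#' @param pileup pileup table from [pileup_allele_counts()].
#' @param het_sites character vector of snp_ids to use (the biallelic
#'   heterozygous sites shared across datasets at the required depth).
#' @param min_depth minimum total panel-allele depth per site (default 3).
#' @param alpha,n_tests see [bonferroni_adjust()].
#' @return data.frame, one row per variant class present: class, n_sites,
#'   est_ad_ratio, dispersion, p_value, significant_raw,
#'   significant_bonferroni.
#' @export
allele_bias_table <- function(pileup, het_sites, min_depth = 3L,
                              alpha = 0.05, n_tests = 18L) {
  p <- pileup[pileup$snp_id %in% het_sites, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(class = character(), n_sites = integer(),
                      est_ad_ratio = numeric(), dispersion = numeric(),
                      p_value = numeric(), significant_raw = logical(),
                      significant_bonferroni = logical()))
  vc <- classify_variant(p$allele1, p$allele2)
  mat <- as.matrix(p[DNA_BASES])
  idx <- seq_len(nrow(p))
  k <- mat[cbind(idx, match(vc$first_allele, DNA_BASES))]
  other <- ifelse(p$allele1 == vc$first_allele, p$allele2, p$allele1)
  n <- k + mat[cbind(idx, match(other, DNA_BASES))]
  ok <- n >= min_depth
  rows <- lapply(sort(unique(vc$class[ok])), function(cl) {
    sel <- ok & vc$class == cl
    res <- quasibinomial_bias_test(k[sel], n[sel], class = cl)
    data.frame(class = cl, n_sites = res$n_sites,
               est_ad_ratio = res$est_ad_ratio, dispersion = res$dispersion,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bonferroni_adjust(out$p_value, alpha = alpha, n_tests = n_tests)
  out$significant_raw <- adj$significant_raw
  out$significant_bonferroni <- adj$significant_bonferroni
  attr(out, "threshold") <- attr(adj, "threshold")
  out
}
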