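#' Configuration for the synthetic ancient-DNA capture simulator
#'
#' Bundles every knob of the data-generating process the QC pipeline assumes:
#' a block-structured reference with a small mitochondrial compartment, two
#' nested SNP panels with distinct probe geometries, short lognormal
#' fragments, 5' C-to-T deamination, on-/off-target capture with a
#' per-design enrichment factor, a GC-dependent capture multiplier, a
#' saturation regime capping achievable target efficiency, PCR duplicates,
#' and an exogenous (unmappable) read compartment. Identical config + seed
#' gives byte-identical outputs.
#'
#' @param seed integer seed governing every random draw.
#' @param genome_length autosomal contig length in bp.
#' @param gc_blocks list of `c(length, gc)` pairs concatenated into the
#'   autosomal contig; lengths must sum to `genome_length`. Default one block
#'   at 41.5% GC (a crow-like base composition).
#' @param mito_length,mito_gc mitochondrial contig length and GC fraction.
#' @param mito_name mitochondrial contig name.
#' @param n_snps_a,n_snps_b panel sizes; panel B's site set is a superset of
#'   panel A's (nested designs).
#' @param design_a,design_b [probe_design()] objects for the two panels.
#' @param ts_tv transition:transversion ratio used when drawing alternative
#'   alleles.
#' @param endogenous_fraction probability a raw molecule is endogenous.
#' @param frag_mean,frag_sd,frag_min,frag_max fragment length distribution:
#'   rounded lognormal with the given natural-scale mean and sd, clamped to
#'   `[frag_min, frag_max]`.
#' @param d0,lambda 5' deamination model: each C at read offset i (1-based)
#'   reads as T with probability `d0 * exp(-lambda * (i - 1))`.
#' @param damage_3p also apply the same decay from the 3' end.
#' @param enrichment_factor capture weight multiplier for molecules
#'   overlapping a target footprint (off-target, mitochondrial and exogenous
#'   molecules have weight 1); `1` simulates shotgun sequencing.
#' @param saturation_cap maximum achievable expected target efficiency
#'   (fraction of mapped reads on target); the on-target weight is rescaled
#'   when the configured enrichment would exceed it. `1` disables the cap.
#' @param gc_multiplier function mapping an integer GC bin (0..100) of a
#'   target footprint to a capture weight multiplier.
#' @param duplication_rate expected fraction of emitted reads that are PCR
#'   duplicates; per molecule the number of extra copies is geometric.
#' @param mito_fraction probability an endogenous molecule is mitochondrial.
#' @param n_reads total raw reads emitted (endogenous + exogenous, including
#'   duplicates).
#' @param read_baseq,read_mapq fixed base quality (phred) and mapping quality
#'   written to the simulated records.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       gc_blocks = list(c(genome_length, 0.415)),
                       mito_length = 16000L, mito_gc = 0.45,
                       mito_name = "chrM",
                       n_snps_a = 500L, n_snps_b = 1100L,
                       design_a = design_mybaits(),
                       design_b = design_twist(),
                       ts_tv = 2,
                       endogenous_fraction = 0.1,
                       frag_mean = 45, frag_sd = 10,
                       frag_min = 20L, frag_max = 80L,
                       d0 = 0.30, lambda = 0.3, damage_3p = FALSE,
                       enrichment_factor = 8,
                       saturation_cap = 1,
                       gc_multiplier = function(bin) rep(1, length(bin)),
                       duplication_rate = 0.3,
                       mito_fraction = 0.001,
                       n_reads = 1e5,
                       read_baseq = 40L, read_mapq = 37L) {
  assert_fraction(endogenous_fraction, "endogenous_fraction")
  assert_fraction(saturation_cap, "saturation_cap")
  if (duplication_rate < 0 || duplication_rate >= 1)
    stop2("duplication_rate must be in [0, 1)")
  if (mito_fraction < 0 || mito_fraction > 1)
    stop2("mito_fraction must be in [0, 1]")
  if (enrichment_factor < 1) stop2("enrichment_factor must be >= 1")
  if (d0 < 0 || d0 > 1 || lambda < 0) stop2("invalid deamination parameters")
  blk_len <- sum(vapply(gc_blocks, `[`, numeric(1), 1))
  if (blk_len != genome_length)
    stop2("gc_blocks lengths must sum to genome_length")
  for (b in gc_blocks)
    if (length(b) != 2L || b[1] < 1 || b[2] < 0 || b[2] > 1)
      stop2("each gc_block must be c(length >= 1, gc in [0, 1])")
  if (frag_min < 1L || frag_max < frag_min)
    stop2("need 1 <= frag_min <= frag_max")
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_blocks = gc_blocks, mito_length = as.integer(mito_length),
         mito_gc = mito_gc, mito_name = mito_name,
         n_snps_a = as.integer(n_snps_a), n_snps_b = as.integer(n_snps_b),
         design_a = design_a, design_b = design_b, ts_tv = ts_tv,
         endogenous_fraction = endogenous_fraction,
         frag_mean = frag_mean, frag_sd = frag_sd,
         frag_min = as.integer(frag_min), frag_max = as.integer(frag_max),
         d0 = d0, lambda = lambda, damage_3p = damage_3p,
         enrichment_factor = enrichment_factor,
         saturation_cap = saturation_cap, gc_multiplier = gc_multiplier,
         duplication_rate = duplication_rate, mito_fraction = mito_fraction,
         n_reads = as.integer(n_reads), read_baseq = as.integer(read_baseq),
         read_mapq = as.integer(read_mapq)),
    class = "sim_config"
  )
}

random_dna <- function(n_bases, gc) {
  is_gc <- runif(n_bases) < gc
  out <- character(n_bases)
  half <- runif(n_bases) < 0.5
  out[is_gc & half] <- "G"; out[is_gc & !half] <- "C"
  out[!is_gc & half] <- "A"; out[!is_gc & !half] <- "T"
  out
}

#' Generate the synthetic reference genome
#'
#' One autosomal contig ("chr1") built from the configured GC blocks (bases
#' drawn independently: G/C with the block's GC probability, A/T otherwise)
#' plus a mitochondrial contig.
#'
#' @param config a [sim_config()].
#' @return [Biostrings::DNAStringSet] with contigs chr1 and the mito contig.
#' @export
make_genome <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed + 101L)
  auto <- unlist(lapply(config$gc_blocks, function(b)
    random_dna(as.integer(b[1]), b[2])))
  mito <- random_dna(config$mito_length, config$mito_gc)
  genome <- DNAStringSet(c(paste(auto, collapse = ""),
                           paste(mito, collapse = "")))
  names(genome) <- c("chr1", config$mito_name)
  genome
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate the two nested SNP panels
#'
#' Places panel B's SNPs on chr1 on a jittered grid wide enough that probe
#' footprints (and the fragment-overlap windows around them) never collide,
#' draws alternative alleles at the configured transition:transversion
#' ratio, and takes panel A's sites as a random subset of B's (shared
#' snp_ids), mirroring nested commercial designs. The mitochondrial contig
#' carries no targets.
#'
#' @param config a [sim_config()].
#' @param genome genome from [make_genome()].
#' @return list with `panel_a`, `panel_b` ([derive_target_intervals()]
#'   panels) and `sites_b`.
#' @export
make_panels <- function(config, genome) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed + 202L)
  G <- config$genome_length
  margin <- 300L
  spacing_needed <- max(config$design_a$footprint_length,
                        config$design_b$footprint_length) +
    config$frag_max + 10L
  step <- (G - 2L * margin) %/% config$n_snps_b
  if (step < spacing_needed)
    stop2("genome too small to place ", config$n_snps_b,
          " SNPs without footprint collisions")
  jitter <- sample.int(step - spacing_needed + 1L, config$n_snps_b,
                       replace = TRUE) - 1L
  pos <- margin + (seq_len(config$n_snps_b) - 1L) * step + jitter
  ref_base <- substring(as.character(genome[[1]]), pos, pos)
  # alternative allele: transition with prob ts_tv / (ts_tv + 1)
  p_ts <- config$ts_tv / (config$ts_tv + 1)
  is_ts <- runif(config$n_snps_b) < p_ts
  alt <- character(config$n_snps_b)
  alt[is_ts] <- transition_of[ref_base[is_ts]]
  tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  pick <- 1L + (runif(config$n_snps_b) < 0.5)
  alt[!is_ts] <- vapply(which(!is_ts), function(i)
    tv_choices[[ref_base[i]]][pick[i]], character(1))
  sites_b <- snp_sites(data.frame(
    chrom = "chr1", pos = pos, allele1 = ref_base, allele2 = alt,
    snp_id = sprintf("snp%05d", seq_len(config$n_snps_b)),
    stringsAsFactors = FALSE
  ))
  idx_a <- sort(sample.int(config$n_snps_b, config$n_snps_a))
  sites_a <- sites_b[idx_a, , drop = FALSE]
  sl <- c(chr1 = G, stats::setNames(config$mito_length, config$mito_name))
  list(
    panel_a = derive_target_intervals(sites_a, config$design_a, sl,
                                      name = config$design_a$name),
    panel_b = derive_target_intervals(sites_b, config$design_b, sl,
                                      name = config$design_b$name),
    sites_b = sites_b
  )
}

# exact pmf of the rounded, clamped lognormal fragment length
frag_len_pmf <- function(config) {
  cv <- config$frag_sd / config$frag_mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$frag_mean) - sdlog^2 / 2
  support <- config$frag_min:config$frag_max
  p <- stats::plnorm(support + 0.5, meanlog, sdlog) -
    stats::plnorm(support - 0.5, meanlog, sdlog)
  p[1] <- stats::plnorm(config$frag_min + 0.5, meanlog, sdlog)
  p[length(p)] <- 1 - stats::plnorm(config$frag_max - 0.5, meanlog, sdlog)
  list(support = support, p = p, meanlog = meanlog, sdlog = sdlog)
}

draw_frag_len <- function(config, n) {
  pmf <- frag_len_pmf(config)
  len <- round(rlnorm(n, pmf$meanlog, pmf$sdlog))
  pmin(pmax(len, config$frag_min), config$frag_max)
}

# expected probability that an endogenous molecule overlaps a target
# footprint of `panel` (footprints are non-colliding by construction)
expected_on_target_prob <- function(config, panel) {
  pmf <- frag_len_pmf(config)
  fp <- panel$design$footprint_length
  n_sites <- nrow(panel$sites)
  G <- config$genome_length
  t_given_auto <- sum(pmf$p * n_sites * (fp + pmf$support - 1) /
                        (G - pmf$support + 1))
  (1 - config$mito_fraction) * t_given_auto
}

# per-interval capture weight (enrichment x GC multiplier), plus the
# saturation rescale keeping expected target efficiency at or below the cap
capture_weights <- function(config, panel, genome) {
  bins <- gc_bins_of(panel$intervals, genome)
  mult <- config$gc_multiplier(bins)
  w <- config$enrichment_factor * mult
  t <- expected_on_target_prob(config, panel)
  e_w <- mean(w)
  te_exp <- t * e_w / (t * e_w + (1 - t))
  scale <- 1
  if (te_exp > config$saturation_cap) {
    scale <- config$saturation_cap * (1 - t) /
      ((1 - config$saturation_cap) * t * e_w)
    w <- w * scale
  }
  list(w = w, scale = scale, t = t)
}

#' Enrichment factor giving a requested on-target raw-read fraction
#'
#' Inverts the simulator's retention model: with endogenous fraction e and
#' on-target prior t (from the panel geometry and fragment lengths), thinning
#' with on-target weight W and weight 1 elsewhere yields an expected
#' on-target fraction of raw reads f = e t W / (e t W + e (1 - t) + (1 - e)).
#' Returns the W achieving a requested f (useful for building calibrated
#' truth scenarios). Assumes a unit GC multiplier and no saturation cap.
#'
#' @param config a [sim_config()].
#' @param panel the captured `probe_panel`.
#' @param target_fraction desired expected fraction of raw reads on target.
#' @return the enrichment factor (scalar, >= 1).
#' @export
calibrate_enrichment <- function(config, panel, target_fraction) {
  assert_fraction(target_fraction, "target_fraction")
  e <- config$endogenous_fraction
  t <- expected_on_target_prob(config, panel)
  f <- target_fraction
  w <- f * (e * (1 - t) + (1 - e)) / (e * t * (1 - f))
  if (w < 1)
    warning("requested fraction below the uncaptured rate; returning 1")
  max(w, 1)
}

# vectorised 5' (and optional 3') C->T deamination over read-oriented seqs
apply_deamination <- function(seqs, config) {
  if (config$d0 == 0 || length(seqs) == 0L)
    return(list(seqs = seqs, positions = vector("list", length(seqs))))
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  off5 <- sequence(lens)                      # 1-based offset from 5' end
  rate <- config$d0 * exp(-config$lambda * (off5 - 1))
  if (config$damage_3p) {
    off3 <- unlist(lapply(lens, function(l) rev(seq_len(l))), use.names = FALSE)
    rate3 <- config$d0 * exp(-config$lambda * (off3 - 1))
    rate <- 1 - (1 - rate) * (1 - rate3)
  }
  hit <- flat == "C" & runif(length(flat)) < rate
  flat[hit] <- "T"
  read_id <- rep.int(seq_along(seqs), lens)
  positions <- split(off5[hit], factor(read_id[hit], levels = seq_along(seqs)))
  out <- vapply(split(flat, read_id), paste, character(1), collapse = "")
  list(seqs = unname(out), positions = unname(positions))
}

#' Simulate a captured (or shotgun) sequencing run
#'
#' Generates `n_reads` raw reads by the mechanism described in
#' [sim_config()]: uniformly placed endogenous fragments (autosomal or
#' mitochondrial) and random exogenous molecules are thinned with probability
#' proportional to their capture weight (enrichment x GC multiplier on
#' target, 1 elsewhere, rescaled under the saturation cap), deaminated at the
#' 5' end, and re-emitted as PCR duplicates at the configured rate. Records
#' carry true coordinates, so no aligner is needed downstream.
#'
#' @param config a [sim_config()].
#' @param genome genome from [make_genome()].
#' @param panels panels from [make_panels()].
#' @param panel which design is captured: `"a"`, `"b"`, or `"none"` for a
#'   shotgun run (all capture weights 1).
#' @return list with `reads` (data.frame in the [read_alignments()] layout),
#'   `truth` (per-read truth: qname, endogenous, chrom, start, end, strand,
#'   on_target, snp_id of the originating footprint, duplicate, n_deaminated,
#'   deaminated positions as a comma string), and `weights` (the capture
#'   weight diagnostics, including the saturation scale).
#' @export
simulate_reads <- function(config, genome, panels,
                           panel = c("a", "b", "none")) {
  stopifnot(is(config, "sim_config"))
  panel <- match.arg(panel)
  set.seed(config$seed + 303L)
  cap_panel <- switch(panel, a = panels$panel_a, b = panels$panel_b,
                      none = NULL)
  if (is.null(cap_panel)) {
    cw <- list(w = 1, scale = 1, t = NA_real_)
    targets <- GRanges()
    target_ids <- character()
  } else {
    cw <- capture_weights(config, cap_panel, genome)
    targets <- granges(cap_panel$intervals)
    target_ids <- mcols(cap_panel$intervals)$snp_id
  }
  w_max <- max(cw$w, 1)
  e <- config$endogenous_fraction
  G <- config$genome_length
  mito_len <- config$mito_length
  # expected keep probability, to size candidate batches
  t_prior <- if (is.null(cap_panel)) 0 else cw$t
  p_keep <- (e * t_prior * mean(cw$w) + e * (1 - t_prior) + (1 - e)) / w_max
  mol <- list()
  n_kept <- 0L
  need_mols <- config$n_reads  # upper bound on molecules needed
  while (n_kept < need_mols) {
    batch <- ceiling((need_mols - n_kept) / max(p_keep, 1e-6) * 1.15) + 500L
    endo <- runif(batch) < e
    is_mito <- endo & runif(batch) < config$mito_fraction
    len <- draw_frag_len(config, batch)
    clen <- ifelse(is_mito, mito_len, G)
    start <- 1L + floor(runif(batch) * (clen - len + 1L))
    end <- start + len - 1L
    strand <- ifelse(runif(batch) < 0.5, "+", "-")
    w <- rep(1, batch)
    tgt <- rep(NA_integer_, batch)
    if (!is.null(cap_panel)) {
      cand <- which(endo & !is_mito)
      if (length(cand)) {
        gr <- GRanges("chr1", IRanges(start[cand], end[cand]))
        hit <- findOverlaps(gr, targets, select = "first")
        on <- !is.na(hit)
        w[cand[on]] <- cw$w[hit[on]]
        tgt[cand[on]] <- hit[on]
      }
    }
    keep <- runif(batch) < w / w_max
    if (any(keep)) {
      mol[[length(mol) + 1L]] <- data.frame(
        endo = endo[keep], mito = is_mito[keep], start = start[keep],
        end = end[keep], strand = strand[keep], tgt = tgt[keep],
        stringsAsFactors = FALSE
      )
      n_kept <- n_kept + sum(keep)
    }
  }
  mol <- do.call(rbind, mol)
  # duplicates: copies per molecule, truncated so exactly n_reads are emitted
  extra <- rgeom(nrow(mol), prob = 1 - config$duplication_rate)
  copies <- 1L + extra
  cum <- cumsum(copies)
  n_mol <- which(cum >= config$n_reads)[1L]
  mol <- mol[seq_len(n_mol), , drop = FALSE]
  copies <- copies[seq_len(n_mol)]
  copies[n_mol] <- copies[n_mol] - (cum[n_mol] - config$n_reads)
  # molecule sequences (read orientation), with deamination on endogenous
  seqs <- character(n_mol)
  endo_i <- which(mol$endo)
  if (length(endo_i)) {
    gr <- GRanges(ifelse(mol$mito[endo_i], config$mito_name, "chr1"),
                  IRanges(mol$start[endo_i], mol$end[endo_i]))
    ref <- as.character(extract_ref_seqs(gr, genome))
    minus <- mol$strand[endo_i] == "-"
    ref[minus] <- revcomp_chr(ref[minus])
    dm <- apply_deamination(ref, config)
    seqs[endo_i] <- dm$seqs
    deam_pos <- vector("list", n_mol)
    deam_pos[endo_i] <- dm$positions
  } else {
    deam_pos <- vector("list", n_mol)
  }
  exo_i <- which(!mol$endo)
  if (length(exo_i)) {
    lens <- mol$end[exo_i] - mol$start[exo_i] + 1L
    flat <- random_dna(sum(lens), 0.5)
    seqs[exo_i] <- vapply(split(flat, rep.int(seq_along(exo_i), lens)),
                          paste, character(1), collapse = "")
  }
  # expand molecules into reads (duplicate copies after the first)
  ridx <- rep.int(seq_len(n_mol), copies)
  dup <- unlist(lapply(copies, function(k) c(FALSE, rep(TRUE, k - 1L))),
                use.names = FALSE)
  qname <- sprintf("sim%07d", seq_along(ridx))
  read_seq <- seqs[ridx]
  minus <- mol$endo[ridx] & mol$strand[ridx] == "-"
  sam_seq <- read_seq
  sam_seq[minus] <- revcomp_chr(sam_seq[minus])   # SAM stores plus strand
  qual_char <- rawToChar(as.raw(config$read_baseq + 33L))
  lens <- nchar(read_seq)
  quals <- strrep(qual_char, lens)
  reads <- data.frame(
    qname = qname,
    mapped = mol$endo[ridx],
    chrom = ifelse(mol$endo[ridx],
                   ifelse(mol$mito[ridx], config$mito_name, "chr1"),
                   NA_character_),
    start = ifelse(mol$endo[ridx], mol$start[ridx], NA_integer_),
    end = ifelse(mol$endo[ridx], mol$end[ridx], NA_integer_),
    strand = ifelse(mol$endo[ridx], mol$strand[ridx], NA_character_),
    mapq = ifelse(mol$endo[ridx], config$read_mapq, 0L),
    seq = sam_seq,
    qual = quals,
    duplicate = dup,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    qname = qname,
    endogenous = mol$endo[ridx],
    chrom = reads$chrom,
    start = reads$start,
    end = reads$end,
    strand = reads$strand,
    on_target = !is.na(mol$tgt[ridx]),
    snp_id = ifelse(is.na(mol$tgt[ridx]), NA_character_,
                    target_ids[mol$tgt[ridx]]),
    duplicate = dup,
    n_deaminated = lengths(deam_pos)[ridx],
    deaminated_pos = vapply(deam_pos[ridx], paste, character(1),
                            collapse = ","),
    stringsAsFactors = FALSE
  )
  list(reads = validate_reads(reads), truth = truth, weights = cw)
}

#' Simulate per-site allele-count tables
#'
#' Draws a pileup-shaped allele-count table for a set of heterozygous panel
#' sites: per-site depth is Poisson, and the count of the (alphabetically)
#' first allele is binomial at `true_ratio`. Sites listed in `hom_cc_sites`
#' emulate the damage miscall mechanism: their true genotype is homozygous
#' for the first allele, and reads of the second allele arise only by
#' deamination-style leakage at rate `damage_leak`, producing apparent
#' heterozygotes whose depth ratio exceeds 0.5.
#'
#' @param sites validated SNP table (het sites to simulate).
#' @param mean_depth Poisson mean site depth.
#' @param true_ratio expected fraction of the first allele at genuine
#'   heterozygous sites.
#' @param hom_cc_sites snp_ids simulated as damage-miscalled homozygotes.
#' @param damage_leak per-read leakage probability at those sites.
#' @param seed integer seed.
#' @return pileup-shaped data.frame (see [pileup_allele_counts()]).
#' @export
simulate_allele_counts <- function(sites, mean_depth = 10, true_ratio = 0.5,
                                   hom_cc_sites = character(),
                                   damage_leak = 0.1, seed = 1L) {
  sites <- snp_sites(sites)
  set.seed(seed + 404L)
  n <- nrow(sites)
  out <- sites[c("snp_id", "chrom", "pos", "allele1", "allele2")]
  for (b in DNA_BASES) out[[b]] <- 0L
  if (n == 0L) { out$total_depth <- integer(0); return(out) }
  depth <- rpois(n, mean_depth)
  first <- pmin(sites$allele1, sites$allele2)
  second <- pmax(sites$allele1, sites$allele2)
  is_hom_leak <- sites$snp_id %in% hom_cc_sites
  k_first <- integer(n)
  k_first[!is_hom_leak] <- rbinom(sum(!is_hom_leak), depth[!is_hom_leak],
                                  true_ratio)
  # damage-miscalled homozygote: second allele appears only through leakage
  leak <- rbinom(sum(is_hom_leak), depth[is_hom_leak], damage_leak)
  k_first[is_hom_leak] <- depth[is_hom_leak] - leak
  mat <- as.matrix(out[DNA_BASES])
  mat[cbind(seq_len(n), match(first, DNA_BASES))] <- k_first
  mat[cbind(seq_len(n), match(second, DNA_BASES))] <- depth - k_first
  for (b in DNA_BASES) out[[b]] <- as.integer(mat[, b])
  out$total_depth <- as.integer(depth)
  out
}

#' Run the simulator end to end and optionally write all artifacts
#'
#' Convenience wrapper: genome, panels, one captured run, and (optionally)
#' files on disk — reference FASTA, panel BEDs and site TSVs, reads as SAM
#' and FASTQ, and the per-read truth TSV.
#'
#' @param config a [sim_config()].
#' @param panel captured design (`"a"`, `"b"`, `"none"`).
#' @param out_dir if non-NULL, directory to write artifacts into.
#' @return list with genome, panels, reads, truth, weights and (if written)
#'   file paths.
#' @export
simulate_dataset <- function(config, panel = "a", out_dir = NULL) {
  genome <- make_genome(config)
  panels <- make_panels(config, genome)
  run <- simulate_reads(config, genome, panels, panel = panel)
  out <- list(genome = genome, panels = panels, reads = run$reads,
              truth = run$truth, weights = run$weights, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "genome.fa"),
      bed_a = file.path(out_dir, "panel_a.bed"),
      bed_b = file.path(out_dir, "panel_b.bed"),
      sites_a = file.path(out_dir, "sites_a.tsv"),
      sites_b = file.path(out_dir, "sites_b.tsv"),
      sam = file.path(out_dir, "reads.sam"),
      fastq = file.path(out_dir, "reads.fastq"),
      truth = file.path(out_dir, "truth.tsv")
    )
    writeXStringSet(genome, paths$fasta)
    write_panel_bed(panels$panel_a, paths$bed_a)
    write_panel_bed(panels$panel_b, paths$bed_b)
    write.table(panels$panel_a$sites, paths$sites_a, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(panels$panel_b$sites, paths$sites_b, sep = "\t",
                quote = FALSE, row.names = FALSE)
    sl <- stats::setNames(c(config$genome_length, config$mito_length),
                          c("chr1", config$mito_name))
    write_sam(run$reads, paths$sam, sl)
    write_fastq(run$reads, paths$fastq)
    write.table(run$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write reads as FASTQ (in sequencing orientation)
#'
#' Minus-strand alignments are reverse-complemented back to the orientation
#' in which the molecule was sequenced.
#'
#' @param reads reads data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  seqs <- reads$seq
  minus <- reads$mapped & !is.na(reads$strand) & reads$strand == "-"
  seqs[minus] <- revcomp_chr(seqs[minus])
  quals <- reads$qual
  quals[minus] <- revstr(quals[minus])
  writeLines(paste0("@", reads$qname, "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}
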