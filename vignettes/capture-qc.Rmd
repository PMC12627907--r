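---
title: "Evaluating hybridization-capture enrichment of ancient DNA with enrichQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hybridization-capture enrichment of ancient DNA with enrichQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In-solution capture hybridizes biotinylated probes to a sequencing library
and pulls down the hybrids, enriching a panel of target SNPs before
sequencing. For degraded material — short fragments, heavy cytosine
deamination, endogenous fractions anywhere from under 1 % to over 90 % —
the performance of a probe design is an empirical question, and different
commercial designs answer it differently. `enrichQC` implements the full
evaluation battery a capture experiment needs: panel geometry and the
cross-design comparable partition, read classification and ratio metrics,
coverage evenness, GC-bias dropout, damage profiling, genotype concordance
and an allelic-bias test, plus a simulator that generates data with known
truth so every stage can be verified end to end.

## Panel geometry and the comparable partition

A probe design is summarised by its per-SNP *footprint*: the total span the
probes cover around the SNP, and the SNP's offset within it. Two canned
geometries are provided: a tiled design of four 60 bp ssRNA probes covering
121 bp with the SNP centred (offset 61), and a single 80 bp dsDNA probe
covering 80 bp. Vendors do not publish exact probe placement, only the
covered span, so the offsets are a package convention: the 121 bp footprint
is centred by symmetry, and the even 80 bp footprint puts the SNP at offset
41. Any consistent convention yields the same cross-design results, because
comparisons run on the *intersection* of the two footprints: for SNPs
present in both panels, the comparable target is the geometric intersection
(80 bp inside 121 bp when the designs are nested); SNPs unique to one panel
are that panel's noncomparable targets, excluded from the numerator and the
denominator of every cross-kit ratio. SNP positions are 1-based; intervals
are BED-style 0-based half-open on disk and 1-based closed in memory
(GenomicRanges convention). Footprints of nearby SNPs are never merged, so a
read can be attributed to exactly one class.

## Read classification and ratio metrics

Each read receives exactly one class — unmapped, mitochondrial,
on-comparable, on-noncomparable, or off-target — with precedence
mito > comparable > noncomparable > off-target. A read is "on" an interval
when it overlaps it by at least 1 bp; no minimum-overlap convention is
standard in the field, so the threshold is exposed (`min_overlap`) for
sensitivity analysis. Two ratios summarise enrichment:

- on-target rate = 100 · comparable / (raw − noncomparable). The raw-read
  denominator includes unmapped and adapter-derived reads, so `total_raw`
  must be supplied (from the FASTQ read count or the simulator truth); it
  cannot be recovered from a mapped-only BAM.
- target efficiency = 100 · comparable / (mapped − noncomparable), the
  endogenous-only view; duplicates are *included* in the headline numbers
  (they reflect what was sequenced) and duplicate-removed variants are
  reported alongside.

Because the raw denominator is always at least the mapped one, on-target
rate never exceeds target efficiency; the test suite asserts this over
randomly generated count vectors. Duplicate flags present in the input are
trusted; `redetect_duplicates = TRUE` re-marks by identical
(chrom, start, end, strand), keeping the first record of each group. The
re-marking is deliberately not an automatic fallback: a correctly marked
file with zero duplicates is indistinguishable from an unmarked one, and
coordinate re-marking would misflag coincidental coordinate collisions.

Fold enrichment divides the captured target efficiency by the shotgun
target efficiency of the same library, and is undefined (missing, with a
warning) when the shotgun efficiency is zero. Undefined ratios are always
emitted as missing values — never as 0 — and written as "." in TSVs.
Expected library coverage uses the qPCR-based estimate
qPCR molecules × (mapped/total) × mean read length / genome length,
scaled by the fraction of the library volume that entered the capture
reaction; the genome length defaults to 1.12 Gb (a crow-sized bird genome).

## GC bias

Target intervals are tiled end-to-end with non-overlapping 80 bp windows
(partial trailing windows dropped), each assigned the integer bin
round(100·GC) computed from A/C/G/T counts (N ignored; all-N windows
excluded and counted). Bins are always computed as
`round(100 * gc_count / acgt_count)` from integer counts; the grouping
matters, since `100 * (47/80)` and `(100*47)/80` can round to different
integers in floating point. Reads are credited to the window containing
their 5′ alignment start — the biologically meaningful end for capture and
damage — with the rightmost base used for minus-strand alignments; an
alignment-midpoint rule is available (`credit = "midpoint"`). AT dropout
sums the positive shortfall of read percentage against window percentage
over bins 0–50, GC dropout over bins 50–100; bin 50 belongs to both sums as
the ranges are conventionally written, and `split_bin_50 = TRUE` gives the
exclusive split. Normalized coverage is reads-per-window relative to the
global mean; its window-weighted mean is 1 by construction (asserted to
1e-9), and empty tables are flagged rather than filled with zeros.

## Damage profiling

Deamination converts cytosine to uracil, read as thymine, concentrated at
fragment ends. The profile counts, at each 5′ offset i, reads carrying T
where the reference has C, among reads whose reference base there is C —
reads aligned to the minus strand are reverse-complemented (together with
their reference slice) before counting, so plus-strand G→A events
contribute correctly. Offsets with no reference-C observations are missing,
not zero. Profiling runs on untrimmed reads; the 5 bp end-trim is applied
only before genotyping pileups. Substitutions are identified directly
against the reference FASTA (no MD-tag dependence), and gapped alignments
are skipped. The exponential model d(i) = d₀·e^(−λ(i−1)) is fitted by a
log-link binomial GLM on the positional counts, which handles
zero-substitution tail positions correctly (a log-scale least-squares fit
would have to drop them and biases d₀ downward). The headline statistic is
the first-base rate. By default the profile covers whatever reads are
passed in; for capture experiments the on-target subset is the natural
choice and is what `run_capture_qc()` uses.

## Genotyping and allelic bias

Allele counts at panel SNPs take non-duplicate, ungapped reads with
mapq ≥ 20 and baseq ≥ 20, after trimming 5 bp from both read ends to remove
most damage. The genotyper is an explicit simplification — a counting
caller, not a genotype-likelihood model: no call below 3× depth; alleles
need ≥ 2 supporting reads and ≥ 20 % of site depth; more than two
qualifying bases keeps the two deepest (alphabetical tie-break) and flags
the site. Concordance against a shotgun baseline counts a match when the
two call sets share at least one allele, a rule robust to shallow baselines
missing one allele of a true heterozygote; it is independent of the caller
choice.

Allelic bias pools heterozygous sites by variant class (AG, CT, AC, AT, CG,
GT — labels alphabetical, so the "first allele" of a class is the
alphabetically first base, a fixed canonicalization that makes ratio tables
reproducible). Within a class with per-site first-allele counts kᵢ of nᵢ,
the estimate is p̂ = Σk/Σn, overdispersion is the Pearson statistic over
m − 1 degrees of freedom, and the two-sided Wald test compares logit(p̂)
with logit(0.5) using the dispersion-inflated variance and a t reference
with m − 1 df — exactly the behaviour of an intercept-only quasibinomial
`glm()`, with which the implementation is cross-checked in the tests. The
Wald test is on the logit scale (standard GLM behaviour); a fixed-dispersion
variant (`dispersion = 1`) reduces to the ordinary binomial Wald test and
uses the normal reference. Degenerate inputs are flagged rather than
silently handled: p̂ ∈ {0, 1} gets a boundary flag and a continuity-corrected
estimate (Σk + 0.5)/(Σn + 1) for testing; fewer than two sites pin the
dispersion at 1. Bonferroni correction is applied within sample across the
tested families; the default family size of 18 corresponds to 6 classes × 3
datasets (shotgun plus two enrichment methods). The model is intercept-only
because the counts at each site are treated as exchangeable binomial
outcomes of one class-level probability; site-level covariates are out of
scope.

A practical caveat the direction checks exercise: at transition sites,
deamination can convert true homozygous CC sites into apparent CT
heterozygotes. The spurious T reads are few, so the "heterozygote" shows a
C-skewed ratio — an excess of the *retained* allele, not evidence of capture
bias. The simulator reproduces this mechanism (`hom_cc_sites` with a leakage
rate), and the CT class ratio moves above 0.5 as expected.

## The simulator

`sim_config()` fixes the data-generating process; identical config + seed
gives byte-identical outputs (FASTA, SAM, FASTQ, BED, truth TSV). The
defaults describe a realistic degraded-sample capture experiment:

- genome: one 2 Mb autosomal contig at 41.5 % GC (crow-like base
  composition) plus a 16 kb mitochondrial contig carrying no targets;
  GC blocks are configurable for GC-bias studies.
- panels: 1,100 SNPs for the larger design with the smaller design's 500
  SNPs a strict subset (nested commercial panels), placed on a jittered
  grid wide enough that footprints and fragment-overlap windows never
  collide; alternative alleles drawn at a 2:1 transition:transversion
  ratio; the reference base is allele 1.
- fragments: rounded lognormal, mean 45 bp, sd 10 bp, clamped to 20–80 bp.
- endogenous fraction 0.1 (degraded samples commonly sit near 10 %),
  mitochondrial fraction 0.001 of endogenous molecules.
- damage: each C at 5′ offset i flips to T with probability
  d₀·e^(−λ(i−1)), defaults d₀ = 0.30, λ = 0.3 — a strong non-UDG
  single-stranded-library signal; 3′-end damage is available by option and
  off by default since the 5′ profile is the reporting convention.
- capture: molecules overlapping a target footprint carry weight
  enrichment_factor × GC multiplier; off-target, mitochondrial and
  exogenous molecules carry weight 1; reads are retained by thinning
  proportional to weight. The saturation regime caps the achievable
  expected target efficiency: when the configured enrichment would exceed
  `saturation_cap`, the on-target weight is rescaled so the expected
  efficiency equals the cap — the simplest mechanism that produces the
  efficiency/fold-enrichment plateau observed when hybridization saturates,
  since no quantitative saturation model is established.
- duplicates: each retained molecule is re-emitted k extra times with
  k geometric, so the expected duplicate fraction equals
  `duplication_rate` (default 0.3, a moderate value for PCR-amplified
  captured aDNA libraries); duplicates are flagged in SAM and truth.
- exogenous molecules are unalignable random sequence emitted unmapped;
  environmental contamination that happens to map is not modelled.

Because placements are uniform and footprints non-colliding, the expected
on-target probability of an endogenous molecule has a closed form, which
`calibrate_enrichment()` inverts to hit a requested on-target raw-read
fraction exactly in expectation — useful for building truth scenarios with
known rates.

What the simulator does *not* emulate: sequencing error, indels and gapped
alignments, paired-end mechanics, platform quality profiles, mappability
and reference bias, contaminant genomes that align. Passing tests therefore
demonstrate the correctness of the metric definitions and the pipeline's
bookkeeping on idealised alignments — not robustness to alignment artefacts
in real data, which enter upstream of this package's scope.

## Verification strategy and problem sizes

The test suite checks every metric three ways: worked arithmetic identities
at full floating-point precision; exact equivalence between the pipeline and
independent plain-R brute-force recounts of the simulator's truth tables
(interval logic via `findInterval`, orientation via `chartr`, no shared code
path) on a seeded 100,000-read run; and stochastic recovery of programmed
truth parameters at stated tolerances — on-target fraction 0.25 within 3
binomial standard errors at 100k reads, enrichment factor 8 within ±10 %,
d₀ = 0.30 within ±0.02 at 50k reads, a GC capture multiplier of 0.5 above
bin 70 within ±0.1, and the duplication rate within ±10 %. The allelic-bias
test is calibrated on 2,000 null replicates (m = 100 sites, depths 3–30;
type-I error 0.05 ± 0.01) and must exceed 90 % power at a true ratio of 0.6
with nᵢ = 20, m = 100 at the Bonferroni threshold. These problem sizes keep
the whole suite and the acceptance script within a few minutes on a single
CPU while leaving the stochastic bands at three or more standard errors.

## Known limitations

- The genotyper is a threshold caller; studies needing genotype
  likelihoods should genotype externally and feed the allele-count tables
  in (`allele_bias_table()` accepts any pileup-shaped table).
- Overlap classification is single-valued by precedence; reads spanning a
  comparable and a noncomparable footprint count once as comparable, which
  slightly favours the comparable numerator when footprints are adjacent.
- The saturation cap is phenomenological: it reproduces the plateau, not
  the hybridization kinetics behind it.
- Expected-coverage estimates inherit the assumptions of the qPCR method:
  uniformly distributed reads and negligible duplication in the shallow QC
  sequencing.
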