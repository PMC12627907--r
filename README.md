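# enrichQC

Quality control for in-solution hybridization-capture (target-enrichment)
experiments on degraded and ancient DNA.

Ancient-DNA libraries typically contain a few percent endogenous DNA in short
(~30–80 bp), deaminated fragments. In-solution capture with biotinylated
probes enriches a panel of target SNPs before sequencing, and the practical
questions are always the same: how much of the sequencing effort landed on
target, how much better than shotgun is that, how even is the coverage, is
capture biased by GC content or against one allele at heterozygous sites, and
does the damage signal survive enrichment? `enrichQC` computes this whole
evaluation battery for one or two competing probe designs (e.g. a tiled
121 bp ssRNA design versus a single-probe 80 bp dsDNA design), and ships a
synthetic aDNA capture simulator with per-read ground truth so the full
pipeline is testable without any external data.

## What it computes

For two panels A and B, the *comparable targets* are the geometric
intersection of the two footprints at SNPs shared by both designs; targets
unique to one design are *noncomparable* and excluded from both sides of the
cross-kit ratios. With reads classified against that partition:

- **On-target rate** = 100 × comparable reads (incl. duplicates) /
  (total raw reads − noncomparable reads)
- **Target efficiency** = 100 × comparable reads /
  (total mapped reads − noncomparable reads), with a duplicate-removed
  variant, and what-if adjustments that rescale on-/off-target read counts
  (probe-tiling and panel-size scenarios)
- **Fold enrichment** = target efficiency after capture / target efficiency
  of the same library shotgun-sequenced
- **Expected coverage** = qPCR molecules × (mapped/total reads) × mean read
  length / genome length × volume fraction of the library used
- **Coverage evenness**: per-SNP depth at the exact SNP base; % of SNPs
  reaching 1×–5×, flagged when ≥ 80 % of SNPs meet a threshold
- **GC bias**: 80 bp windows over the targets binned by integer GC%;
  per-bin normalized coverage (1 = mean); AT dropout = Σ positive
  (window% − read%) over bins 0–50, GC dropout the same over bins 50–100
- **Damage**: positional C→T substitution rate from the 5′ read end
  (minus-strand alignments reoriented), with an exponential-decay fit
  d(i) = d₀·e^(−λ(i−1))
- **Genotyping**: quality-filtered allele counts at panel SNPs (mapq ≥ 20,
  baseq ≥ 20, duplicates excluded, 5 bp end-trim first), a threshold
  genotyper (min depth 3), and concordance against a shotgun baseline
  (match = at least one shared allele)
- **Allelic bias**: per variant class (AG, CT, AC, AT, CG, GT), an
  intercept-only quasibinomial test of the allele-depth ratio against 0.5,
  with per-sample Bonferroni correction (default family 0.05/18)

## Worked example

Simulate a capture experiment (15 % endogenous DNA, 40× on-target capture
weight, 30 % PCR duplicates, d₀ = 0.3 deamination), then run the QC:

```r
library(enrichQC)

cfg <- sim_config(seed = 42, genome_length = 2e6, n_snps_a = 500L,
                  n_snps_b = 1100L, n_reads = 50000L,
                  endogenous_fraction = 0.15, enrichment_factor = 40,
                  duplication_rate = 0.3, d0 = 0.3, lambda = 0.3)
sim  <- simulate_dataset(cfg, panel = "a")
part <- comparable_partition(sim$panels$panel_a, sim$panels$panel_b)
#> comparable_partition: 500 comparable, 0 only-myBaits, 600 only-Twist

counts <- tally_sample(sim$reads, part, total_raw = nrow(sim$reads))
on_target_rate(counts)              # 14.9 %
target_efficiency(counts)           # 48.2 %
mito_fraction(counts)               # 0.006 % of mapped

depths <- snp_site_depths(sim$reads, sim$panels$panel_a$sites)
snp_site_coverage(depths)           # 5.4 x
evenness(depths)
#>   threshold pct_snps  flag
#> 1         1     97.6  TRUE
#> 2         2     91.8  TRUE
#> 3         3     82.2  TRUE
#> 4         4     69.8 FALSE
#> 5         5     57.4 FALSE

prof <- ct_profile(sim$reads, sim$genome)
attr(prof, "first_base_rate")       # 0.323
fit_damage_decay(prof)              # d0 = 0.315, lambda = 0.305
```

Read the numbers as a practitioner would: ~15 % of all raw sequencing
(including the unmappable exogenous fraction) landed on comparable targets,
and 48 % of *mapped* reads did; mean SNP coverage is 5.4× with 82 % of SNPs
at ≥ 3×, so the 80 %-of-SNPs evenness flag holds up to 3×; the first-base
C→T rate of 0.32 and fitted decay recover the simulated damage model,
confirming the library behaves like a non-UDG single-stranded aDNA library.

`run_capture_qc()` wraps all stages for a sample sheet and writes
`metrics.tsv`, `evenness.tsv`, `gc.tsv`, `damage.tsv`, `allele_bias.tsv` and
`summary.json`; `compare_kits()` produces the paired two-kit comparison
table.

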