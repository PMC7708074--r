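# cracbind

Downstream analysis of CRAC (UV crosslinking and analysis of cDNA)
experiments for RNA-binding-protein target mapping, written for
computational biologists who have aligned CRAC reads in hand and want the
standard post-alignment battery: RNA-class composition, 5'UTR/CDS/3'UTR
binding geometry, replicate statistics, and enrichment-based target
calling against RNA-seq. A seeded synthetic-data generator with ground
truth makes every stage testable end to end, and a small protein toolkit
covers the conservation analysis of R3H-SUZ domain proteins.

## What it computes

Starting from uniquely mapped reads (BED6 or SAM/BAM) and a GFF3
transcriptome annotation:

* **Class shares** — each read's midpoint assigns it to one RNA class
  (priority rRNA > tRNA > snRNA > snoRNA > mRNA > other, else intergenic).
* **Counts and RPM** — per-transcript counts by strand-aware midpoint
  containment (ties by largest exonic overlap, then id);
  `rpm = count / library * 1e6` over transcriptome-assigned reads.
* **Metagene profiles** — each mRNA rescaled to 120 bins (10 / 100 / 10
  for 5'UTR / CDS / 3'UTR); a transcript's reads are normalized to 1 and
  the aggregate is the unweighted mean over transcripts passing an RPM
  filter (default > 100 RPM), so the profile reflects binding geometry,
  not abundance. Region fractions, boxplot summaries (type-7 quartiles,
  1.5 IQR whiskers) and heatmap matrices accompany it.
* **Replicate statistics** — Spearman/Pearson correlations and sample PCA
  on `log2(rpm + 1)`.
* **High-confidence targets** — per mRNA, all three strict criteria:
  mean CRAC RPM > 128, CRAC/RNA-seq ratio > 1.5, and a one-sided
  enrichment p < 0.01. The default test standardizes each transcript's
  log2 effect by the robust transcriptome-wide effect distribution
  (an empirical-null moderated z, calibrated under correlated technical
  replicates); Welch t variants are available.
* **Coverage tracks** — per-base bedGraph export of raw unique-read
  coverage.
* **Domains toolkit** — consensus-motif scanning (e.g. the SUZ motif
  `EERXXXYXXXRX+IF`, `+` = K/R), global-alignment percent
  identity/similarity (BLOSUM62, gap 10/0.5), greedy 60% redundancy
  reduction, and R3H-SUZ region extraction (residues 5–195 by default).

## Worked example

Simulate a small experiment (500 mRNAs, 2x2 tagged replicates plus an
untagged control, 40 spiked targets at 4–8x enrichment) and run the
pipeline:

```r
library(cracbind)

cfg <- sim_config(n_mrna = 500, n_ncrna = c(rRNA = 5, tRNA = 15, snRNA = 2,
                                            snoRNA = 10, other = 3),
                  reads_per_sample = 2e5, n_true_targets = 40,
                  target_enrichment = c(4, 8), seed = 7)
sim   <- simulate_transcriptome(cfg)
reads <- simulate_crac_experiment(sim)

classify_reads(reads, sim$annotation)   # class shares per sample
#>       sample      class  count fraction
#>  tagged_b1t1       rRNA  50166 0.250830
#>  tagged_b1t1       tRNA   9956 0.049780
#>  tagged_b1t1      snRNA   4033 0.020165
#>  tagged_b1t1     snoRNA   6044 0.030220
#>  tagged_b1t1       mRNA 119812 0.599060
#>  tagged_b1t1      other   9989 0.049945
#>  tagged_b1t1 intergenic      0 0.000000

cm <- rpm_normalize(count_per_transcript(reads, sim$annotation))
cm <- add_counts(cm, simulate_quant_experiment(sim, "rnaseq"), "rnaseq")

profs <- metagene_profiles(reads, sim$annotation)
aggregate_metagene(profs, cm, min_rpm = 100)
#> <metagene_profile> aggregate over 453 transcripts; 3'UTR mass 0.751

rc <- count_by_region(reads, sim$annotation)
rf <- region_fraction(pool_region_counts(rc))
region_fraction_summary(rf)
#>           f5  fcds    f3
#> median 0.049 0.199 0.752
#> mean   0.050 0.199 0.751

sm <- sample_matrix(cm)
correlate(sm, "tagged_b1t1", "tagged_b2t1", "spearman")
#> [1] 0.849

tc <- call_targets(mrna_counts(cm, sim$annotation))
tc
#> <target_calls> 500 transcripts, 42 high-confidence (RPM > 128, ratio > 1.5, p < 0.01; pooled_z test)
#>    transcript_id crac_rpm rnaseq_rpm ratio   p_value ...
#> 1     mRNA_00136     9376     1257.5 7.456 2.079e-09
#> 2     mRNA_00092    11385     1540.0 7.393 2.421e-09
```

Reading the output: ~75% of per-transcript binding mass sits in 3'UTR
bins/regions (the simulated protein is a 3'UTR binder); biological
replicates rank-correlate at ~0.85; and 42 transcripts clear all three
target filters, 40 of them the spiked ground-truth targets.

`run_pipeline(cfg, outdir)` chains all stages (simulate, classify, count,
metagene, stats, call-targets, track, domains), writes fixed-name TSV /
bedGraph artifacts plus a `manifest.json` with parameters, seed and file
checksums, and is also exposed as a thin command line
(`inst/scripts/cracbind.R <stage|all> --outdir DIR [--config cfg.yaml]
[--seed N] ...`).

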