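# synthassoc

Case–control association simulations contrasting **synthetic associations**
— significant common array markers driven by one or more *rare* causal
variants in partial linkage disequilibrium with them — with **natural
associations**, whose causal variants are themselves common. The package is
aimed at statistical geneticists studying what synthetic associations imply
for GWAS interpretation and fine-mapping design: how far from an associated
marker one must sequence to capture a causal variant, and whether the minor
allele frequency (MAF) profile of associated markers can flag rare causal
variants at play.

## What it computes

The pipeline simulates a fully resequenced 100-kb disease locus with 3-cM
flanks under a coalescent (SMC′) with either a constant-size or a
bottleneck-plus-growth demography, expands the panel to a study population
of 10,000 diploids with a Li–Stephens mosaic resampler, ascertains
common-biased array markers, and then runs the disease model: for a causal
set *C* drawn from a frequency window (rare 0.005–0.04, common 0.1–0.3),
individual disease risk is

> *p<sub>i</sub>* = min(1, π₀ · γ^*a<sub>i</sub>*),

with baseline risk π₀ = 0.15, genotypic relative risk γ (1.5 for common,
3 for rare causal variants) and *a<sub>i</sub>* the individual's total
risk-allele count over *C*. 1,000 cases and 1,000 controls are sampled by
status, every array marker within 3 cM of the locus is tested by logistic
regression of case status on allele dosage (Wald test, Firth fallback on
separation), and significance uses a region-wide Bonferroni threshold
α/M (α = 0.05).

Pooling 50 causal sets × 10 phenotype replicates per scenario and locus
yields the signature statistics: genetic distance from each significant
marker to the causal variant it is in highest r² with, capture curves over
resequencing window sizes, Gabriel LD-block capture, associated-MAF
summaries (median, fraction < 0.1, SD), the MAF of the most significant
association per test, and an age-of-mutation partition of rare causal
variants (minor allele absent from an out-panel = relatively more recent).

## Worked example

A desk-scale run of one European-like locus under a natural and a synthetic
scenario (about 15 s):

```r
library(synthassoc)
cfg <- experiment_config(
  demographies = "bottleneck_growth",   # European-like growth demography
  n_loci = 1, n_pop = 10000,
  scenarios = scenario_presets()[c("common2_grr1.5", "rare5_grr3")],
  n_sets = 6, n_replicates = 2, seed = 42)
run <- run_experiment(cfg)
print(run$summary[, c("scenario", "n_tests_sig", "median_dist_cm",
                      "capture_0.1cm", "median_maf", "frac_maf_below_0.1",
                      "sd_maf")], digits = 2)
#>           scenario n_tests_sig median_dist_cm capture_0.1cm median_maf
#> 1 common(2) GRR1.5          11          0.013             1       0.38
#> 2     rare(5) GRR3           8          0.018             1       0.17
#>   frac_maf_below_0.1 sd_maf
#> 1               0.00  0.103
#> 2               0.19  0.087
```

Reading the numbers: of 12 tests per scenario, 11 (natural) and 8
(synthetic) produced at least one significant association. Synthetic
associations sit slightly further from their highest-r² causal variant
(median 0.018 vs 0.013 cM) — both far below the 0.15 cM bound — and every
test that found an association captured a causal variant within 0.1 cM
(`capture_0.1cm = 1`). The MAF signature separates the scenarios: no
natural association had MAF < 0.1, versus 19% of synthetic ones, whose
median MAF is also much lower (0.17 vs 0.38). At this desk scale the SD
contrast is noisy; the pooled runs in `analysis/` show the full pattern.

The `analysis/` directory contains the numbered workflow drivers
(`01_simulate_panels.R` … `05_age_partition.R`) that run the complete study
at a chosen `--scale` and write TSV tables under `results/`.

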