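---
title: "Simulating signatures of synthetic and natural GWAS associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating signatures of synthetic and natural GWAS associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A genome-wide association study genotypes common "tag" markers and compares
their allele frequencies between cases and controls. When the true causal
variants at a locus are *rare* (risk-allele frequency 0.005–0.04), one or
more of them can nevertheless drive a significant signal at a common marker
that is in partial linkage disequilibrium (LD) with them — a *synthetic
association*. When the causal variant is itself common (frequency 0.1–0.3),
the resulting signal is a *natural association*. The two kinds of
association have different practical consequences for fine-mapping: how far
from the signal must one sequence to capture a causal variant, and can the
associated marker's minor allele frequency (MAF) profile flag rare causal
variants at play?

`synthassoc` implements, as a tested and reusable pipeline, a simulation
study of these signatures: a disease locus with realistic rare-variant
content is simulated, causal variants are drawn under controlled scenarios,
disease risk is assigned under a genotypic-relative-risk (GRR) model,
cases/controls are sampled, an array-based region-wide association scan is
run, and the signature statistics are pooled.

## The pipeline, stage by stage

### 1. Coalescent simulation of a resequenced disease locus

`simulate_panel()` draws a phased haplotype panel for a region consisting of
a 100-kb central disease locus plus 3 cM of flanking sequence on each side,
under the sequentially Markov coalescent (SMC'). Marginal genealogies are
updated along the sequence at recombination breakpoints (rate: total branch
length per Morgan), the detached lineage re-coalescing against the full
standing genealogy — the SMC' variant, which is an accurate approximation of
the full coalescent with recombination at these scales. Mutations are
Poisson on branches (infinite sites).

Two demographies are provided (`demography()`):

* `constant` — diploid effective size $N_e = 10{,}000$ at all times
  (a West-African-like baseline);
* `bottleneck_growth` — exponential growth from $N_e = 1{,}000$ at 2,000
  generations ago to $N_e = 10^6$ at present, ancestral size 10,000 (a
  European-like history; the recent explosive growth inflates the proportion
  of rare variants, which is what makes synthetic associations interesting).

The mutation rate defaults to $1.2\times10^{-8}$ per bp per generation and
the recombination backdrop to a constant 1.3 cM/Mb (the human genome-wide
average). Under the constant demography the simulator is calibrated against
closed-form coalescent theory: the tests check the segregating-site count
against the Watterson expectation $\theta \sum_{i<n} 1/i$ and pairwise
diversity against $\theta$; under the growth demography the tests check the
rare-variant excess (fraction of variants with MAF < 0.04) against the
constant preset across seeds.

```{r}
library(synthassoc)
sim <- simulate_panel(demography("bottleneck_growth"),
                      locus_length = 1e5, flank_cm = 3, n_hap = 220,
                      seed = 7)
sim$panel
```

### 2. Mosaic expansion to a study population

Resequencing panels are small (220 haplotypes by default), so
`resample_mosaic()` expands them to a study population (10,000 diploids by
default) with a Li–Stephens copying model: each new haplotype copies a
uniformly chosen template, switching templates along the genetic map as a
Poisson process with intensity $\lambda$ per cM (so the switch probability
between adjacent variants $d$ cM apart is $1-e^{-\lambda d}$), with a
per-site copying-error rate $\varepsilon$. The default
$\lambda = 4 N_e \cdot 0.01 / k$ per cM (with a fixed scaling size
$N_e = 10{,}000$ and $k$ the panel size) is the Li–Stephens effective
switch rate; $\varepsilon$ defaults to $10^{-4}$, i.e. essentially no new
mutations, matching the null copying-mutation setting of HAPGEN-style
expansion. Using the present-day size of the growth demography here would
be wrong — it would shred the very LD the resampler must preserve — which is
why the scaling size is fixed rather than taken from the demography.

Two properties of this resampler are load-bearing and tested: output allele
frequencies are binomial around panel frequencies (no systematic drift), and
mean pairwise $r^2$ binned by genetic distance matches the panel within
0.05 for common variants. Because template switches target a uniformly
chosen haplotype, the copying process restricted to any subset of sites has
the same law as the full process observed at those sites; the pipeline
exploits this by expanding only the columns it needs (disease-locus variants
plus array markers), which is exact, not an approximation.

### 3. Array ascertainment

`ascertain_array()` emulates the genotyping array: variants with panel MAF
at or above 0.05 are eligible and are thinned to a mean spacing of ~2,000 bp
(about the density of the combined Affymetrix 6.0 + Illumina 1M arrays).
Within each spacing bin the pick is made with probability proportional to
MAF: a sequencing-derived site-frequency spectrum is approximately
$\propto 1/f$, so MAF-proportional thinning yields the roughly flat marker
MAF spectrum characteristic of double-hit-ascertained commercial arrays.
Without this (option `weight = "uniform"`), ~30% of markers would sit at
MAF 0.05–0.1, which is array-unrealistic and inflates the low-MAF tail of
natural associations.

### 4. Disease model and case/control sampling

For a scenario with $m$ causal variants, frequency window $[l, h]$ (measured
in the expanded sample) and genotypic relative risk $\gamma$,
`select_causal()` draws $m$ distinct eligible variants uniformly at random
from the central locus (flanks never contain causal variants; singletons in
the pre-expansion panel are never eligible). `assign_risk()` sets individual
risk

$$p_i = \min\!\left(1,\; \pi_0\, \gamma^{a_i}\right),$$

where $\pi_0 = 0.15$ is the baseline risk and $a_i$ the individual's total
risk-allele count over the causal set. This per-copy multiplicative rule is
the package default; `rule = "carrier"` applies a single factor $\gamma$ to
carriers of any risk allele instead. The choice matters and is genuinely
open: with two *common* causal variants the per-copy rule lets risk compound
across variants (up to $\gamma^4$), so haplotypes carrying several risk
alleles produce stronger marker signals — including occasional significant
markers of low MAF — whereas the carrier rule caps every carrier at
$\pi_0\gamma$ and produces none of that amplification but much lower power.
For *rare* causal variants the two rules nearly coincide (multi-carriers are
vanishingly rare). We keep per-copy as the default because it makes
$\gamma = 1$ an exact null and is the standard reading of "per-allele GRR";
the consequences of this choice for the MAF signature are discussed under
*Limitations*.

`sample_case_control()` draws disease status independently as
Bernoulli($p_i$), then samples 1,000 cases and 1,000 controls uniformly
without replacement from the affected and unaffected pools, redrawing
statuses (up to `max_retries`) if a pool is short — rare-variant scenarios
can produce small affected pools. `null_assignment()` provides the matching
null: labels assigned at random with no genotype dependence.

### 5. Region-wide association scan

`region_scan()` tests every array marker whose genetic position lies within
3 cM of the disease locus (closed interval), excluding markers that are
themselves causal variants, by maximum-likelihood logistic regression of
case status on additive allele dosage (IRLS; Wald p-value) — the behaviour
of PLINK's logistic test. Significance uses a region-wide Bonferroni
threshold $\alpha / M$ with $\alpha = 0.05$ and $M$ the number of markers
actually tested. Monomorphic markers are skipped with NA. Markers with
detected separation or non-convergence (possible for rare markers in a
1,000 v 1,000 sample) fall back to a Firth-penalised fit and are flagged
rather than dropped — dropping them would bias capture fractions. The scan
core reduces each marker to its 2×3 phenotype-by-dosage table before
fitting, which is exact for 0/1/2 dosages and makes a ~2,000-marker scan
take a fraction of a second; the single-marker route is cross-checked in the
tests against `glm()` and against the closed-form 2×2 log odds ratio for
binary predictors.

### 6. Distances, capture curves, LD blocks

Genetic positions come from linear interpolation on the recombination map
(`genetic_position()`; constant-rate extrapolation beyond map ends). For
each significant association, `assoc_distance()` finds the causal variant in
highest $r^2$ (phased haplotype $r^2$ on the expanded sample; ties broken by
genetic proximity, then position) and records the distance to it and to the
closest causal variant — the latter is never larger, and the tests assert
this on every record. `capture_curve()` turns pooled distance records into
the fraction of tests that capture a causal variant within each window size
(0–10 cM grid, 0.005 cM steps).

`ld_blocks()` estimates Gabriel-style haplotype blocks on the array markers
of a seeded subsample of 2,000 diploids: D′ confidence intervals by
multinomial likelihood over a 0.005-step grid with 5% tails; "strong LD" =
CI within [0.70, 0.98+]; "strong recombination" = upper bound < 0.90; a
block requires a strong outermost pair and ≥95% strong informative pairs
(PLINK's defaults), with spans capped at 200 kb and markers below MAF 0.05
excluded. Each block is expanded by 0.0005 cM per side to absorb boundary
uncertainty before `block_capture()` asks whether an association's block
contains a causal variant.

### 7. Signatures and the age-of-mutation partition

`maf_summary()`, `top_assoc_maf()` and `compare_scenarios()` pool
significant associations across causal sets and replicates: median MAF,
fraction below 0.1, and the sample standard deviation (n−1) of associated
MAF — the statistic proposed as a practical flag for underlying rare causal
variants. Contrasts between scenarios come with bootstrap confidence
intervals obtained by resampling *tests*, not associations, respecting the
replicate structure (1,000 draws, seeded).

`classify_age()` implements the age partition: a rare variant (narrowed
window 0.005–0.02) is *more recent* if its minor allele is absent from every
out-panel, *older* otherwise. The pipeline realises out-panels by holding
out a subsample of haplotypes from the same coalescent simulation (a
zero-divergence split) rather than simulating a structured two-population
model: absence from an independent sample is already a recency signal —
young alleles sit on short external branches — so the partition works, but
it is weaker than with true population divergence, making the observed
more-recent > older distance ordering a conservative check.

## Study design and the desk profile

The full design mirrors the study: per demography × locus × scenario, 50
causal-variant sets × 10 phenotype replicates = 500 association tests,
with scenarios common(2) GRR 1.5, common(2) GRR 3, common(5) GRR 1.5,
rare(5) GRR 3, rare(9) GRR 3 and a random-label null. Loci are independent
seeded coalescent draws; locus-to-locus heterogeneity, a central observation
of the study, arises naturally from the coalescent rather than from five
named genomic regions. All randomness flows from one master seed through
`derive_seed()` (fixed-order hashing), so any stage is independently
reproducible, and every per-test record carries the seed that regenerates
it.

The tests and the acceptance script use a desk profile chosen to keep runs
in the minutes range while preserving every statistic's definition: 1–2 loci
per demography, 8–25 sets × 2 replicates, the full 10,000-diploid
population and 1,000 + 1,000 sampling for causal scenarios, and a
2,000-diploid population for the null scans. At these sizes the Monte-Carlo
error of pooled fractions is a few percentage points.

## What the synthetic data do and do not show

The generator reproduces the *mechanisms* behind the signatures: rare
variants are abundant (especially under growth), their tags are common
markers in partial LD, and the qualitative orderings all hold on seeded
runs — synthetic associations are further from their causal variants than
natural ones (per locus), raising the effect size of common causal variants
raises distance, the gap is not explained by the number of causal variants,
synthetic associations have lower median MAF, a larger fraction below 0.1
and a larger SD of MAF, the most significant association has reduced MAF,
and more recent rare causal variants give larger distances than older ones.
Median synthetic distances stay well inside the 0.15 cM bound, and ≥90% of
rare-causal tests capture a causal variant within 0.1 cM.

Two empirical features of real data are deliberately not modelled, and they
bound what passing tests mean:

* **Recombination hotspots.** The backdrop is uniform, so LD decays
  smoothly; Gabriel blocks are small (~0.007 cM flanked, matching the
  study's block scale) but sparse, and the fraction of associations whose
  block captures a causal variant is far below what hotspot-punctuated real
  maps give. Block capture is therefore reported but not compared to
  real-data values.
* **Empirical array/LD idiosyncrasies.** With a neutral coalescent and a
  flat marker MAF spectrum, a small excess (~2–7%, seed-dependent) of
  natural associations falls below MAF 0.1, driven by low-frequency markers
  in moderate LD with multi-risk-allele haplotypes under the per-copy risk
  rule; the carrier rule reproduces the near-absence of such associations
  at the cost of much lower power. On real HapMap LD this fraction was
  <1%. The direction of the natural/synthetic contrast is unaffected.

## Numerical choices

* Coordinates: 1-based inclusive physical positions (VCF convention);
  cumulative cM from region start; the ±3 cM scan window and block
  intervals are closed.
* Monomorphic markers: skipped with NA, excluded from the Bonferroni count
  $M$ (they are not tests).
* Tie-breaks: highest-$r^2$ causal by genetic proximity then bp; "most
  significant association" by p, then larger |β|, then bp. Both are
  deterministic and conservative for distance claims.
* D′ grid step 0.005 with 5% tails; logistic IRLS tolerance $10^{-8}$,
  maximum 30 iterations, separation flagged at |β| > 12 or SE > 50.
* SD of associated MAF uses the sample (n−1) denominator.
* File I/O: phased VCF v4.2 and 3-column HapMap-format genetic maps;
  coordinates are written with `%.17g` so write→read round trips are
  bit-exact.

## Known limitations

Besides hotspots and the risk-rule ambiguity discussed above: phasing and
imputation of real unphased data are out of scope (synthetic data are
phased and complete by construction); there is no genotyping error, no
covariates or population structure in the phenotype model, and no
rare-variant burden testing; X-chromosome handling is absent; and the
age partition uses zero-divergence out-panels, so its more-recent class is
noisier than a cross-population classification would be.
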