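---
title: "Bootstrap stability analysis of circulating miRNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap stability analysis of circulating miRNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirboot)
library(dplyr)
```

## The problem

Circulating microRNAs in maternal plasma respond to prenatal alcohol
exposure and are candidate biomarkers for fetal alcohol spectrum
disorders. Whether that response depends on fetal sex is hard to test in
typical cohorts: disaggregating ~20-35 subjects per exposure group by
fetal sex leaves strata of 7-22 samples, too small for stable
single-shot hypothesis tests. `mirboot` implements the resampling
strategy built for exactly this situation: instead of a single p-value
per miRNA, every statistic is recomputed over thousands of bootstrap
resamples (drawn with replacement, each stratum to its own size), and
inference is based on the *stability* of the statistic across resamples.
The same machinery replaces multiple-testing correction: a result is
trusted when it recurs in most resamples, not when a single p-value
survives an adjustment.

The cohort design the package assumes has three exposure groups
(unexposed `UE`; heavily exposed, infant apparently unaffected `HEua`;
heavily exposed, infant affected `HEa`), two fetal sexes, and two
sampling time points (mid-pregnancy and late pregnancy, "trimester 2"
and "trimester 3").

## The pipeline

### Preprocessing

qPCR cycle-threshold (Ct) values are preprocessed in three fixed steps:

1. **Sentinel imputation** (`impute_undetected()`): reactions that never
   crossed the amplification threshold are assigned Ct = 45, the last
   cycle of the run.
2. **Expression filter** (`filter_expressed()`): an assay is kept when
   detected in at least 80% of the samples. The threshold is inclusive
   (exactly 80% passes). The default pools all samples across exposure
   groups; a per-group mode (`by_group = TRUE`) requires the threshold
   within every group, because "at least 80% of the samples in all
   groups" admits both readings. Detection is an input flag from the
   instrument, never a Ct cutoff invented downstream.
3. **Global-mean normalization** (`global_mean_normalize()`): each
   retained assay's Ct is expressed relative to the average Ct of all
   retained assays in the same sample (delta-Ct). This removes
   per-sample additive technical offsets exactly and is the
   best-performing normalizer for large miRNA panels without spike-in
   controls. A consequence worth remembering: after normalization only
   *relative* contrasts between assays are identifiable.

### The resampling engine

All analyses share one primitive (`resample_strata()`): within each
stratum, draw sample positions uniformly with replacement until the
stratum size is reached. Draws are keyed by
`(master seed, analysis stream, iteration, stratum)` through a
deterministic integer hash, so

* every result is exactly reproducible from the seed,
* draws are independent across strata and iterations,
* adding a new analysis never perturbs existing results, and
* results do not depend on the row order of the input tables
  (strata are sorted by sample id before drawing).

One draw per iteration is shared across the whole miRNA panel. The
marginal distribution of any per-miRNA statistic is identical to using
a separate stream per miRNA (the strict audit mode, `per_mirna = TRUE`),
but sharing is orders of magnitude faster because every test is then a
vectorized matrix operation across the panel.

The default iteration count is B = 2000 at significance level 0.05.
`iteration_calibration()` reproduces the selection procedure: the
across-run variance of the mean bootstrap statistic shrinks roughly as
1/B over a grid from 50 to 3000 iterations, and 2000 is comfortably on
the flat part of that curve.

### Significance-stability profiles

`stability_profile()` reports, per miRNA and stratum (aggregated, male,
female), the proportion of iterations in which a one-way ANOVA across
the three exposure groups (or an ANCOVA adjusting for gestational age at
blood draw) is significant at p < 0.05. Implementation notes:

* The ANOVA is computed from group sums and sums of squares across the
  whole panel at once; the ANCOVA is the F drop test of the group factor
  against the covariate-only model, via one QR decomposition per
  iteration.
* Resampling can duplicate one sample enough times to produce a
  zero-variance group. Such degenerate iterations count as
  *non-significant* rather than being redrawn, keeping the iteration
  count fixed.
* For ANCOVA the default covariate is the gestational age at the blood
  draw being analyzed; `covariates = "both"` uses both draws' ages.

A miRNA is classified **fetal sex-specific** (`classify_sex_specific()`)
when a sex stratum's proportion strictly exceeds both the aggregated
proportion and 0.5. Both inequalities are strict; ties do not count.
A miRNA whose aggregated proportion is already above 0.5 can still be
classified when a stratum strictly improves on it.

### Effect sizes

`hedges_g()` implements the standardized mean difference with the
small-sample correction J = 1 - 3/(4N - 9), exposed group minus
unexposed reference, computed on delta-Ct. **Sign convention:** higher
Ct means lower abundance, so positive g = lower abundance in the exposed
group. `bootstrap_effect_size()` reports the median and the 2.5/97.5
bootstrap percentiles (linear interpolation between order statistics)
over B iterations; zero-pooled-SD draws contribute g = 0. Three
classification rules follow:

* `classify_significant_effect()`: the 95% interval excludes zero
  (endpoints touching zero do not count);
* `classify_outside_composite()`: a sex-stratified median falls strictly
  outside the composite sample's interval;
* `baseline_dimorphism()`: within the unexposed group only, the
  male-minus-female bootstrap g excludes zero.

### Correlation networks

`pearson_matrix()` builds the full product-moment correlation matrix of
one stratum with two-sided p-values from the t transform; constant
columns yield r = 0, p = 1 so the pair universe never shrinks, and
perfect correlations are clamped to the smallest positive double.
`bootstrap_correlation_counts()` resamples the stratum and records the
number of significant pairs per iteration; internally it thresholds
|r| at the critical value equivalent to p < 0.05, which is exactly the
same rule and much cheaper than materializing the p matrix 2000 times.

`correlation_count_test()` is the count-exceedance test: the fraction of
exposed-group iterations whose count strictly exceeds the mean reference
(unexposed) count, subtracted from 1. Ties do not exceed. Two honest
caveats, visible in the package's own calibration tests: the bootstrap
inflates counts (duplicated samples inflate |r|), and it inflates them
more for smaller strata, so a small reference stratum makes the test
conservative; and the null distribution of the p-value is not uniform —
the test is a descriptive exceedance probability, not an exact test.

`partial_correlation_matrix()` controls for gestational age by the
residual method (correlations of least-squares residuals), and
`correlation_concordance()` compares full and partial matrices by the
squared correlation of their upper triangles.

### Chromosome-pair enrichment

Significant miRNA pairs are mapped to unordered chromosome-label pairs
(`map_pairs_to_chromosomes()`; intra-chromosome pairs are legal
buckets, labels are strings so X and Y survive). Per pair,
`percent_change()` is `100 (exposed - control) / control`; pairs absent
from the control group are undefined and excluded from
`top_pairs()` ranking (ties broken by exposed count, then pair label,
for a deterministic order).

### Cohort statistics

`fisher_exact_rxc()` (Freeman-Halton two-sided exact test, with a
seeded >= 10^6-draw Monte Carlo tail for tables larger than 3 x 3) and
`kruskal_wallis()` (tie-corrected) reproduce the demographic table
statistics; `demographic_tables()` packages the reference cohort's
printed count tables, whose recomputed p-values are the package's fixed
numerical anchors.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates cohorts
with known ground truth so that every downstream stage has a recovery
test. The generative model per entry is

```
Ct_ij = base_i + shift_j + slope_i (GA_j - mean GA)
        + planted group/sex shift + factor contribution
        + N(0, noise_sd)
```

with per-miRNA baseline Ct ~ U(22, 35), per-sample technical shift
~ N(0, 1 Ct), residual SD 1.5 Ct, and gestational ages
N(18.9, 4.9) / N(33.1, 2.4) weeks clipped to 10-42. Stratum sizes
default to the reference cohort design (25/19/24 samples in trimester 2
and 36/23/34 in trimester 3, with the matching male/female splits).
Undetected entries are generated as missing-with-flag with a per-miRNA
dropout probability; the Ct = 45 substitution is deliberately left to
preprocessing so generation and imputation stay separable.

Choices that were genuinely open, and how they were fixed:

* **Ct distribution parameters.** No reference distributions exist for
  this panel chemistry; U(22, 35) baselines with 1.5-cycle noise are
  plausible for plasma panels and are config-exposed, not hard-coded.
* **Dropout mixture.** 75% of candidate assays are robustly expressed
  (dropout U(0, 0.02)) and 25% poorly detected (U(0.3, 0.9)), so the
  80% filter keeps roughly 150 of 200 candidates. The low component is
  deliberately small: a Ct = 45 sentinel is a 10-20-cycle outlier, and
  at realistic stratum sizes even a 5% dropout rate would put a
  sentinel in half of all 13-sample columns and erase genuine
  correlation structure that robustly expressed miRNAs do show.
* **Co-secretion model.** The factor is a single latent Gaussian added
  to member miRNAs in selected (group, sex, time point) strata — the
  simplest structure that produces a dense cross-correlated block.
  Member loadings alternate in sign. This matters: delta-Ct values are
  relative abundances, and a one-signed factor spanning a large block
  is largely absorbed by the global-mean normalizer; a sign-balanced
  factor is orthogonal to the per-sample mean, so the planted
  member-pair correlation (|r| = loading^2 x scale) survives
  normalization, and mixed-sign correlation blocks are what the real
  networks show.
* **Co-secretion defaults.** 100 members of the 200-candidate panel at
  loading 0.95 (member |r| = 0.9) reproduce the observed density of
  exposed-female networks (roughly 30% of all pairs significant). The
  factor is fully active in HEa-female strata at both time points and
  in HEa-male late pregnancy, and active at `scale = 0.8` in
  HEua-female mid-pregnancy. The 0.8 is calibrated from the reported
  count excess of the intermediate group relative to the affected
  group (~0.72), mapped through the pairwise-significance power curve
  at n = 12 — i.e. the intermediate stratum is intermediate in the
  same sense the real data were.
* **X enrichment.** Half of the members are requested from
  X-chromosome-annotated miRNAs, capped by the X pool implied by the
  chromosome weights (which follow the approximate distribution of
  annotated human miRNAs, X included).

What the generator does **not** emulate: hemolysis and other sample-QC
failures, plate and inter-run effects, detection that depends on
abundance (dropout is independent of the latent Ct), and non-Gaussian
expression noise. Passing recovery tests therefore show that the
*statistics* behave as intended under the assumed design — not that the
biological conclusions of any particular cohort are correct.

## Reference problem sizes

The package's own test suite exercises the pipeline at the cohort's
design sizes (161 samples, 150-200 assays) with 100-1000 bootstrap
iterations per check and 10-50 simulation seeds per recovery rate;
production analyses use B = 2000. These sizes were chosen so the full
suite documents the method's operating characteristics while remaining
routine to run on a laptop.

## Known limitations

* The count-exceedance test inherits the bootstrap's small-sample
  inflation of correlation counts; comparisons against a much smaller
  reference stratum (e.g. 8 unexposed females at mid-pregnancy) are
  conservative, and an intermediate-strength effect in a 12-sample
  stratum sits close to that test's detection limit. In the package's
  own acceptance suite the full cross-strata activity pattern (eight
  cells, all of which must agree) is recovered in roughly 60% of
  seeds; the fully active strata are recovered essentially always, and
  the intermediate female stratum against the 8-sample unexposed
  reference is the binding cell.
* The sex-specific classification rule (stratum proportion > aggregated
  and > 0.5, both strict) has a null flag rate of roughly 15% at these
  stratum sizes (measured in the acceptance suite over 50 seeded
  cohorts): a null miRNA that draws a lucky observed difference in one
  sex keeps it in most resamples. The rule trades
  specificity for sensitivity exactly as the stability heuristic
  intends; users should treat classified miRNAs as candidates, not
  discoveries.
* Percentile intervals (not BCa) are used throughout, matching the
  method; they can undercover slightly for skewed statistics at the
  smallest stratum sizes.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 1,
                                  cosecretion = cosecretion_spec()))
dct <- global_mean_normalize(impute_undetected(sim$ct),
                             filter_expressed(sim$ct))
cfg <- bootstrap_config(n_iterations = 2000, seed = 1)

prof <- stability_profile(dct, sim$meta, time_point = 2, config = cfg)
classify_sex_specific(prof) |> dplyr::filter(label != "none")

heaF <- bootstrap_correlation_counts(dct, sim$meta, "HEa", 2, sex = "F",
                                     config = cfg)
ueF <- bootstrap_correlation_counts(dct, sim$meta, "UE", 2, sex = "F",
                                    config = cfg)
correlation_count_test(heaF, ueF)
```
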