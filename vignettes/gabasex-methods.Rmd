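---
title: "Models, simulations and design choices in gabasex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulations and design choices in gabasex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gabasex` implements a chain of analyses linking sex-related factors to
the expression of GABA-related genes (*SST*, *GAD67*, *GAD65*): effect-size
meta-analysis of case-control expression studies with a sex moderator,
seed-gene co-expression networks, sex-stratified X-chromosome eQTL mapping,
and a genetic-sex × gonadal-sex × hormone factorial analysis in Four Core
Genotypes (FCG) mice. This vignette documents the statistical models, the
synthetic study system every stage is tested against, the numerical
choices, and the limits of what the simulations can show.

## 1. Meta-analysis stage

### Model

Each study contributes a covariate-adjusted standardized mean difference.
Adjustment is per study: the gene's expression is regressed on that study's
*declared* covariates only, and the residuals (plus the study mean) carry
forward. The effect metric is Hedges' g with its usual small-sample
correction `J = 1 − 3/(4·df − 1)` and large-sample variance
`(n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂))`. Pooling uses the non-iterative
DerSimonian–Laird (DL) random-effects estimator; the moderator analysis is
a weighted least-squares meta-regression on a male/female indicator with
method-of-moments residual τ² (the DL generalization with moderators) and
a Wald chi-square (QM) test. Confidence intervals use the 1.96 normal
multiplier throughout.

Design choices made where the procedure was genuinely open:

* **Effect metric.** No specific metric is mandated by the reported
  forest-plot layout; Hedges' g is the standard for small postmortem
  cohorts and is what the package uses. Case-control pairing is *ignored*
  in the variance (unpaired formula), which is conservative when pairing
  is informative.
* **τ² estimator.** DL was chosen because it is closed-form and exactly
  reproducible; it matches `metafor::rma(method = "DL")` to 1e-8 in the
  test suite, which serves as the independent cross-check rather than the
  implementation.
* **Stouffer weights.** The Z-trend combination uses √n weights on signed
  one-sided quantiles `dir · Φ⁻¹(1 − p/2)`; two-sided inputs are assumed
  because the per-study tests were two-sided. Percent-of-control summaries
  weight per-study percentages by N, with the SEM taken from the unbiased
  N-weighted variance divided by the number of studies.

### Calibration facts the tests establish

With only eight studies the DL normal-reference test is visibly
*conservative*: under the simulated global null the pooled z-statistic has
standard deviation ≈ 0.90 (τ² truncation at zero inflates the standard
error whenever Q happens to exceed its expectation), so null p-values are
not exactly uniform — the acceptance suite's Kolmogorov–Smirnov check at
2000 replicates detects precisely this well-known small-k conservatism,
and the same applies to the moderator QM test. This is a property of the
prescribed estimator, not of the implementation (which agrees with
`metafor` to numerical precision).

Power is the second structural limit. In the default study system
(8 studies of 18–42 subjects, planted effects −0.8 SD in females and
−0.3 SD in males) the per-study sampling variance of g is ≈ 0.14, so even
an oracle z-test with *known* variances has `se(β̂) ≈ 0.27` for the 0.5 SD
sex difference — a noncentrality of ~1.85 and power of ~0.46 at α = 0.05.
The implemented test measures ≈ one-third power in the acceptance suite;
the *sign* of the moderator is recovered in ~95% of replicates and the
pooled female effect is the more negative one in well over 90%. A
collection of this size supports directional, not confirmatory, moderator
claims.

## 2. Synthetic study system

The generator defaults *are* the study conditions; they are set once, in
`sim_config()`, and every acceptance simulation runs against them.

* **Eight case-control studies** (two DLPFC, four ACC, two amygdala; half
  female; 9–21 matched pairs) with study-specific declared covariate sets,
  one of them empty. Covariates are drawn from postmortem-typical ranges —
  age ~ N(50.8, 14.9) truncated to 16–96 y, PMI ~ N(17.2, 5.9) h,
  pH ~ N(6.7, 0.3), RIN ~ N(8.0, 0.73) — and enter expression through
  configurable linear slopes. Binary covariates (alcohol, suicide) are
  drawn *independently of diagnosis* so that the planted case-control
  shift, expressed in residual-SD units, remains the exact ground truth an
  unbiased analysis should recover; a declared covariate is redrawn in the
  rare event it comes out constant, since a study cannot adjust for a
  constant.
* **Two-region co-expression cohort** (214 subjects). A single latent
  factor drives the module genes with loading 0.85, giving the analytic
  pairwise-correlation target `loading² = 0.7225`. Non-module GABA-panel
  genes load at 0.3 and background genes at Uniform(−0.3, 0.35), spreading
  the seed-gene profile realistically while keeping every non-module
  correlation safely below the 0.5 edge threshold. Because both regions
  are measured on the same subjects, each gene's non-factor variance is
  split 70/30 into a region-shared subject component and region noise;
  this is what makes the two regions' seed-correlation profiles agree at
  r ≈ 0.96–0.98, comfortably above the 0.95 averaging gate the profile
  stage enforces.
* **X genotypes** (136 hemizygous males, 34 diploid females; 500 SNPs in
  blocks of 10). Within a block every SNP copies a block-ancestral allele
  with probability `1 − ε` and redraws otherwise; `ε = 1 − ld_r2^(1/4)`
  makes the expected pairwise correlation `(1−ε)² = √ld_r2`, i.e. squared
  correlation `ld_r2`, while preserving the marginal MAF. Planted trans
  effects default to 1.4 SD/allele in females and 0.6 in males: with only
  34 females, a noncentrality of `β·√(n·2p(1−p)) ≈ 5.3` is needed for the
  female-biased asymmetry to be reliably expressed, while 0.6 at n = 136
  males yields deliberately partial detection. These magnitudes were fixed
  by that design-time power calculation.
* **FCG design.** Unbalanced cells of 12–20 animals. Endpoints are drawn
  on their natural scales (seconds of a 600-s session, percentages,
  counts, cm, arbitrary expression units) with planted deltas of 1 SD:
  XY lowers *Sst*/*Gad67*/*Gad65*, open-arm/center measures and locomotor
  activity; testosterone raises open-arm/center measures and activity;
  gonadal males show higher sucrose preference plus a gonadal-male ×
  testosterone interaction. Raw counts (arm entries, distances, fluid
  volumes) are back-computed from the planted percentages so the *derived*
  endpoints carry the effects; counts are rounded and truncated at
  physical limits.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, population structure or relatedness in the genotypes,
X-inactivation mosaicism, litter effects, or longitudinal (baseline vs
post-stress) correlation — the two behavioral timepoints are treated as
separate datasets, as the factorial analysis treats them. Passing tests
therefore demonstrate the *statistical machinery* recovers planted
structure, not that real cohorts of this size would behave as cleanly.

## 3. Co-expression stage

Pearson profiles of the seed gene are computed per region (zero-variance
genes are dropped with a warning — flat probes are a fact of arrays), and
averaged only if the two regions agree at r ≥ 0.95; otherwise the
averaging step refuses, carrying the observed similarity in the error.
Gene selection keeps r strictly greater than 0.725, sorts descending, and
breaks ties lexicographically so results are platform-independent; the
default panel cap is 200 genes. The network stage thresholds pairwise
correlations strictly at 0.5 and keeps the correlation as edge weight — a
literal hard-threshold weighted network, not a soft-power adjacency, since
that is the stated construction. The core module is the seed set plus
nodes adjacent to a majority (⌈k/2⌉, configurable) of the seeds.

## 4. eQTL stage

Scans are sex-stratified throughout: males (dosage 0/1) and females
(0/1/2) are never mixed, so the dosage coding scale only rescales β within
a stratum. The per-pair model is OLS `expression ~ dosage + age + pH +
RIN`, computed by residualizing expression and dosages on the covariate
design once per stratum (Frisch–Waugh–Lovell), which the tests verify is
identical to per-pair `lm()` fits to 1e-10. Genotype enters additively; a
factor coding is a documented alternative but not the default, matching
the ANCOVA convention. SNPs with stratum minor-allele count below 3 are
skipped (the t-test is degenerate there). BH correction is applied within
each (gene, stratum) family across all tested SNPs — the family that
matches "correction across X-chromosome SNPs" — with a pooled-family
option. LD blocks are single-linkage components at r² ≥ 0.8 within
500 kb; multi-SNP components are reported as blocks, singletons
separately, matching the "N blocks (M individual SNPs)" reporting
convention. The cis follow-up tests only trans-significant SNPs against
transcripts whose ±50 kb window (inclusive at both ends, 1-based
coordinates; BED input converted from 0-based half-open) contains the
SNP, at raw p < 0.05 without correction — the SNP set is
hypothesis-driven by construction.

The FDR acceptance simulation plants ten 0.8 SD/allele effects, one per
LD block, spread over the three target genes, and counts truth at the
block level (the scan's own reporting unit). Empirical FDR stays at the
nominal 0.05. Detection of a 0.8 SD/allele effect at n = 136 sits near
0.70, not higher: each gene carries 3–4 planted effects whose unmodeled
siblings inflate the residual SD to ~1.16, leaving a noncentrality of
~3.7 against a BH-adaptive threshold near z ≈ 3.0. Recovering ≥ 90% of
such effects would require β ≈ 0.95+ at this sample size; the suite
reports the measured rate rather than assuming it.

## 5. FCG factorial stage

Endpoint derivation is exact formula application: percent open-arm
entries, percent center distance, sucrose preference as a percentage of
total fluid; zero denominators yield missing values that are removed
listwise per endpoint and logged. The ANOVA uses Type III sums of squares
under sum-to-zero contrasts because the cells are unbalanced; on balanced
data it coincides with the sequential decomposition, which the tests
assert exactly. Tukey-adjusted contrasts are computed for significant
terms on marginal means (for a two-level main effect this reproduces the
F-test) and on the four cell means of two-way interactions. Significance
is flagged at p < 0.05 and trend at p < 0.1. An ANCOVA option adds a
locomotor endpoint (total entries or total distance) as a covariate for
the anxiety measures, an explicit stand-in for "controlled for locomotor
activity", whose exact original form is not specified anywhere.

At the default cell sizes, a 1 SD main effect is detected essentially
always, while the planted 1 SD sucrose interaction has per-run power of
roughly 0.75–0.8; the acceptance suite therefore checks the interaction
over ten generator seeds (direction in ≥ 9, significance in a majority)
instead of betting on a single draw.

## 6. Determinism and problem sizes

All randomness flows from one seed: each generator derives a fixed
per-stage offset from `config$seed`, so rerunning any stage cannot
perturb another, and the RNG state of the calling session is saved and
restored. The test suite runs its Monte-Carlo checks at desk scale —
500 replicates for moderator recovery, 2000 for null calibration, 200 for
FDR and network recovery, 100 for stratum asymmetry and negative
controls — sizes chosen so the whole suite completes in a few minutes on
one CPU while keeping binomial Monte-Carlo error around one percentage
point.

## 7. Known limitations

* DL + normal reference is conservative at k = 8 (see §1); a
  Knapp–Hartung adjustment would trade that for different small-k
  behavior but is not what the procedure specifies.
* The moderator analysis at this collection size has ~⅓ power for a
  0.5 SD sex difference; its value is directional.
* The LD model is blockwise-exchangeable with independent blocks; real
  haplotype decay, recombination hotspots, and inter-block LD are absent.
* Negative-control guarantees are per BH family (gene × stratum): under
  the global null the probability of *any* rejection in a family equals
  the FDR level, so bundling several families necessarily multiplies that
  small failure rate.
* The cis stage reports uncorrected p-values by design; its output is a
  candidate list, not an inference.
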