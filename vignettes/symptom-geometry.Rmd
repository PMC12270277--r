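---
title: "Methods: symptom-improvement geometry and baseline connectivity mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom-improvement geometry and baseline connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(symgeo)
```

## The problem

Placebo-controlled antidepressant trials usually compare arms on a total
scale score or a single clinician-rated global impression. Both collapse a
heterogeneous, multi-scale symptom panel to one prespecified number, and in
trials with a strong placebo response they often show no arm difference at
all. symgeo implements an alternative: treat the week-to-week change of
every individual item — depression (HRSD), mania (ASRM), suicidality
(CHRT) and associated symptoms (CAST), 73 items in the default layout — as
a vector per patient, and ask whether the cohort's change vectors
concentrate along a low-dimensional axis. If the leading axis is shared
between arms, patients can be scored on a *common axis of improvement* and
arms compared on that score; baseline clinical and neural measures can then
be tested as predictors of the score.

The neural side summarizes each subject's parcellated resting-state scan as
parcel-wise *global brain connectivity* (GBC): each parcel's mean
correlation with every other parcel. GBC is mapped onto improvement scores
parcel by parcel, with family-wise error controlled by max-statistic
permutation, and at coarser spatial scales (12 functional networks, named
subcortical structures, whole brain) with repeated-measures ANOVA.

## The improvement geometry

For subjects complete at both visits, `compute_deltas()` builds the
subjects-by-items matrix of `value(before) − value(after)`, so positive
deltas mean symptom reduction. `fit_pca()` is a plain SVD-based PCA; by
default items are z-scored first. The scaling choice is deliberate: item
ranges are all 0–4 in the synthetic default but need not be in real panels,
and without standardization wide-range items dominate the leading axis. A
raw-covariance mode (`standardize = FALSE`) is kept as a switch.

Three conventions make the decomposition reproducible:

* **Sign.** The first component is oriented so its scores correlate
  positively with the total HRSD reduction (falling back to the row sums
  when no HRSD items are present); later components get the deterministic
  "largest loading positive" rule. Orienting twice changes nothing.
* **Zero-variance items** (an item nobody changes on) are dropped with a
  warning and re-inserted as zero loadings, so loading vectors always have
  the full item dimension.
* **Degenerate inputs** (fewer than 3 subjects, an all-zero matrix) are
  errors, not silent results.

Two checks decide whether a component is interpretable:

* `pc_significance()` permutes each item column independently across
  subjects and compares variance-explained fractions component-wise, with
  the add-one convention `p = (1 + #exceedances) / (n_perm + 1)`. Defaults:
  1000 permutations.
* `split_half_reliability()` repeatedly halves the cohort (stratified by
  arm when arms are present), fits a PCA in each half, matches components
  greedily in rank order by maximal absolute loading correlation, and
  reports the median |r| over splits (default 1000). The absolute value
  makes the measure invariant to the arbitrary sign of either half.

`retain_components()` keeps a component when it is significant **and** its
reliability is at least 0.5. The exact permutation scheme and split-half
protocol behind published analyses of this kind are not fully specified in
the primary literature; the column-permutation null and the greedy
|r|-matching used here are documented package conventions.

`fit_common()` pools all arms into one PCA, sign-aligns each arm's PC1 to
the pooled PC1, and tabulates cross-group loading correlations. Pooled
scores are exactly the projection of each subject's standardized delta row
onto the pooled loadings, so per-arm score distributions can be compared
with `compare_scores()` — pooled-variance two-sample t-tests
(`df = n1 + n2 − 2`), chosen over Welch because integer design dfs are the
quantity of interest; Cohen's d is reported alongside.

`baseline_pca()` applies identical machinery to baseline item values
(severity rather than change), and `predict_improvement()` regresses
common-axis scores on each baseline predictor in a sequential
`score ~ predictor × arm` model with per-arm Pearson follow-ups. Depression
severity as a two-level factor is a median split on the baseline HRSD total
(`severity_split()`, threshold configurable) — the cut point is a package
convention, not an established clinical threshold.

## GBC and brain-behavior mapping

`compute_gbc()` correlates every parcel with every other parcel
(time series are centered by the correlation itself; no filtering — MRI
preprocessing is out of scope), clips correlations to ±(1 − 1e−7),
Fisher-z transforms by default, and averages excluding the self-term.
Fisher-z averaging is the field convention for GBC; a raw-r mode is kept
because published variants differ. Zero-variance parcels are masked: NA in
the output, excluded from other parcels' means, NA rows in downstream maps.
`aggregate_gbc()` takes unweighted means per network, per subcortical
structure and over all parcels.

`map_univariate()` computes per-parcel two-tailed Pearson correlations
between GBC and a behavioral score and controls the family-wise error rate
with the max-statistic permutation method: the score vector is permuted
over subjects (1000 times by default), each parcel's |r| is compared to its
own permutation distribution (`p_unc`) and to the distribution of the
maximum across parcels (`p_fwe`), both with the add-one convention. This
guarantees `p_fwe ≥ p_unc ≥ 1/(n_perm+1)` parcel-wise. Covariates are
optional and default off (the plain-correlation map is the primary
procedure); when supplied, both sides are residualized and the residualized
scores are permuted (Freedman–Lane), the standard behavior of permutation
ANOVA tools.

`interaction_map()` fits `gbc ~ score × arm (+ covariates)` per parcel and
maps the interaction t, using Freedman–Lane permutation of the reduced
(no-interaction) model's residuals for FWE. A regression interaction was
chosen over a z-difference of per-arm correlations because it admits
covariates and has the same null behavior. `compare_map_strength()` runs a
paired t-test across parcels on |Fisher-z r| (`df = P − 1`); a signed mode
exists because the absolute-value choice is a convention.
`correlate_maps()` correlates two maps' Fisher-z statistics across parcels.

`rm_anova()` fits
`gbc ~ age + gender + site + score * treatment * network` with subject as
the error stratum: subject-constant terms are tested against the
between-subject residual, network terms against the subject-by-network
residual. Sums of squares are sequential (Type I) with covariates first —
the term order is recorded in the returned table's attributes. With a
complete 192-subject cohort, 4 sites, binary gender, continuous age and 12
networks the residual dfs are 183 (between) and 2068 (within); these are
design identities and are verified by the test suite. The design must be
balanced (every subject at every network level); unbalanced input is an
error rather than a silently different model. `per_group_model()` is the
per-arm long-format least-squares analogue (`score ~ covariates +
gbc × network` on subject-by-network rows); because the score repeats
across a subject's rows its denominator dfs pool rows, which matches how
such models are conventionally reported but means its p-values should be
read as descriptive. `network_followups()` adds per-level correlations with
Bonferroni adjustment at a configurable family size.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` produce cohorts with known planted
structure so every downstream stage is testable without restricted trial
data. The generative model:

* A latent improvement `u_i ~ N(δ_arm, 1)` with defaults δ = 0.80
  (sertraline) and 0.35 (placebo): a standardized arm difference of 0.45,
  sized so the common-axis score comparison lands near the t ≈ 3 regime a
  192-subject trial with arms of 93/99 would show.
* A baseline severity latent `s_i` correlated ρ = 0.20 with `u_i`.
* Baseline items `round/clip(μ + λ_j s_i + ε)` with μ = 2 on a 0–4 ordinal
  grid, λ = 2|w|, baseline noise sd 0.8.
* Week-8 items subtract `effect_scale · w_j · u_i + ε'` with per-item noise
  sd 0.5, then round and clip. Week-16 items repeat the process with a
  second latent drawn after the stage-2 reassignment rule (sertraline
  nonresponders → bupropion, placebo nonresponders → sertraline, responders
  continue; response = noisy threshold on `u_i`, threshold 0.72, noise sd
  0.5, giving response rates near 53%/38%).
* Time series follow an equicorrelated common-signal model per subject,
  with the subject's mean pairwise coupling (Fisher-z scale) equal to
  `coupling_base + slope_arm · u_i + N(0, 0.06)`.

**Why `effect_scale` exists.** The loading geometry `w` is unit-norm and
`u` has unit variance, so with `effect_scale = 1` each item's planted
change is about 0.1 ordinal units — far below the integer grid step. On an
ordinal grid the rounding itself contributes variance of about 1/12 per
item, and a factor of total strength 1 spread over 73 items cannot produce
a leading component that survives split-half validation at n = 192: the
planted factor would fail the package's own retention rule, which would
make the synthetic cohort a poor emulation of real multi-scale panels,
where the leading change axis is reliable and explains on the order of a
fifth to a quarter of item variance. The default `effect_scale = 3`
(ordinal units per latent sd) puts PC1 variance-explained near 0.2 and
makes the planted factor reliable while mania items still barely move —
matching the qualitative structure of real panels. `effect_scale = 1`
recovers the bare parameterisation for anyone who wants it.

**The default loading geometry** (`default_loading_geometry()`) loads HRSD
and CHRT items strongly and positively, ASRM items near zero to slightly
negative, CAST items across a wide range. The heterogeneity is not
cosmetic: loading-vector similarity measures are Pearson correlations,
which center the vectors, so a near-uniform geometry would leave split-half
reliability and cross-arm similarity dominated by noise regardless of how
well the axis itself is estimated.

**Coupling calibration.** The default sertraline coupling slope (0.0222
z-units per latent sd) was fixed once by a delta-method calculation: the
target whole-brain GBC–improvement correlation 0.34 equals
`b / sqrt(b² + σ²)` where σ² combines the planted between-subject coupling
sd (0.06) and the measured sampling noise of mean GBC at the default
dimensions of 718 parcels × 400 timepoints (≈ 0.014). The placebo slope is
0. Per-arm estimates at n = 93/99 carry Fisher CI half-widths around ±0.19,
so individual cohorts scatter visibly around the planted values; the
acceptance checks therefore test CI coverage, not point equality.

**Reproducibility.** Every draw comes from a per-subject stream derived
deterministically from `(seed, subject index)` (clinical and time-series
streams are separate), so a subset of subjects is bit-identical regardless
of cohort size, and identical `(spec, seed)` gives byte-identical cohorts.
Arms are allocated by deterministic interleaving to the target 93/99
fractions; sites round-robin.

**What the generator does not emulate:** BOLD autocorrelation and
hemodynamics, motion artifacts, site- or scanner-specific structure beyond
a site label, item-response-theory calibration of the ordinal scales,
missing-not-at-random dropout (missingness is a uniform per-subject rate),
and any spatial autocorrelation of parcels within networks. Passing the
recovery tests on this cohort therefore demonstrates the statistical
machinery, not robustness to those real-data features.

## The pipeline

`run_pipeline()` sequences cohort → geometry → common axis → baseline
prediction → GBC → maps → ANOVAs and writes every table with a checksum
manifest; the single config seed fans out to per-stage seeds through a
documented derivation (`derive_seed`), so identical configs reproduce
identical checksums and stages remain independently reproducible. Input
paths are validated before any computation. The command-line front end
(`inst/cli/symgeo`) is a thin Rscript wrapper over `generate_clinical()`
and `run_pipeline()`.

## Problem sizes used by the tests

Unit tests run on cohorts of 5–80 subjects with 40 parcels and 60
timepoints. The end-to-end checks use the full design where the quantity
depends on it: 192 subjects for degrees of freedom, geometry recovery (20
replicate cohorts) and reliability (200 splits); 200 replicates of
50 parcels × 100 subjects × 199 permutations for FWE calibration; and the
full 718 × 400 neural dimensions for coupling recovery. The demo pipeline
config uses 24 subjects, 60 parcels and 80 timepoints.

## Known limitations

* The per-arm long-format model pools subject-by-network rows; a
  mixed-effects model would be the stricter inference and is deliberately
  not substituted, to keep the reported dfs comparable to the conventional
  analysis.
* Fisher-z averaging versus raw-r averaging in GBC changes values slightly
  (Jensen's inequality); both modes are exposed and the default is a
  convention.
* Complete-case analysis per stage; no imputation.
* CIFTI-2 `.ptseries.nii` reading is a convenience branch through RNifti;
  the TSV matrix dialect is the canonical, tested path.
* Permutation p-values are lower-bounded at `1/(n_perm+1)`; with the
  default 1000 permutations, FWE-adjusted significance below 0.001 is not
  resolvable.
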