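---
title: "Methods: community thermal restructuring from paired resurveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community thermal restructuring from paired resurveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deboreal)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical choices made where the design was open.

## 1. The survey model

The unit of observation is a 2 × 5 m benthic quadrat scored at two
timepoints roughly half a century apart. Per-species cover is recorded
either as a fraction or on a modified Braun-Blanquet ordinal scale whose
classes are converted to bin midpoints: `5` → 0.88, `4` → 0.63, `3` →
0.38, `2` → 0.155, `1` → 0.03. The `<1%` class (`+`) has an open bin with
no printed midpoint; we use the midpoint of (0, 1%) = **0.005**, exposed
as the `plus_value` argument of `cover_code_to_fraction()` so analysts
who prefer 0.001 or 0.0025 can rebind it. Total cover may exceed 1
because canopy and understory overlap; no renormalization is applied.

Depths are meters *below chart datum* (positive downward); intertidal
(negative) depths are rejected because the design is strictly subtidal.
Quadrat pairs whose substrate is exactly `{sand}` at either timepoint are
excluded (`filter_quadrats()`), since cover change over mobile sand
reflects sediment movement, not macroalgal dynamics; mixed substrates
that merely include sand are retained. Species names are matched exactly
after trimming and case-folding — taxonomic synonym resolution is
deliberately the caller's job.

Species reaching 5% cover in at least one quadrat at either timepoint
pass the rare-species filter (`rare_species_filter()`, threshold
configurable); only those species receive an STI and enter the CTI and
the decomposition. Applying the same filter to both is a choice: the
alternative (decomposing over all species) changes the weights only
through species that are, by construction, nearly absent.

## 2. Thermal indices

The **species temperature index** is the unweighted mean of a coastal SST
climatology over the 0.1°-latitude bins whose centers fall inside the
species' range. Binning latitudinally first (rather than averaging raw
coastal pixels) prevents longitudinally extended stretches of coastline
from dominating the mean. Bins are half-open on the upper edge; a sample
exactly on a boundary joins the upper bin. The 0.1° width matches the
precision at which range limits are typically recorded.

The **community temperature index** is the cover-weighted mean STI of the
species present. It is invariant to uniform rescaling of cover and always
lies between the minimum and maximum STI present, properties the test
suite asserts. A quadrat whose scored species all have zero cover has no
CTI (explicit error), rather than a silently imputed one.

**Affinity.** The baseline is the *unweighted* mean STI over species
documented in the historical survey — presence-based, not
abundance-weighted, so a community dominated by one cold kelp does not
drag the baseline to that single species. Warm affinity requires an STI
*strictly above* the baseline; an exact tie classifies cold. Both choices
follow the definition of warm affinity as "higher than" the historical
mean; the tie rule matters only on pathological equal-STI inputs.

## 3. CTI shift and the four-process decomposition

`estimate_cti_shift()` defaults to a **paired bootstrap**: the point
estimate is the mean over quadrats of (modern CTI − historical CTI), the
CI a percentile bootstrap over quadrats (default `n_boot = 2000`, seed
mandatory). Percentile rather than BCa: the per-pair differences are
approximately symmetric by construction and the percentile interval is
transparent; at n = 48 it runs 1–3 points below nominal coverage, which
the acceptance criterion (≥ 90% empirical coverage at the 95% level)
absorbs. A `spline_model` method is provided for depth-structured data: a
Gaussian GAM with a year effect, year-stratified depth smoother and
per-quadrat random intercept, the shift being the difference of marginal
means averaged over a 101-point depth grid, with a delta-method CI. The
smoothing machinery (mgcv, REML) is deliberately only contract-level: the
bootstrap is the tested estimator.

The **decomposition** groups quadrats into 1-m depth bins — half-open
[k, k+1) on *historical* depth, since modern relocation matched the
historical depth — to counteract the shallow bias of historical sampling.
Within a bin, per-species cover is averaged across quadrats at each
timepoint; the species weight is |Δcover| L1-normalized within the bin;
weights accrue to the process given by sign(Δ) × affinity. Overall
proportions are the **equal-weight mean over bins with any change**. The
aggregation was genuinely open: normalizing by Σ|Δ| (not signed ΣΔ) keeps
weights positive and interpretable as shares of turnover, and equal bin
weighting is what actually removes the shallow-sampling bias — weighting
bins by their share of total |Δ| (available as
`bin_weighting = "l1"`) partially reintroduces it. Species with zero
change carry no process and are excluded from normalization; a world with
no change anywhere returns all-zero proportions behind an explicit
`no_change` flag rather than NaNs.

## 4. Community statistics, from first principles

Bray–Curtis, PERMANOVA, dispersion homogeneity and SIMPER are implemented
directly (vegan appears only as an independent oracle in the tests):

* **PERMANOVA** uses the one-way pseudo-F from squared dissimilarities,
  with p by free permutation of year labels and the add-one correction
  p = (k+1)/(n_perm+1). When the two-group label arrangements number at
  most `n_perm`, the exact distribution is enumerated instead and p is the
  exact tail proportion (seed irrelevant, bit-reproducible). Free
  permutation is the default because the method's standard usage ignores
  pairing; a paired scheme (independent within-quadrat label swaps via
  `strata`) is available and flagged in the output.
* **Dispersion homogeneity** embeds samples by principal coordinates of
  −d²/2 (double-centred), **dropping negative-eigenvalue axes without
  Lingoes/Cailliez correction** — the simplest defensible choice, exact
  for Euclidean inputs (asserted against the direct computation in
  tests). Distances to group centroids get a classical one-way ANOVA F.
  Note vegan's `betadisper` retains imaginary axes, so the two agree
  exactly only on Euclidean matrices.
* **SIMPER** computes, for every between-group pair, species k's share
  |x_ik − x_jk| / Σ_m(x_im + x_jm), then averages over pairs, so
  contributions sum *identically* to the mean between-group Bray–Curtis
  dissimilarity (machine-precision acceptance check). Only the mean is
  reported; the ranked view is a sort, not a separate statistic.

Default `n_perm = 999`: with the add-one correction the smallest
attainable Monte-Carlo p is 0.001, matching the conventional reporting
granularity.

## 5. SST events and trends

Event detection scans the **whole year** (events can straddle month
edges) for maximal runs of consecutive calendar days with SST ≥ threshold;
"2 weeks" is read as 14 inclusive days and all comparisons are `>=`.
A missing day breaks a run — conservative for gappy lighthouse records;
no gap interpolation is offered because a tolerance would silently
manufacture event days. Threshold-day *counts* use the June–August window
(the biologically relevant stress season); winter means assign December to
the following January's year so a winter is never split.

Mann–Kendall uses the tie-corrected variance, a continuity-corrected
normal approximation, and tau-b; Sen's slope is the median of all
pairwise slopes. Both are enumeration-checked in the tests and the MK
null calibration (type-I error within [0.03, 0.07] at α = 0.05, n = 50,
1000 replicates) is part of the acceptance suite.

The decadal warming rate smooths annual means with a cubic smoothing
spline whose penalty is chosen by **GCV** (`stats::smooth.spline`), then
averages the first derivative over the period and scales by 10. A
smoothing spline contains exact lines in its null space, so a linear
series returns its slope exactly (asserted). The CI is a residual
bootstrap (resample residuals around the fitted curve, refit, percentile
interval). Event-frequency trends use a maximum-likelihood logistic fit
of the annual event indicator on year (IRLS via `stats::glm`,
convergence tolerance 1e−8), reporting exp(slope) as odds ratio per year
and a Wald CI; complete separation is detected (non-convergence or
|slope| > 10, or the fitted-probability warning) and flagged rather than
silently reported. Known limitation: the logistic MLE's odds ratio is
biased slightly away from 1 at n ≈ 60 years; recovery is therefore judged
against the estimator's sampling SD, not the Monte-Carlo SE of the mean.

## 6. What the generators emulate — and what they do not

`gen_climatology()` builds a linear poleward-cooling coastal gradient
(defaults: 30 − 0.4·lat °C over 5–61° N, i.e. ~28 °C near Central America
to ~5.6 °C in the Gulf of Alaska) with optional per-bin noise, and
species ranges whose noiseless STIs are known in closed form. Cold
species ranges center on 48–58° N and warm on 20–30° N; with the default
gradient the class STI intervals ([7.8, 10.8] vs [18, 22] °C) are
separated by any historical baseline whenever n_cold ≥ 1 and
n_warm < 2.5·n_cold, so generator roles provably match
`classify_affinity()` (asserted over seeds).

`gen_paired_surveys()` emulates the 48-paired-quadrat, two-timepoint
design with Beta-distributed covers (bounded support; mean/concentration
parameterization) tapered logistically with depth (midpoint 5 m, scale
2 m) to mimic shallow-biased historical abundance. Two modes:

* **`process_mix`** applies one fixed signed Δcover per species in every
  quadrat, with head-room built into the historical draw so no clamping
  occurs; bin means then shift by exactly Δ, making the decomposition
  equal the target mix *exactly* — the recovery tests are sharp, not
  statistical.
* **`cti_shift`** draws a per-quadrat CTI change from N(1.4, 0.8) °C and
  realizes it *exactly* by rescaling cold-species cover (the scaling
  factor has a closed form because CTI is a ratio of linear functions of
  the multiplier), clamping only at feasibility edges (< 1% of draws).
  The mean 1.4 °C is the stated world; the SD 0.8 °C is the package's own
  choice, set once by the feasibility window the generated STI spread
  allows for the exact construction (the source study's wider CI reflects
  GAM marginal-mean machinery, not per-quadrat dispersion). It is not a
  tuning knob.

`gen_sst_series()` produces a 1962–2023 daily series: seasonal cosine
(mean 12 °C, amplitude 5 °C, peak ≈ Aug 1, so the noiseless summer peak
of 17 °C sits just *below* the 18 °C threshold and every noiseless event
is an injected one), optional linear trend, AR(1) noise (default φ = 0.6,
innovation SD 0.35 °C), injected non-overlapping exceedance blocks with a
ledger of which definitions they meet, and optional whole-year gaps.

What a green test does *not* establish: the generators have no spatial
autocorrelation between quadrats, no taxonomic error, no observer
drift between survey eras, no depth-varying *direction* of change, no
El Niño-like interannual clustering in the SST noise, and species ranges
are independent of each other. Recovery on this world validates the
estimators' arithmetic and calibration, not robustness to those field
realities.

## 7. Numerical choices and degenerate inputs

* Half-open bins everywhere (climatology latitude, depth); boundary
  samples go up. Latitude/width ratios are rounded at 1e−9 before
  flooring to stabilize float boundaries.
* Exhaustive PERMANOVA enumeration compares permuted F against observed
  minus 1e−12 so the identity relabeling always counts.
* All-equal Mann–Kendall series: τ = 0, p = 1 (not NaN). Zero-width
  bootstrap CIs are allowed for degenerate identical shifts.
* Every stochastic routine requires an explicit seed; generators are
  bit-reproducible given (scenario, seed); `run_pipeline()` is
  byte-deterministic given (config, seed), with provenance (config hash,
  stage order) embedded in the report.

## 8. Known limitations

STIs assume range-wide thermal exposure represents local populations (no
subpopulation STIs). The decomposition attributes change by sign and
affinity only — it cannot distinguish thermal causation from, e.g.,
herbivory. The spline CTI-shift method's CI ignores smoothing-parameter
uncertainty. The paired bootstrap treats quadrats as exchangeable,
ignoring transect-level clustering.
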