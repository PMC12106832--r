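---
title: "Modelling the burst of gyrification at birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the burst of gyrification at birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perigyri)
```

## The scientific question

Cortical folding (gyrification) expands dramatically between mid-gestation
and the first months of life. Because fetal and neonatal MRI are usually
analysed separately, the effect of birth itself on folding is easy to miss:
a pooled perinatal sample shows an apparent jump in the gyrification index
around 37 weeks post-conception (wPC), the conventional term-birth
threshold. `perigyri` implements the quantitative machinery needed to ask
whether such a jump is real and specific: a mesh-based gyrification index, a
sharp regression-discontinuity (RDD) estimator at the birth cutoff, a
growth-partition statistic, and the sensitivity analyses that separate a
biological discontinuity from acquisition or processing artefacts. A
synthetic cohort generator reproduces the statistical structure of a pooled
fetal/neonatal sample so that every stage is testable without imaging data.

## The gyrification index

For a closed triangulated cortical surface the package computes

$$\mathrm{GI} = \frac{A_{\text{surface}}}{A_{\text{hull}}},$$

the total mesh area divided by the area of the convex hull of its vertices.
The index is 1 for convex shapes, grows with folding, and is invariant to
rigid motion and uniform scaling. The convex hull is the strict vertex hull:
for a closed mesh the hull of the vertex set equals the hull of the surface,
and the generated test surfaces are star-shaped by construction. Degenerate
faces (area below $10^{-12}$ mm²) are rejected at load; inward orientation
is detected by a negative signed volume and flipped with a warning; an open
mesh is a hard error that names the offending boundary edges, because the
area ratio is meaningless on a surface with holes.

Synthetic folded surfaces are produced by radially deforming an icosphere,
$r(u) = R\,(1 + a\,s(u))$, where $s$ is a seeded, band-limited smooth field
(plane-wave superposition, spherical-harmonic degree 12–24 equivalent)
softly saturated with a tanh so its excursions stay bounded near 1.2 sd.
The saturation is what lets the deformation fold deeply — amplitude is
limited by the positive-radius (star-shape) constraint $a\,|s| < 1$, and a
bounded field leaves more admissible amplitude than a Gaussian one, whose
rare extremes would cap the reachable index well below 2. The band and
saturation are constants of the generator; the amplitude $a$ is the single
dial, calibrated by bisection on the empirically monotone map
$a \mapsto \mathrm{GI}(a)$ (tolerance 0.005, at most 60 iterations). The
default icosphere subdivision is 4 (2\,562 vertices), at which the
measurement is self-consistent across the calibration loop; tests verify
against a 4×-density reference on a band resolved at both densities.

## Trajectory model and the growth partition

The developmental trajectory of each feature is summarised by ordinary
least squares on centred age and its square. Ages are centred before the
polynomial expansion purely for conditioning; raw-scale coefficients are
back-transformed. The fit reports $R^2$, the residual standard error with
denominator $n - 3$, and the overall F-test.

The growth partition evaluates full-side quadratic fits at the window
bounds and the cutoff:

* fetal share: $100\,(\hat f_{\text{pre}}(c) - \hat f_{\text{pre}}(a_{\min}))/T$,
* birth jump: $100\,(\hat f_{\text{post}}(c) - \hat f_{\text{pre}}(c))/T$,
* postnatal share: $100\,(\hat f_{\text{post}}(a_{\max}) - \hat f_{\text{post}}(c))/T$,

with $T$ the total growth between the fitted endpoints. The three shares
telescope to 100% identically, so fixing the fetal and postnatal shares at
45.0% and 33.6% forces a 21.4% jump — an arithmetic identity the test suite
checks through the code path rather than by subtraction. Full-side fits are
used for the endpoints (rather than the RDD's bandwidth-limited local fits)
so that the partition is internally consistent over the whole 21–45 wPC
window; side membership at the cutoff follows the RDD convention (ages
$\ge c$ are postnatal).

## The regression-discontinuity estimator

`rdd_fit()` estimates the jump $\tau$ at a known cutoff $c$ (default 37
wPC) from two local polynomial regressions on powers of $(x - c)$, fitted
jointly by weighted least squares with kernel weights (triangular by
default) and an order-2 polynomial per side. The discontinuity is the
difference of the two boundary intercepts. Covariates named on the formula
right-hand side enter additively with a single coefficient common to both
sides, matching how a sex covariate is conventionally added to such models;
we found no reason to let the covariate effect jump at birth, and a common
coefficient keeps $\tau$ interpretable as the outcome discontinuity.

**Bandwidth.** When no fixed bandwidth is given, a deterministic
leave-one-out cross-validation selector is used. Scores for different
bandwidths are made comparable by evaluating the side-specific local fits'
LOO squared error on a fixed set of sessions nearest the cutoff (the
smallest admissible window — at least $4(p+1)$ observations and 30% of each
side), using the weighted hat-matrix identity rather than refitting.
Because score differences between admissible bandwidths are often within
their own sampling noise, the selector applies a one-standard-error rule
and takes the largest bandwidth whose score is statistically
indistinguishable from the minimum; this prefers the lowest-variance
boundary fit among equally supported candidates and removes
selection-noise-driven small-window outliers. The floor on the window size
means the selector targets global-to-moderate bandwidths; with a fixed
`bandwidth` argument any window wide enough to identify the fit is
accepted.

**Inference.** Standard errors come from a heteroskedasticity-robust
sandwich with HC3-style leverage correction, $e_i / (1 - h_{ii})$ in the
meat. The leverage correction matters here: kernel weighting concentrates
leverage on the few sessions nearest the cutoff, and unshrunk (HC0)
residuals understate the boundary variance by roughly 10% in this design,
enough to push nominal 95% intervals below their coverage band. Two
inferences are reported side by side:

* *conventional* — the order-$p$ fit's estimate and robust se; its
  $z = |\tau|/\mathrm{se}$ is the effect size conventionally printed in
  feature screens;
* *bias-corrected* (default) — the fit is re-run at order $p+1$ on the
  pilot bandwidth (equal to the main bandwidth), which removes the leading
  smoothing-bias term and propagates the bias-estimation variance into the
  robust se.

With the pilot equal to the main bandwidth, the bias-corrected estimate is
exactly the higher-order local fit, a standard equivalence. P-values are
two-sided normal. The effect size $|\tau|/\mathrm{se}$ inherits the chosen
inference; note that the ratio is coefficient over standard error — the
reverse convention sometimes seen in print produces numbers inconsistent
with their own p-values.

**The multi-feature screen.** `multi_feature_rdd()` runs the model over a
feature list with a Bonferroni correction across features. It deliberately
mixes the two inferences the way such screens are reported: effect sizes
are the conventional point-z statistics, while p-values (and the
significance flags) come from the bias-corrected robust inference, which is
what protects smoothly curved but continuous features (sigmoidal volume
trajectories) from being flagged for pure smoothing bias.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs.

* **Demographics.** Four sub-cohorts with session counts 149 / 213 / 457
  normative plus 102 preterm; truncated-normal scan ages (inverse-CDF
  sampling, so sample sizes are exact and seed-stable) with the published
  means, sds and ranges; exact sex splits including 22 unknown-sex fetal
  sessions; two scanners (84:65) in the clinical fetal cohort. Preterm
  birth ages follow their published truncated normal, clipped per session
  so birth precedes the scan. At-term birth ages are not tabulated in the
  source demographics; a truncated normal centred on 40 wPC within
  37–42 wPC is a realistic obstetric default.
* **Gyrification.** The standardized mean trajectory is piecewise quadratic
  with a level shift at the cutoff. Each side is parameterised by its
  endpoint values — growth shares 45.0% fetal, 21.4% jump, 33.6% postnatal
  of the total growth $G = g_{\text{end}} - g_{\text{start}}$ — plus one
  curvature coefficient in $[-1, 1]$, the exact range on which the
  quadratic is monotone between its endpoints. Defaults accelerate
  prenatally (0.6) and decelerate postnatally (−0.5), the qualitative shape
  of perinatal folding. The absolute level $g_{\text{start}} = 0.55$ is a
  free amplitude: the printed confidence intervals and the printed growth
  shares cannot both be taken literally on a max-1 scale, so the generator
  targets the shares and leaves the amplitude conventional. Residual noise
  is Gaussian with sd 0.04, the residual scale of the quadratic trajectory
  fit.
* **Volumes.** Eight tissue volumes follow smooth monotone logistic growth
  curves with no discontinuity; a monotone-quadratic member of the family
  is available, and is the one on which a local quadratic fit recovers a
  zero jump to machine precision (a sigmoid is not polynomial, so its
  noiseless jump estimate is merely negligible, not zero). Noise is
  proportional (4% of the local mean); CSF noise is inflated before birth
  by a configurable variance ratio (default 4), mimicking the high fetal /
  low postnatal CSF variability. Derived columns follow the study
  definitions: CSF = eCSF + lateral ventricles, ICV = sum of all eight.
* **Preterms.** Preterm sessions are drawn from a continuous version of the
  gyrification trajectory: the jump share is folded into the fetal share,
  so the curve leaves the fetal trajectory, reaches the post-birth level
  continuously at the cutoff, and coincides with the postnatal curve
  afterwards — the overlay pattern that distinguishes a birth effect from
  an acquisition effect.

What the generator does *not* emulate: longitudinal within-participant
correlation (the analysis is cross-sectional by design; repeated sessions
are independent rows), gestational-dating error, scanner-by-age
interactions, spatially structured segmentation error, or any regional
folding structure. Passing tests therefore demonstrate that the estimators
recover the truth under the study's sampling design and noise scale — not
that the real data meet those assumptions.

## Sensitivity suite

* `scanner_anova()` fits outcome ~ age + age² + scanner within fetuses and
  tests the scanner factor by extra-sum-of-squares F (robust to the
  unbalanced 84:65:213 scanner groups). Pairwise contrasts are reported
  with a standardized effect size — the age-adjusted mean difference over
  the residual sd — because the corresponding printed effect sizes carry no
  stated units.
* `stratified_rdd()` refits the discontinuity independently per stratum;
  strata without adequate per-side support are flagged and skipped, and the
  explicit `"NA"` sex level is excluded unless requested.
* `preterm_overlay()` maps preterm sessions onto the normative side fits:
  deviations, z-scores against the side residual SE (homoscedastic within
  side), out-of-domain flags, and a preterm-only discontinuity fit.
* `variant_comparison()` compares two feature screens (e.g. two
  segmentation variants): per-feature deltas, Spearman rank correlation of
  effect sizes, and flags for features whose Bonferroni significance status
  differs.

## Numerical choices and degenerate inputs

Fits go through QR decompositions; rank deficiencies (too few distinct ages
within the window, collinear covariates) are errors that report the
effective support. Ties in age are kept as distinct observations. A
constant outcome yields $R^2 = 0$ by convention. A single-session summary
reports sd 0 with an explicit flag. The truncated-normal sampler uses the
inverse-CDF on the truncated interval, never rejection, so a fixed seed
fixes every draw. All randomness is locally seeded (`with_seed`), leaving
the caller's RNG state untouched.

## Problem sizes in the test suite

The simulation-based tests use the study's own cohort size (n = 819 + 102)
with 60–500 replicates per property — enough for the binomial noise on an
empirical rate to sit well inside the asserted bands — and icosphere
subdivision 4 for mesh work, with a single subdivision-5 reference in the
convergence checks. The acceptance script re-runs the same pipeline at 50–200
replicates per quantity.

## Known limitations

* The bandwidth selector is tailored to boundary estimation with a
  window-size floor; it is not an MSE-optimal plug-in selector, and on
  strongly curved truths it will prefer wider windows than an oracle would.
* The bias-corrected inference pins the pilot bandwidth to the main one
  (ρ = 1); a separately selected pilot is not implemented.
* Fuzzy designs, discrete-running-variable corrections, clustered errors
  and cutoff estimation are out of scope.
* GIfTI surface input is not supported; OFF and PLY (ASCII and
  binary-little-endian) are.
* The convex hull is computed by an $O(nF)$ incremental algorithm — ample
  for morphometry-sized meshes (≈10⁴ vertices), not for million-vertex
  surfaces.

## A worked example

```{r example, eval = FALSE}
tab <- simulate_cohort(seed = 1)
norm <- filter_group(tab, c("fetal", "postnatal"))
summarize_cohort(norm)

fit <- rdd_fit(gyrification_index ~ scan_age_wpc, norm)
summary(fit)
plot(fit)

sf <- side_fits(norm, "gyrification_index")
growth_decomposition(sf$pre, sf$post)

multi_feature_rdd(norm, c("gyrification_index", "WM_mm3", "cGM_mm3",
                          "csf_mm3", "icv_mm3"))
```
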