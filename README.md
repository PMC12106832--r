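# perigyri

Cortical folding (gyrification) surges through the perinatal period, from
mid-gestation into the first months of life. Pooled fetal + neonatal MRI
samples show an abrupt step in the gyrification index right at the
term-birth threshold of 37 weeks post-conception (wPC) — a step absent from
tissue-volume trajectories. `perigyri` is an R package for developmental
neuroimaging researchers who want to quantify and stress-test such a birth
effect:

* a **3D gyrification index** on triangulated cortical meshes,
  `GI = surface area / convex-hull area` (1 for convex surfaces, larger the
  more folded), with OFF/PLY readers and a calibrated generator of folded
  synthetic surfaces;
* a **sharp regression-discontinuity (RDD) estimator** at the birth cutoff:
  local polynomial regressions on each side of 37 wPC (order 2, triangular
  kernel), leave-one-out cross-validated bandwidth, heteroskedasticity-
  robust leverage-corrected standard errors, conventional and bias-corrected
  inference, covariates, and a Bonferroni-corrected multi-feature screen;
* the **growth partition**: the fetal / birth-jump / postnatal percentage
  shares of total gyrification growth over 21–45 wPC, which telescope to
  100%;
* **sensitivity analyses**: scanner ANOVA within fetuses, sex-stratified
  discontinuity models, the preterm overlay (preterm babies are scanned
  with postnatal protocols but born before 37 wPC, so a continuous preterm
  trajectory rules out acquisition artefacts), and segmentation-variant
  comparison;
* a **synthetic cohort generator** reproducing the statistical structure of
  a pooled 819-session perinatal sample plus a 102-session preterm
  subgroup — truncated-normal age designs, exact sex and scanner
  composition, a piecewise-quadratic standardized gyrification trajectory
  with a configurable jump at birth (default shares 45.0% fetal, 21.4%
  jump, 33.6% postnatal), smooth continuous volume trajectories, and
  fetal-inflated CSF variance.

The discontinuity model, for outcome `Y`, running variable `X` (age in
wPC) and cutoff `c = 37`:

```
Y = β₀ + β₁(X−c) + ... + β_p(X−c)^p + ε   for X < c
Y = γ₀ + γ₁(X−c) + ... + γ_p(X−c)^p + ε   for X ≥ c
τ̂ = γ̂₀ − β̂₀,   effect size = |τ̂| / se(τ̂)
```

## Worked example

```r
library(perigyri)

tab  <- simulate_cohort(seed = 1)                     # 819 normative + 102 preterm
norm <- filter_group(tab, c("fetal", "postnatal"))
summarize_cohort(norm)
#> Cohort summary
#>   sessions:     819 (788 participants)
#>   sex (M:F:NA): 424:373:22
#>   scan age:      21.9-44.7 wPC (mean = 36.5; sd = 6.0)

fit <- rdd_fit(gyrification_index ~ scan_age_wpc, norm)
summary(fit)
#> Sharp regression discontinuity at 37 wPC (gyrification_index)
#>   tau = 0.08969, se = 0.0303, effect size = 2.96, p = 0.00312 [bias_corrected]
#>   95% CI [0.03021, 0.1492]; bandwidth 15.07 wk (triangular kernel, order 2); n = 361 + 457
#>   conventional   tau =   0.09895  se =   0.0176  z =   5.61  p = 2.02e-08
#>   bias_corrected tau =   0.08969  se =   0.0303  z =   2.96  p = 0.00312

sf <- side_fits(norm, "gyrification_index")
growth_decomposition(sf$pre, sf$post)
#> Perinatal growth partition (21-45 wPC, cutoff 37 wPC)
#>   fetal:      43.7 %
#>   birth jump: 22.9 %
#>   postnatal:  33.5 %
#>   total growth: 0.4592 (outcome units)
```

The fitted jump (`tau ≈ 0.09`, standardized units) recovers the injected
discontinuity (21.4% of a total growth of 0.45, i.e. 0.0963); the estimated
partition reproduces the generator's 45.0 / 21.4 / 33.6 shares up to
sampling noise, and exactly when noise is switched off. The screen across
the full feature set flags gyrification only:

```r
multi_feature_rdd(norm, c("gyrification_index", "WM_mm3", "cGM_mm3",
                          "csf_mm3", "icv_mm3"))
#> Discontinuity screen over 5 features (Bonferroni)
#>             feature       tau effect_size p_value  p_adj significant
#>  gyrification_index  9.89e-02      5.6103 0.00312 0.0156        TRUE
#>             csf_mm3 -1.76e+03      1.7356 0.53948 1.0000       FALSE
#>             icv_mm3 -2.81e+03      1.2486 0.47804 1.0000       FALSE
#>              WM_mm3 -6.02e+02      0.5942 0.87187 1.0000       FALSE
#>             cGM_mm3  5.39e+01      0.0345 0.64696 1.0000       FALSE
```

Mesh morphometry works on any closed triangulated surface:

```r
m <- simulate_folded_mesh(target_gi = 1.3, seed = 7)   # calibrated synthetic surface
gyrification_index(m)        # ~1.30
gyrification_index(icosphere(4))   # 1 (convex)
```

See `vignettes/perinatal-gyrification.Rmd` for the model, the generator's
assumptions, and the design choices behind the bandwidth selector and the
robust inference.

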