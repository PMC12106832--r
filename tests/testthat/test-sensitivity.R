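test_that("scanner ANOVA controls its size and detects injected offsets", {
  # size under a zero scanner effect
  p <- trajectory_params()
  rej <- vapply(1:200, function(s) {
    fet <- filter_group(simulate_cohort(seed = 400 + s), "fetal")
    scanner_anova(fet)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)

  # an additive offset on one scanner is recovered by the contrast
  delta <- 0.05
  fet <- filter_group(simulate_cohort(
    simulation_config(scanner_offsets = c(marsfet_15t = delta)),
    seed = 77), "fetal")
  an <- scanner_anova(fet)
  row <- an$contrasts[an$contrasts$scanner_a == "marsfet_15t" &
                        an$contrasts$scanner_b == "marsfet_3t", ]
  expect_lt(abs(abs(row$estimate) - delta), 3 * row$se)
  expect_lt(an$p, 0.05)
})

test_that("scanner ANOVA is invariant to row order and validates input", {
  fet <- filter_group(simulate_cohort(seed = 55), "fetal")
  a1 <- scanner_anova(fet)
  a2 <- scanner_anova(fet[rev(seq_len(nrow(fet))), ])
  expect_equal(a1$f_statistic, a2$f_statistic, tolerance = 1e-10)
  expect_equal(sort(a1$contrasts$estimate), sort(a2$contrasts$estimate),
               tolerance = 1e-10)
  expect_error(scanner_anova(fet[fet$scanner_id == "dhcp_3t", ]),
               "at least 2 scanner")
  expect_error(scanner_anova(simulate_cohort(seed = 1)), "fetal sessions")
})

test_that("scanner ANOVA reduces to a two-group comparison without age effects", {
  set.seed(8)
  n <- 60
  tab <- tiny_cohort(n)
  tab$scanner_id <- rep(c("a", "b"), each = n / 2)
  tab$scan_age_wpc <- rep(seq(25, 35, length.out = n / 2), 2)  # balanced
  tab$gyrification_index <- rnorm(n, 1.2 + 0.05 * (tab$scanner_id == "b"),
                                  0.03)
  an <- scanner_anova(tab)
  direct <- lm(gyrification_index ~ scanner_id +
                 poly(scan_age_wpc, 2), data = tab)
  expect_equal(an$contrasts$estimate[1],
               -unname(coef(direct)["scanner_idb"]), tolerance = 1e-8)
})

test_that("stratified models agree with the pooled model when strata match", {
  tab <- normative_table(seed = 14)
  tab$constant <- "all"
  st <- stratified_rdd(tab, gyrification_index ~ scan_age_wpc, "constant")
  pooled <- rdd_fit(gyrification_index ~ scan_age_wpc, tab)
  expect_equal(st$all$tau, pooled$tau, tolerance = 1e-12)

  # same generating process in both sexes: estimates agree within noise
  sx <- stratified_rdd(tab, gyrification_index ~ scan_age_wpc, "sex")
  expect_named(sx, c("M", "F"), ignore.order = TRUE)
  expect_lt(abs(sx$M$tau - sx$F$tau),
            3 * sqrt(sx$M$se^2 + sx$F$se^2))
})

test_that("the birth jump is detected within each sex stratum", {
  taus <- matrix(NA_real_, 60, 2)
  both_sig <- logical(60)
  for (s in 1:60) {
    tab <- normative_table(seed = s)
    sx <- stratified_rdd(tab, gyrification_index ~ scan_age_wpc, "sex")
    taus[s, ] <- c(sx$M$conventional$tau, sx$F$conventional$tau)
    both_sig[s] <- sx$M$conventional$p_value < 0.05 &&
      sx$F$conventional$p_value < 0.05
  }
  J <- 0.214 * (1 - 0.55)
  expect_lt(abs(mean(taus) / J - 1), 0.10)
  # per-stratum power is ~0.95 at these stratum sizes, so joint detection
  # lands near 0.90
  expect_gte(mean(both_sig), 0.75)
})

test_that("failed strata are flagged while the rest are returned", {
  tab <- normative_table(seed = 14)
  tab$odd <- ifelse(seq_len(nrow(tab)) <= 5, "rare", "common")
  st <- stratified_rdd(tab, gyrification_index ~ scan_age_wpc, "odd")
  expect_s3_class(st$rare, "rdd_stratum_failure")
  expect_s3_class(st$common, "rdd")
  expect_output(print(st), "skipped")
})

test_that("preterm sessions on the normative mean produce zero deviations", {
  p0 <- trajectory_params(noise_sd = 0)
  tab <- simulate_cohort(simulation_config(volume_noise_frac = 0), p0,
                         seed = 9)
  norm <- filter_group(tab, c("fetal", "postnatal"))
  sf <- side_fits(norm, "gyrification_index")
  pt <- filter_group(tab, "preterm")
  # place preterm sessions exactly on the normative fits
  pt$gyrification_index <- ifelse(pt$scan_age_wpc < 37,
                                  predict(sf$pre, pt$scan_age_wpc),
                                  predict(sf$post, pt$scan_age_wpc))
  ov <- preterm_overlay(pt, sf)
  expect_true(all(abs(ov$sessions$deviation) < 1e-10))
  expect_identical(nrow(ov$sessions), nrow(pt))
})

test_that("preterm overlay z-scores centre on zero after term", {
  tab <- simulate_cohort(seed = 41)
  norm <- filter_group(tab, c("fetal", "postnatal"))
  sf <- side_fits(norm, "gyrification_index")
  pt <- filter_group(tab, "preterm")
  ov <- preterm_overlay(pt, sf)
  post <- ov$sessions[ov$sessions$side == "post", ]
  expect_lt(abs(mean(post$z)), 3 / sqrt(nrow(post)))
  expect_s3_class(ov$rdd, "rdd")
  expect_output(print(ov), "preterm-only")
  # sessions outside the normative domain are flagged, not dropped
  pt2 <- pt
  pt2$scan_age_wpc[1] <- min(norm$scan_age_wpc) - 2
  ov2 <- preterm_overlay(pt2, sf)
  expect_true(ov2$sessions$flagged[1])
  expect_identical(nrow(ov2$sessions), nrow(pt2))
})

test_that("variant comparison flags divergences and ranks concordantly", {
  tab <- normative_table(seed = 26)
  feats <- c("gyrification_index", "WM_mm3", "cGM_mm3", "csf_mm3")
  a <- multi_feature_rdd(tab, feats)
  cmp <- variant_comparison(a, a)
  expect_true(all(cmp$per_feature$delta_tau == 0))
  expect_equal(cmp$rank_correlation, 1)
  expect_false(any(cmp$per_feature$status_differs))

  b <- a
  b$tau[b$feature == "WM_mm3"] <- 2 * b$tau[b$feature == "WM_mm3"]
  b$significant[b$feature == "WM_mm3"] <- TRUE
  cmp2 <- variant_comparison(a, b)
  expect_true(cmp2$per_feature$status_differs[
    cmp2$per_feature$feature == "WM_mm3"])
  expect_false(all(cmp2$per_feature$delta_tau == 0))

  # two independent re-simulations of the same truth rank gyrification first
  b2 <- multi_feature_rdd(normative_table(seed = 27), feats)
  cmp3 <- variant_comparison(a, b2)
  expect_identical(cmp3$top_feature_a, "gyrification_index")
  expect_identical(cmp3$top_feature_b, "gyrification_index")

  expect_error(variant_comparison(a, b2[b2$feature != "WM_mm3", ]),
               "mismatch")
})
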