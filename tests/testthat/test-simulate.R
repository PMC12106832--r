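test_that("trajectory mean realizes the configured growth partition", {
  p <- trajectory_params()
  G <- p$g_end - p$g_start
  eps <- 1e-9
  jump <- trajectory_mean(37, p) - trajectory_mean(37 - eps, p)
  expect_equal(jump, p$jump_fraction * G, tolerance = 1e-6)

  # postnatal share of total growth matches the printed 33.6%
  expect_equal((trajectory_mean(45, p) - trajectory_mean(37, p)) / G, 0.336,
               tolerance = 1e-12)
  expect_equal((trajectory_mean(37 - 1e-12, p) - trajectory_mean(21, p)) / G,
               0.450, tolerance = 1e-9)

  cont <- trajectory_params(fetal_fraction = 0.664, jump_fraction = 0,
                            postnatal_fraction = 0.336)
  expect_lt(abs(trajectory_mean(37, cont) - trajectory_mean(37 - 1e-9, cont)),
            1e-7)

  # monotone non-decreasing on each side
  gl <- seq(21, 37 - 1e-9, length.out = 200)
  gr <- seq(37, 45, length.out = 200)
  expect_true(all(diff(trajectory_mean(gl, p)) >= -1e-12))
  expect_true(all(diff(trajectory_mean(gr, p)) >= -1e-12))

  expect_error(trajectory_mean(20, p), "outside")
  expect_error(trajectory_params(fetal_fraction = 0.5), "sum to 1")
  expect_error(trajectory_params(side_shape = c(2, 0)), "monotone")
  expect_error(trajectory_params(g_start = 1.2), "positive")
})

test_that("age sampling honours bounds, seeds, and truncated-normal moments", {
  ages <- sample_ages(seed = 9)
  expect_identical(lengths(ages, use.names = FALSE), c(149L, 213L, 457L, 102L))
  expect_true(all(ages$marsfet >= 23.7 & ages$marsfet <= 37.0))
  expect_identical(sample_ages(seed = 9), ages)
  expect_false(identical(sample_ages(seed = 10), ages))

  # closed-form truncated-normal mean as independent oracle
  cfg <- simulation_config(cohorts = list(
    marsfet = list(n = 0L), dhcp_fetal = list(n = 0L),
    dhcp_preterm = list(n = 0L), dhcp_postnatal = list(n = 10000L)))
  x <- sample_ages(cfg, seed = 3)$dhcp_postnatal
  mu <- 41.5; sdv <- 1.6; lo <- 37.4; hi <- 44.9
  a <- (lo - mu) / sdv; b <- (hi - mu) / sdv
  Z <- pnorm(b) - pnorm(a)
  m_true <- mu + sdv * (dnorm(a) - dnorm(b)) / Z
  v_true <- sdv^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                       ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_lt(abs(mean(x) - m_true), 3 * sqrt(v_true / length(x)))
  expect_error(sample_ages(simulation_config(cohorts = list(
    marsfet = list(age = c(mean = 30, sd = 1, low = 33, high = 31))))),
    "degenerate")
})

test_that("simulated cohorts have the study's composition and are seed-stable", {
  tab <- simulate_cohort(seed = 21)
  expect_identical(nrow(tab), 921L)
  expect_identical(sum(tab$group != "preterm"), 819L)
  expect_identical(sum(tab$group == "preterm"), 102L)
  expect_identical(simulate_cohort(seed = 21), tab)
  expect_false(identical(simulate_cohort(seed = 22)$gyrification_index,
                         tab$gyrification_index))
  # preterm invariants hold at the source
  pt <- tab[tab$group == "preterm", ]
  expect_true(all(pt$birth_age_wpc < 37 & pt$birth_age_wpc <= pt$scan_age_wpc))
})

test_that("noise-free simulation reproduces the mean structure exactly", {
  p0 <- trajectory_params(noise_sd = 0)
  cfg <- simulation_config(volume_noise_frac = 0)
  tab <- simulate_cohort(cfg, p0, seed = 8)
  norm <- filter_group(tab, c("fetal", "postnatal"))
  expect_equal(norm$gyrification_index,
               trajectory_mean(norm$scan_age_wpc, p0), tolerance = 1e-12)

  # preterm rows lie on the continuous trajectory and overlay the postnatal
  # curve after term
  pt <- filter_group(tab, "preterm")
  post_term <- pt$scan_age_wpc >= 37
  expect_equal(pt$gyrification_index[post_term],
               trajectory_mean(pt$scan_age_wpc[post_term], p0),
               tolerance = 1e-12)
  cont <- trajectory_params(noise_sd = 0, jump_fraction = 0,
                            fetal_fraction = 0.664,
                            postnatal_fraction = 0.336)
  expect_equal(pt$gyrification_index,
               trajectory_mean(pt$scan_age_wpc, cont), tolerance = 1e-12)
})

test_that("noiseless volume trajectories carry no discontinuity at birth", {
  p0 <- trajectory_params(noise_sd = 0)
  # polynomial member of the growth family: representable exactly, tau = 0
  tabq <- normative_table(seed = 13, params = p0, volume_noise_frac = 0,
                          volume_family = "quadratic")
  f <- rdd_fit(WM_mm3 ~ scan_age_wpc, tabq, bandwidth = 6)
  expect_lt(abs(f$conventional$tau), 1e-8)
  expect_lt(abs(f$tau), 1e-8)
  # default sigmoid family: smooth, so the jump is negligible relative to
  # the volume scale though not exactly representable by a quadratic
  tabl <- normative_table(seed = 13, params = p0, volume_noise_frac = 0,
                          volume_family = "logistic")
  fl <- rdd_fit(WM_mm3 ~ scan_age_wpc, tabl, bandwidth = 6)
  lvl <- mean(tabl$WM_mm3)
  expect_lt(abs(fl$tau) / lvl, 1e-3)
})

test_that("sex and scanner offsets act additively on the standardized scale", {
  p0 <- trajectory_params(noise_sd = 0)
  base <- simulate_cohort(simulation_config(volume_noise_frac = 0), p0,
                          seed = 30)
  bumped <- simulate_cohort(
    simulation_config(sex_offset = 0.05,
                      scanner_offsets = c(marsfet_15t = -0.02),
                      volume_noise_frac = 0), p0, seed = 30)
  delta <- bumped$gyrification_index - base$gyrification_index
  expect_equal(delta,
               0.05 * (base$sex == "M") - 0.02 * (base$scanner_id == "marsfet_15t"),
               tolerance = 1e-12)
})
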