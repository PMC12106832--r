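test_that("kernel weights have the textbook shape", {
  expect_equal(kernel_weights(37, 37, 4), 1)
  expect_equal(kernel_weights(41, 37, 4), 0)
  expect_equal(kernel_weights(39, 37, 4), 0.5)
  expect_equal(kernel_weights(c(36, 37, 39), 37, 2, "uniform"), c(1, 1, 1))
  expect_equal(kernel_weights(37, 37, 2, "epanechnikov"), 0.75)
  w <- kernel_weights(seq(20, 50, 0.5), 37, 3)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[abs(seq(20, 50, 0.5) - 37) >= 3] == 0))
  expect_error(kernel_weights(1:5, 37, 0), "positive")
})

test_that("local polynomial fit equals OLS and the weighted normal equations", {
  set.seed(3)
  x <- runif(100, 30, 44)
  y <- 2 + 0.3 * (x - 37) - 0.01 * (x - 37)^2 + rnorm(100, 0, 0.2)

  b_all1 <- fit_local_polynomial(x, y, rep(1, 100), order = 2, center = 37)
  ols <- unname(coef(lm(y ~ I(x - 37) + I((x - 37)^2))))
  expect_equal(unname(b_all1), ols, tolerance = 1e-10)

  # noiseless polynomial of degree <= order is exact
  y0 <- 1 - 0.2 * (x - 37) + 0.05 * (x - 37)^2
  expect_equal(unname(fit_local_polynomial(x, y0, runif(100, 0.1, 1),
                                           order = 2, center = 37)),
               c(1, -0.2, 0.05), tolerance = 1e-10)

  w <- runif(100)
  b <- fit_local_polynomial(x, y, w, order = 2, center = 37)
  X <- outer(x - 37, 0:2, `^`)
  oracle <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(unname(b), drop(oracle), tolerance = 1e-10)
  expect_error(fit_local_polynomial(x[1:2], y[1:2], c(1, 1), order = 2),
               "rank deficiency")
})

test_that("noiseless piecewise-quadratic data return the exact jump", {
  ages <- bimodal_ages()
  J <- 0.123
  y <- piecewise_quadratic(ages, 37, J)
  for (kern in c("triangular", "uniform", "epanechnikov"))
    for (h in c(3, 8, 20)) {
      f <- rdd_fit(y ~ x, data.frame(x = ages, y = y), kernel = kern,
                   bandwidth = h)
      expect_equal(f$conventional$tau, J, tolerance = 1e-8)
      expect_equal(f$tau, J, tolerance = 1e-8)
    }
  f0 <- rdd_fit(y ~ x, data.frame(x = ages,
                                  y = piecewise_quadratic(ages, 37, 0)),
                bandwidth = 6)
  expect_lt(abs(f0$tau), 1e-10)
})

test_that("tau is equivariant under shift and scale of the outcome", {
  tab <- normative_table(seed = 17)
  f <- rdd_fit(gyrification_index ~ scan_age_wpc, tab, bandwidth = 7)
  shifted <- tab; shifted$gyrification_index <- tab$gyrification_index + 5
  fs <- rdd_fit(gyrification_index ~ scan_age_wpc, shifted, bandwidth = 7)
  expect_equal(fs$tau, f$tau, tolerance = 1e-9)
  expect_equal(fs$se, f$se, tolerance = 1e-9)
  expect_equal(fs$boundary, f$boundary + 5, tolerance = 1e-9)

  scaled <- tab; scaled$gyrification_index <- tab$gyrification_index * 3
  fk <- rdd_fit(gyrification_index ~ scan_age_wpc, scaled, bandwidth = 7)
  expect_equal(fk$tau, 3 * f$tau, tolerance = 1e-9)
  expect_equal(fk$se, 3 * f$se, tolerance = 1e-9)
  expect_equal(fk$effect_size, f$effect_size, tolerance = 1e-9)
})

test_that("observations outside the kernel window cannot influence tau", {
  tab <- normative_table(seed = 23)
  f <- rdd_fit(gyrification_index ~ scan_age_wpc, tab, bandwidth = 5)
  tampered <- tab
  far <- abs(tampered$scan_age_wpc - 37) >= 5
  tampered$gyrification_index[far] <- tampered$gyrification_index[far] + 100
  ft <- rdd_fit(gyrification_index ~ scan_age_wpc, tampered, bandwidth = 5)
  expect_equal(ft$tau, f$tau, tolerance = 1e-9)
  expect_equal(ft$se, f$se, tolerance = 1e-9)
})

test_that("additive covariates with common coefficients are recovered exactly", {
  ages <- bimodal_ages()
  set.seed(5)
  sex <- sample(c("M", "F"), length(ages), replace = TRUE)
  J <- 0.1
  y <- piecewise_quadratic(ages, 37, J) + 0.07 * (sex == "M")
  f <- rdd_fit(y ~ x + sex, data.frame(x = ages, y = y, sex = sex),
               bandwidth = 8)
  expect_equal(f$conventional$tau, J, tolerance = 1e-8)
  expect_equal(unname(f$coef_covariates), 0.07, tolerance = 1e-8)
  expect_error(rdd_fit(y ~ x + junk, data.frame(x = ages, y = y)),
               "not in data")
})

test_that("infinite-bandwidth uniform fits coincide with the side quadratics", {
  tab <- normative_table(seed = 31)
  f <- rdd_fit(gyrification_index ~ scan_age_wpc, tab, kernel = "uniform",
               bandwidth = Inf)
  sf <- side_fits(tab, "gyrification_index")
  probe <- c(29, 35, 36.9)
  expect_equal(predict(f, probe), predict(sf$pre, probe), tolerance = 1e-8)
  probe_r <- c(37, 40, 44)
  expect_equal(predict(f, probe_r), predict(sf$post, probe_r),
               tolerance = 1e-8)
  expect_equal(f$conventional$boundary[["right"]] -
               f$conventional$boundary[["left"]],
               f$conventional$tau, tolerance = 1e-12)
})

test_that("cross-validated bandwidths are deterministic and admissible", {
  tab <- normative_table(seed = 2)
  h1 <- select_bandwidth(tab$scan_age_wpc, tab$gyrification_index)
  h2 <- select_bandwidth(tab$scan_age_wpc, tab$gyrification_index)
  expect_identical(as.numeric(h1), as.numeric(h2))
  grid <- attr(h1, "grid")
  expect_gte(as.numeric(h1), min(grid$h))
  expect_lte(as.numeric(h1), max(grid$h))
  # a fixed bandwidth is passed through untouched
  f <- rdd_fit(gyrification_index ~ scan_age_wpc, tab, bandwidth = 4.25)
  expect_identical(f$bandwidth_used, 4.25)
})

test_that("cross-validated bandwidth is competitive with an oracle choice", {
  # truth known: compare boundary MSE of the CV bandwidth against the best
  # fixed bandwidth on the same grid, chosen with knowledge of the truth
  grid_h <- c(2, 3, 4.5, 7, 10, 15)
  truth_right <- piecewise_quadratic(37, 37, 0.1)
  set.seed(99)
  reps <- 40
  err_cv <- numeric(reps)
  err_fixed <- matrix(0, reps, length(grid_h))
  for (r in 1:reps) {
    ages <- c(runif(150, 22, 36.9), runif(150, 37.4, 44.9))
    y <- piecewise_quadratic(ages, 37, 0.1) + rnorm(300, 0, 0.05)
    d <- data.frame(x = ages, y = y)
    fcv <- rdd_fit(y ~ x, d)
    err_cv[r] <- (fcv$conventional$boundary[["right"]] - truth_right)^2
    for (j in seq_along(grid_h)) {
      fj <- rdd_fit(y ~ x, d, bandwidth = grid_h[j])
      err_fixed[r, j] <- (fj$conventional$boundary[["right"]] - truth_right)^2
    }
  }
  best_oracle <- min(colMeans(err_fixed))
  expect_lte(mean(err_cv), 2 * best_oracle)
})

test_that("feature screens adjust p-values by Bonferroni and expose both statistics", {
  tab <- normative_table(seed = 19)
  feats <- c("gyrification_index", "WM_mm3", "cGM_mm3")
  sc <- multi_feature_rdd(tab, feats)
  fits <- attr(sc, "fits")
  expect_equal(sc$p_adj, pmin(1, 3 * sc$p_value))
  expect_equal(sc$p_value,
               vapply(fits, function(f) f$bias_corrected$p_value, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(sc$effect_size,
               vapply(fits, function(f) f$conventional$effect_size,
                      numeric(1)),
               ignore_attr = TRUE)
  expect_true(all(sc$neglog10_p >= 0))
  expect_error(multi_feature_rdd(tab, character(0)), "at least one")
})

test_that("rdd objects print, summarize, predict and plot", {
  tab <- normative_table(seed = 37)
  f <- rdd_fit(gyrification_index ~ scan_age_wpc, tab)
  expect_output(print(f), "regression discontinuity")
  expect_output(summary(f), "bias_corrected")
  expect_named(confint(f)[1, ], c("lower", "upper"))
  expect_length(coef(f), 2 * (f$order + 1))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f))
})
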