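#' Quadratic developmental-trajectory fit
#'
#' Ordinary least squares of an outcome on centred age and its square,
#' the model used to describe the smooth perinatal trajectory of each
#' feature. Ages are centred before the polynomial expansion for numerical
#' conditioning; reported raw-scale coefficients are back-transformed.
#'
#' @param ages numeric vector of ages (wPC).
#' @param y numeric outcome vector, same length.
#' @return An object of class `trajectory_fit` with components
#'   `coefficients` (centred scale: intercept, linear, quadratic), `center`,
#'   `coefficients_raw`, `n`, `r_squared`, `residual_se` (denominator
#'   `n - 3`), `model_p` (overall F test), `fitted`, `residuals`.
#' @examples
#' a <- seq(21, 45, length.out = 50)
#' fit <- fit_quadratic(a, 1 + 0.02 * a + 0.001 * a^2)
#' coef(fit)
#' @export
fit_quadratic <- function(ages, y) {
  stopifnot(length(ages) == length(y))
  keep <- is.finite(ages) & is.finite(y)
  ages <- ages[keep]; y <- y[keep]
  n <- length(y)
  if (length(unique(ages)) < 3L)
    stop("need at least 3 distinct ages for a quadratic fit")
  ctr <- mean(ages)
  a <- ages - ctr
  X <- cbind(1, a, a^2)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("rank-deficient quadratic design")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  df_res <- n - 3L
  sigma <- if (df_res > 0) sqrt(sse / df_res) else 0
  model_p <- if (sst > 0 && df_res > 0 && sse > 0) {
    f <- ((sst - sse) / 2) / (sse / df_res)
    pf(f, 2, df_res, lower.tail = FALSE)
  } else if (sst > 0 && sse <= 0) 0 else NA_real_
  # back-transform to raw-age scale: b0 - b1 c + b2 c^2, b1 - 2 b2 c, b2
  raw <- c(beta[1] - beta[2] * ctr + beta[3] * ctr^2,
           beta[2] - 2 * beta[3] * ctr, beta[3])
  XtXi <- chol2inv(qr.R(qrX))
  structure(list(coefficients = setNames(beta, c("b0", "b1", "b2")),
                 vcov = XtXi * (if (df_res > 0) sse / df_res else 0),
                 center = ctr,
                 coefficients_raw = setNames(raw, c("(Intercept)", "age",
                                                    "age^2")),
                 n = n, r_squared = r2, residual_se = sigma,
                 model_p = model_p, ages = ages, y = y,
                 fitted = fitted, residuals = res),
            class = "trajectory_fit")
}

#' @export
coef.trajectory_fit <- function(object, raw = FALSE, ...)
  if (raw) object$coefficients_raw else object$coefficients

#' @export
vcov.trajectory_fit <- function(object, ...) object$vcov

#' @export
confint.trajectory_fit <- function(object, parm = 1:3, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  tq <- stats::qt(1 - (1 - level) / 2, df = object$n - 3L)
  b <- object$coefficients
  out <- cbind(b - tq * se, b + tq * se)
  colnames(out) <- paste0(c(100 * (1 - level) / 2,
                            100 * (1 - (1 - level) / 2)), " %")
  out[parm, , drop = FALSE]
}

#' @export
residuals.trajectory_fit <- function(object, ...) object$residuals

#' @export
fitted.trajectory_fit <- function(object, ...) object$fitted

#' @export
predict.trajectory_fit <- function(object, ages = object$ages, ...) {
  a <- ages - object$center
  b <- object$coefficients
  drop(cbind(1, a, a^2) %*% b)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Quadratic trajectory fit (n = ", x$n, ")\n", sep = "")
  cat("  coefficients (age centred at ", round(x$center, 2), " wPC):\n",
      sep = "")
  print(round(x$coefficients, 6))
  cat(sprintf("  R-squared = %.3f, residual SE = %.4g, model p = %.3g\n",
              x$r_squared, x$residual_se, x$model_p))
  invisible(x)
}

#' @export
summary.trajectory_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Independent quadratic fits on each side of the cutoff
#'
#' Splits the table at the cutoff (ages `< cutoff` are fetal, `>= cutoff`
#' postnatal, matching the discontinuity model's side convention) and fits a
#' full-side quadratic on each part.
#'
#' @param table cohort `data.frame` with a `scan_age_wpc` column.
#' @param outcome feature column name.
#' @param cutoff cutoff age (wPC).
#' @return A list with elements `pre` and `post`, both `trajectory_fit`.
#' @export
side_fits <- function(table, outcome, cutoff = 37) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  ages <- table$scan_age_wpc
  y <- table[[outcome]]
  l <- ages < cutoff
  if (length(unique(ages[l])) < 3L || length(unique(ages[!l])) < 3L)
    stop("each side of the cutoff needs at least 3 distinct ages")
  list(pre = fit_quadratic(ages[l], y[l]),
       post = fit_quadratic(ages[!l], y[!l]))
}

#' Partition of total perinatal growth at the birth cutoff
#'
#' Decomposes the total fitted growth between `age_min` and `age_max` into
#' the fetal share (growth of the pre-birth fit up to the cutoff), the birth
#' jump (difference between the first fitted value after and the last fitted
#' value before the cutoff) and the postnatal share, each as a percentage of
#' the total. The three shares telescope to 100% by construction.
#'
#' @param pre,post `trajectory_fit` objects for the fetal and postnatal side
#'   (e.g. from [side_fits()]).
#' @param age_min,cutoff,age_max evaluation ages (wPC).
#' @return An object of class `growth_decomposition` with components
#'   `fetal_pct`, `jump_pct`, `postnatal_pct`, `total_growth` and the four
#'   boundary fitted values.
#' @examples
#' tab <- filter_group(simulate_cohort(seed = 7), c("fetal", "postnatal"))
#' sf <- side_fits(tab, "gyrification_index")
#' growth_decomposition(sf$pre, sf$post)
#' @export
growth_decomposition <- function(pre, post, age_min = 21, cutoff = 37,
                                 age_max = 45) {
  stopifnot(inherits(pre, "trajectory_fit"), inherits(post, "trajectory_fit"))
  v_start <- predict(pre, age_min)
  v_cut_pre <- predict(pre, cutoff)
  v_cut_post <- predict(post, cutoff)
  v_end <- predict(post, age_max)
  total <- v_end - v_start
  if (total <= 0) stop("non-positive total growth over the perinatal window")
  structure(list(
    fetal_pct = 100 * (v_cut_pre - v_start) / total,
    jump_pct = 100 * (v_cut_post - v_cut_pre) / total,
    postnatal_pct = 100 * (v_end - v_cut_post) / total,
    total_growth = total,
    boundary = c(start = v_start, cutoff_pre = v_cut_pre,
                 cutoff_post = v_cut_post, end = v_end),
    ages = c(age_min = age_min, cutoff = cutoff, age_max = age_max)),
    class = "growth_decomposition")
}

#' @export
print.growth_decomposition <- function(x, ...) {
  cat("Perinatal growth partition (",
      x$ages[["age_min"]], "-", x$ages[["age_max"]], " wPC, cutoff ",
      x$ages[["cutoff"]], " wPC)\n", sep = "")
  cat(sprintf("  fetal:     %5.1f %%\n", x$fetal_pct))
  cat(sprintf("  birth jump:%5.1f %%\n", x$jump_pct))
  cat(sprintf("  postnatal: %5.1f %%\n", x$postnatal_pct))
  cat(sprintf("  total growth: %.4g (outcome units)\n", x$total_growth))
  invisible(x)
}
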