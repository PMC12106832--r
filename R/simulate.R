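#' Parameters of the standardized gyrification trajectory
#'
#' The generator's mean trajectory on the standardized gyrification scale
#' (series maximum = 1) is piecewise quadratic in postconceptional age with a
#' level shift at the term-birth cutoff. Writing `G = g_end - g_start` for the
#' total perinatal growth, the left (fetal) piece rises from `g_start` at
#' `age_min` to `g_start + fetal_fraction * G` just before the cutoff; the
#' jump at the cutoff is `jump_fraction * G`; the right (postnatal) piece then
#' rises to `g_end` at `age_max`. The three fractions partition the total
#' growth and must sum to one. Each side's curvature is set by a single shape
#' coefficient in `[-1, 1]` (positive = accelerating, negative =
#' decelerating), the range on which the quadratic stays monotone
#' non-decreasing between its endpoints. Defaults reproduce the study
#' conditions: 45.0% fetal, 21.4% jump, 33.6% postnatal growth, with residual
#' noise sd 0.04 on the standardized scale.
#'
#' @param cutoff_wpc term-birth cutoff (weeks post-conception).
#' @param age_min,age_max perinatal age window (wPC).
#' @param g_start,g_end standardized outcome at `age_min` and `age_max`.
#' @param fetal_fraction,jump_fraction,postnatal_fraction growth shares.
#' @param side_shape length-2 numeric, curvature of the fetal and postnatal
#'   pieces.
#' @param noise_sd residual standard deviation (standardized units).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(cutoff_wpc = 37, age_min = 21, age_max = 45,
                              g_start = 0.55, g_end = 1,
                              fetal_fraction = 0.450, jump_fraction = 0.214,
                              postnatal_fraction = 0.336,
                              side_shape = c(fetal = 0.6, postnatal = -0.5),
                              noise_sd = 0.04) {
  if (!(age_min < cutoff_wpc && cutoff_wpc < age_max))
    stop("cutoff must lie strictly inside [age_min, age_max]")
  if (abs(fetal_fraction + jump_fraction + postnatal_fraction - 1) > 1e-12)
    stop("growth fractions must sum to 1")
  if (min(fetal_fraction, jump_fraction, postnatal_fraction) < 0)
    stop("growth fractions must be non-negative")
  if (g_end <= g_start) stop("total growth g_end - g_start must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(side_shape) != 2L || any(abs(side_shape) > 1))
    stop("side_shape must be two coefficients in [-1, 1] (monotone range)")
  structure(list(cutoff_wpc = cutoff_wpc, age_min = age_min,
                 age_max = age_max, g_start = g_start, g_end = g_end,
                 fetal_fraction = fetal_fraction,
                 jump_fraction = jump_fraction,
                 postnatal_fraction = postnatal_fraction,
                 side_shape = side_shape, noise_sd = noise_sd),
            class = "trajectory_params")
}

# Monotone quadratic through (0,0)-(1,1) with curvature k in [-1, 1].
quad_ramp <- function(t, k) t + k * t * (t - 1)

#' Mean standardized gyrification at a given age
#'
#' Deterministic piecewise-quadratic mean function of the generator (no
#' noise). Side membership at the cutoff follows the discontinuity model:
#' ages `>= cutoff` belong to the postnatal piece.
#'
#' @param age numeric vector of ages in wPC, within
#'   `[age_min, age_max]`.
#' @param params a [trajectory_params()] object.
#' @return Numeric vector of standardized outcome values.
#' @examples
#' p <- trajectory_params()
#' trajectory_mean(c(30, 37, 45), p)
#' @export
trajectory_mean <- function(age, params = trajectory_params()) {
  stopifnot(inherits(params, "trajectory_params"))
  if (any(age < params$age_min - 1e-12) || any(age > params$age_max + 1e-12))
    stop("age outside the trajectory domain [", params$age_min, ", ",
         params$age_max, "] wPC")
  G <- params$g_end - params$g_start
  cut <- params$cutoff_wpc
  left_hi <- params$g_start + params$fetal_fraction * G
  right_lo <- left_hi + params$jump_fraction * G
  out <- numeric(length(age))
  l <- age < cut
  tl <- (age[l] - params$age_min) / (cut - params$age_min)
  out[l] <- params$g_start +
    (left_hi - params$g_start) * quad_ramp(tl, params$side_shape[[1]])
  tr <- (age[!l] - cut) / (params$age_max - cut)
  out[!l] <- right_lo +
    (params$g_end - right_lo) * quad_ramp(tr, params$side_shape[[2]])
  out
}

# Continuous preterm variant: the birth jump is removed by folding it into
# the fetal share, so the curve meets the postnatal piece at the cutoff and
# coincides with it afterwards (preterms overlay the postnatal curve
# post-term).
continuous_params <- function(params) {
  trajectory_params(
    cutoff_wpc = params$cutoff_wpc, age_min = params$age_min,
    age_max = params$age_max, g_start = params$g_start, g_end = params$g_end,
    fetal_fraction = params$fetal_fraction + params$jump_fraction,
    jump_fraction = 0, postnatal_fraction = params$postnatal_fraction,
    side_shape = params$side_shape, noise_sd = params$noise_sd)
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the demographic structure of the pooled perinatal study
#' sample: four sub-cohorts with the published session counts, truncated
#' normal scan-age designs (mean/sd/range per sub-cohort), exact sex splits
#' including an explicit unknown-sex level in the clinical fetal cohort, and
#' scanner composition (two scanners in the clinical fetal cohort, one
#' elsewhere). Preterm birth ages follow their published truncated-normal
#' distribution, clipped per session so birth precedes the scan. Postnatal
#' (at-term) birth ages, not tabulated in the source demographics, default to
#' a truncated normal centred on 40 wPC.
#'
#' @param cohorts optional per-cohort override list; see the default for the
#'   expected structure (`n`, `group`, `age = c(mean, sd, low, high)`,
#'   `sex_counts`, `scanners`, optionally `birth_age`, `n_participants`).
#' @param sex_offset additive effect (standardized units) on male sessions.
#' @param scanner_offsets named numeric, additive per-scanner offsets.
#' @param csf_var_ratio pre-birth over post-birth variance ratio of the CSF
#'   noise (`> 1`: fetal CSF is noisier).
#' @param volume_family `"logistic"` (smooth sigmoid growth) or
#'   `"quadratic"` (monotone quadratic member of the family).
#' @param volume_noise_frac per-tissue noise sd as a fraction of the local
#'   mean volume.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cohorts = NULL, sex_offset = 0,
                              scanner_offsets = NULL, csf_var_ratio = 4,
                              volume_family = c("logistic", "quadratic"),
                              volume_noise_frac = 0.04) {
  volume_family <- match.arg(volume_family)
  default_cohorts <- list(
    marsfet = list(
      n = 149L, n_participants = 130L, group = "fetal",
      age = c(mean = 31.6, sd = 2.5, low = 23.7, high = 37.0),
      sex_counts = c(M = 64L, F = 63L, `NA` = 22L),
      scanners = list(marsfet_3t = list(n = 84L, tesla = 3.0),
                      marsfet_15t = list(n = 65L, tesla = 1.5))),
    dhcp_fetal = list(
      n = 213L, n_participants = 202L, group = "fetal",
      age = c(mean = 29.4, sd = 3.5, low = 21.4, high = 36.7),
      sex_counts = c(M = 112L, F = 101L, `NA` = 0L),
      scanners = list(dhcp_3t = list(n = 213L, tesla = 3.0))),
    dhcp_postnatal = list(
      n = 457L, n_participants = 456L, group = "postnatal",
      age = c(mean = 41.5, sd = 1.6, low = 37.4, high = 44.9),
      birth_age = c(mean = 40.0, sd = 1.2, low = 37.0, high = 42.0),
      sex_counts = c(M = 248L, F = 209L, `NA` = 0L),
      scanners = list(dhcp_3t = list(n = 457L, tesla = 3.0))),
    dhcp_preterm = list(
      n = 102L, n_participants = 74L, group = "preterm",
      age = c(mean = 37.1, sd = 4.1, low = 26.7, high = 44.1),
      birth_age = c(mean = 31.8, sd = 3.3, low = 24.2, high = 36.8),
      sex_counts = c(M = 58L, F = 44L, `NA` = 0L),
      scanners = list(dhcp_3t = list(n = 102L, tesla = 3.0))))
  if (!is.null(cohorts)) {
    for (nm in names(cohorts))
      default_cohorts[[nm]] <- utils::modifyList(
        default_cohorts[[nm]] %||% list(), cohorts[[nm]])
    default_cohorts <- default_cohorts[
      vapply(default_cohorts, function(x) (x$n %||% 0L) > 0L, logical(1))]
  }
  for (nm in names(default_cohorts)) {
    ch <- default_cohorts[[nm]]
    if (ch$age[["low"]] >= ch$age[["high"]])
      stop("cohort '", nm, "': degenerate age bounds (low >= high)")
    if (ch$n < 0L) stop("cohort '", nm, "': n must be >= 0")
  }
  if (csf_var_ratio <= 0) stop("csf_var_ratio must be positive")
  structure(list(cohorts = default_cohorts, sex_offset = sex_offset,
                 scanner_offsets = scanner_offsets,
                 csf_var_ratio = csf_var_ratio,
                 volume_family = volume_family,
                 volume_noise_frac = volume_noise_frac),
            class = "simulation_config")
}

# Inverse-CDF truncated-normal sampler: seed-stable sample sizes (exactly n
# draws, no rejection).
rtruncnorm_icdf <- function(n, mean, sd, low, high) {
  if (low >= high) stop("degenerate truncation bounds (low >= high)")
  plo <- pnorm(low, mean, sd)
  phi <- pnorm(high, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Sample per-cohort scan ages
#'
#' Truncated-normal draws (inverse-CDF on the truncated interval) with the
#' configured mean, sd and range for every sub-cohort; sample sizes are exact
#' and reproducible under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return Named list of numeric age vectors (wPC), one per sub-cohort.
#' @export
sample_ages <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, lapply(config$cohorts, function(ch)
    rtruncnorm_icdf(ch$n, ch$age[["mean"]], ch$age[["sd"]],
                    ch$age[["low"]], ch$age[["high"]])))
}

# Exact integer allocation of n into the given counts/weights
# (largest-remainder), returned as a shuffled label vector.
allocate_labels <- function(n, counts) {
  w <- counts / sum(counts)
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0L) {
    frac <- w * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  sample(rep(names(counts), times = base))
}

# Smooth monotone tissue-volume growth curves (mm^3). The logistic family is
# the default; the quadratic member shares the same endpoint volumes so the
# two families are interchangeable in tests.
volume_curve_table <- data.frame(
  tissue = tissue_labels,
  vmax = c(9e4, 2.2e5, 1.8e5, 3.0e4, 9e3, 2.8e4, 7e3, 3.5e3),
  t0 = c(36, 40, 42, 38, 30, 42, 40, 38),
  s = c(7, 5, 6, 6, 5, 5, 8, 7),
  stringsAsFactors = FALSE)

volume_mean <- function(age, tissue, family = "logistic",
                        age_min = 21, age_max = 45) {
  row <- volume_curve_table[volume_curve_table$tissue == tissue, ]
  logi <- function(x) row$vmax / (1 + exp(-(x - row$t0) / row$s))
  if (family == "logistic") return(logi(age))
  v0 <- logi(age_min); v1 <- logi(age_max)
  t <- (age - age_min) / (age_max - age_min)
  v0 + (v1 - v0) * quad_ramp(t, 0.3)
}

#' Simulate a synthetic perinatal cohort with morphometric features
#'
#' Draws one row per MRI session: demographics per [simulation_config()],
#' standardized gyrification from the piecewise-quadratic trajectory (plus
#' optional additive sex/scanner offsets and Gaussian residual noise), and
#' tissue volumes from smooth monotone growth curves with no discontinuity at
#' birth. CSF noise is inflated before the cutoff by the configured variance
#' ratio. Preterm sessions are drawn from a continuous version of the
#' gyrification trajectory (no birth jump, level-matched so they overlay the
#' postnatal curve after term). The output is a valid cohort table containing
#' both the normative sample and the preterm subgroup; use
#' [filter_group()] to separate them.
#'
#' @param config a [simulation_config()].
#' @param params a [trajectory_params()].
#' @param seed integer seed; the full table is reproducible bitwise.
#' @return A cohort `data.frame` with demographic and feature columns.
#' @examples
#' tab <- simulate_cohort(seed = 42)
#' table(tab$group)
#' @export
simulate_cohort <- function(config = simulation_config(),
                            params = trajectory_params(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(params, "trajectory_params"))
  pt_params <- continuous_params(params)
  with_seed(seed, {
    blocks <- lapply(names(config$cohorts), function(nm) {
      ch <- config$cohorts[[nm]]
      n <- ch$n
      ages <- rtruncnorm_icdf(n, ch$age[["mean"]], ch$age[["sd"]],
                              ch$age[["low"]], ch$age[["high"]])
      ages <- pmin(pmax(ages, params$age_min), params$age_max)
      sex <- allocate_labels(n, ch$sex_counts)
      sc_n <- vapply(ch$scanners, function(s) s$n, numeric(1))
      scanner <- allocate_labels(n, sc_n)
      tesla <- vapply(ch$scanners, function(s) s$tesla, numeric(1))[scanner]
      npart <- min(ch$n_participants %||% n, n)
      part <- paste0(nm, "-p", sprintf("%04d", c(
        seq_len(npart), sample.int(npart, n - npart, replace = TRUE))))
      birth <- rep(NA_real_, n)
      if (ch$group %in% c("postnatal", "preterm")) {
        ba <- ch$birth_age
        birth <- rtruncnorm_icdf(n, ba[["mean"]], ba[["sd"]], ba[["low"]],
                                 ba[["high"]])
        birth <- pmin(birth, ages)  # birth precedes the scan
        if (ch$group == "preterm")
          birth <- pmin(birth, params$cutoff_wpc - 1e-6)
      }
      p_use <- if (ch$group == "preterm") pt_params else params
      gi <- trajectory_mean(ages, p_use)
      if (config$sex_offset != 0) gi <- gi + config$sex_offset * (sex == "M")
      if (!is.null(config$scanner_offsets)) {
        off <- config$scanner_offsets[scanner]
        off[is.na(off)] <- 0
        gi <- gi + off
      }
      gi <- gi + rnorm(n, 0, params$noise_sd)
      out <- data.frame(
        session_id = paste0(nm, "-s", sprintf("%04d", seq_len(n))),
        participant_id = part, cohort = nm, group = ch$group,
        scan_age_wpc = ages, birth_age_wpc = birth, sex = sex,
        scanner_id = scanner, field_strength_tesla = tesla,
        gyrification_index = gi, stringsAsFactors = FALSE)
      for (tissue in tissue_labels) {
        mu <- volume_mean(ages, tissue, config$volume_family,
                          params$age_min, params$age_max)
        sdv <- config$volume_noise_frac * mu
        if (tissue == "eCSF")  # fetal CSF is noisier by the variance ratio
          sdv <- sdv * ifelse(ages < params$cutoff_wpc,
                              sqrt(config$csf_var_ratio), 1)
        out[[paste0(tissue, "_mm3")]] <- pmax(mu + rnorm(n, 0, sdv), 1)
      }
      out$csf_mm3 <- out$eCSF_mm3 + out$lateral_ventricles_mm3
      out$icv_mm3 <- rowSums(out[paste0(tissue_labels, "_mm3")])
      out
    })
    tab <- pool_cohorts(blocks)
    validate_cohort(tab)
    tab
  })
}
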