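#' Scanner-effect ANOVA within the fetal sample
#'
#' Linear model of the outcome on age, age squared and scanner (categorical),
#' restricted to fetal sessions. The scanner factor is tested by an
#' extra-sum-of-squares F comparison against the age-only model (robust to
#' unbalanced scanner groups); pairwise scanner contrasts report the
#' age-adjusted mean difference, a standardized effect size (difference
#' divided by the residual SD) and a t-based p-value.
#'
#' @param fetal_table cohort `data.frame` of fetal sessions.
#' @param outcome feature column name.
#' @return An object of class `scanner_anova` with `f_statistic`, `df`, `p`,
#'   and a `contrasts` data.frame.
#' @export
scanner_anova <- function(fetal_table, outcome = "gyrification_index") {
  stopifnot(is.data.frame(fetal_table), outcome %in% names(fetal_table))
  if (!all(fetal_table$group == "fetal"))
    stop("scanner_anova expects fetal sessions only; use filter_group()")
  tab <- fetal_table
  levels_sc <- sort(unique(tab$scanner_id))
  if (length(levels_sc) < 2L) stop("need at least 2 scanner levels")
  cnt <- table(tab$scanner_id)
  if (any(cnt < 3L))
    stop("each scanner needs >= 3 sessions (got: ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), ")")
  tab$scanner_id <- factor(tab$scanner_id, levels = levels_sc)
  a <- tab$scan_age_wpc - mean(tab$scan_age_wpc)
  y <- tab[[outcome]]
  m0 <- lm(y ~ a + I(a^2))
  m1 <- lm(y ~ a + I(a^2) + tab$scanner_id)
  an <- anova(m0, m1)
  sigma <- summary(m1)$sigma
  V <- vcov(m1)
  cf <- coef(m1)
  sc_idx <- grep("scanner_id", names(cf))
  eff <- c(0, cf[sc_idx])          # level effects vs the first level
  names(eff) <- levels_sc
  pairs <- utils::combn(levels_sc, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    ct <- rep(0, length(cf))
    if (l1 != levels_sc[1]) ct[grep(paste0("scanner_id", l1), names(cf))] <- 1
    if (l2 != levels_sc[1]) ct[grep(paste0("scanner_id", l2), names(cf))] <- -1
    est <- drop(ct %*% cf)
    se <- sqrt(drop(t(ct) %*% V %*% ct))
    data.frame(scanner_a = l1, scanner_b = l2, estimate = est, se = se,
               effect_size = abs(est) / sigma,
               p = 2 * pt(-abs(est / se), df = m1$df.residual),
               stringsAsFactors = FALSE)
  }))
  structure(list(f_statistic = an$F[2], df = c(an$Df[2], m1$df.residual),
                 p = an$`Pr(>F)`[2], contrasts = contrasts,
                 residual_sd = sigma, n = nrow(tab), outcome = outcome),
            class = "scanner_anova")
}

#' @export
print.scanner_anova <- function(x, ...) {
  cat("Scanner ANOVA (fetal sessions, ", x$outcome, ", n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n", x$df[1], x$df[2],
              x$f_statistic, x$p))
  print(format(x$contrasts, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Stratified discontinuity models
#'
#' Runs the discontinuity model independently within each level of a
#' stratification column (e.g. sex). Levels lacking adequate per-side
#' support are flagged and skipped rather than aborting the whole analysis;
#' the `"NA"` sex level forms its own stratum only when `include_na = TRUE`.
#'
#' @param data cohort `data.frame`.
#' @param formula passed to [rdd_fit()].
#' @param by stratification column name.
#' @param include_na include the explicit `"NA"` level as a stratum.
#' @param ... passed to [rdd_fit()].
#' @return Named list of `rdd` fits (class `rdd_strata`); failed strata hold
#'   the condition message instead of a fit.
#' @export
stratified_rdd <- function(data, formula, by, include_na = FALSE, ...) {
  stopifnot(by %in% names(data))
  lv <- unique(as.character(data[[by]]))
  if (!include_na) lv <- setdiff(lv, "NA")
  fits <- lapply(setNames(lv, lv), function(l) {
    tryCatch(rdd_fit(formula, data[data[[by]] == l, , drop = FALSE], ...),
             error = function(e) structure(conditionMessage(e),
                                           class = "rdd_stratum_failure"))
  })
  structure(fits, class = "rdd_strata", by = by)
}

#' @export
print.rdd_strata <- function(x, ...) {
  cat("Stratified discontinuity models by '", attr(x, "by"), "'\n", sep = "")
  for (nm in names(x)) {
    cat("-- stratum ", nm, " --\n", sep = "")
    if (inherits(x[[nm]], "rdd_stratum_failure"))
      cat("  skipped: ", unclass(x[[nm]]), "\n", sep = "")
    else print(x[[nm]])
  }
  invisible(x)
}

#' Preterm overlay on the normative trajectory
#'
#' Maps each preterm session onto the normative side fits: the deviation is
#' the observed value minus the normative fitted value at the session's scan
#' age (using the fetal fit below the cutoff and the postnatal fit at or
#' above it), and the z-score divides the deviation by that side's residual
#' SE. Sessions whose scan age falls outside the normative age domain are
#' flagged, not dropped. A discontinuity model restricted to the preterm
#' sessions tests whether their own trajectory is continuous at the cutoff.
#'
#' @param preterm_table cohort `data.frame` of preterm sessions.
#' @param fits normative side fits from [side_fits()].
#' @param outcome feature column name.
#' @param cutoff cutoff age (wPC).
#' @param ... passed to the preterm-only [rdd_fit()].
#' @return An object of class `overlay_report`: per-session table
#'   (`deviation`, `z`, `side`, `flagged`) and the preterm-only `rdd` fit
#'   (`NULL` when the preterm sample cannot support one).
#' @export
preterm_overlay <- function(preterm_table, fits, outcome =
                              "gyrification_index", cutoff = 37, ...) {
  stopifnot(is.data.frame(preterm_table), outcome %in% names(preterm_table))
  if (!all(preterm_table$group == "preterm"))
    stop("preterm_overlay expects preterm sessions only")
  ages <- preterm_table$scan_age_wpc
  y <- preterm_table[[outcome]]
  left <- ages < cutoff
  expected <- ifelse(left, predict(fits$pre, ages), predict(fits$post, ages))
  side_se <- ifelse(left, fits$pre$residual_se, fits$post$residual_se)
  dom <- range(c(fits$pre$ages, fits$post$ages))
  sessions <- data.frame(
    session_id = preterm_table$session_id,
    scan_age_wpc = ages,
    side = ifelse(left, "pre", "post"),
    observed = y, expected = expected,
    deviation = y - expected,
    z = (y - expected) / ifelse(side_se > 0, side_se, 1),
    flagged = ages < dom[1] | ages > dom[2],
    stringsAsFactors = FALSE)
  rdd <- tryCatch(
    rdd_fit(stats::reformulate("scan_age_wpc", response = outcome),
            preterm_table, cutoff = cutoff, ...),
    error = function(e) NULL)
  structure(list(sessions = sessions, rdd = rdd, cutoff = cutoff,
                 outcome = outcome),
            class = "overlay_report")
}

#' @export
print.overlay_report <- function(x, ...) {
  cat("Preterm overlay (", nrow(x$sessions), " sessions, ", x$outcome,
      ")\n", sep = "")
  cat(sprintf("  mean deviation = %.4g; mean |z| = %.2f; %d session(s) outside the normative age domain\n",
              mean(x$sessions$deviation), mean(abs(x$sessions$z)),
              sum(x$sessions$flagged)))
  if (!is.null(x$rdd)) {
    cat("  preterm-only discontinuity at ", x$cutoff, " wPC:\n", sep = "")
    cat(sprintf("    tau = %.4g, effect size = %.2f, p = %.3g\n",
                x$rdd$tau, x$rdd$effect_size, x$rdd$p_value))
  }
  invisible(x)
}

#' Concordance of two multi-feature discontinuity screens
#'
#' Compares the discontinuity results obtained from two feature tables (for
#' example, two segmentation variants of the same sessions): per-feature
#' differences of `tau` and effect size, Spearman rank correlation of effect
#' sizes, and flags for features whose Bonferroni significance status
#' differs between the runs.
#'
#' @param results_a,results_b `rdd_screen` tables over the same feature set.
#' @return An object of class `variant_comparison`.
#' @export
variant_comparison <- function(results_a, results_b) {
  fa <- results_a$feature; fb <- results_b$feature
  if (!setequal(fa, fb))
    stop("feature-set mismatch: only in A: {",
         paste(setdiff(fa, fb), collapse = ", "), "}; only in B: {",
         paste(setdiff(fb, fa), collapse = ", "), "}")
  b <- as.data.frame(results_b)[match(fa, fb), ]
  a <- as.data.frame(results_a)
  per_feature <- data.frame(
    feature = fa,
    delta_tau = b$tau - a$tau,
    delta_effect_size = b$effect_size - a$effect_size,
    significant_a = a$significant, significant_b = b$significant,
    status_differs = a$significant != b$significant,
    stringsAsFactors = FALSE)
  structure(list(
    per_feature = per_feature,
    rank_correlation = cor(a$effect_size, b$effect_size,
                           method = "spearman"),
    top_feature_a = fa[which.max(a$effect_size)],
    top_feature_b = fa[which.max(b$effect_size)]),
    class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Variant comparison over", nrow(x$per_feature), "features\n")
  cat(sprintf("  effect-size rank correlation = %.3f; top feature: %s vs %s\n",
              x$rank_correlation, x$top_feature_a, x$top_feature_b))
  flip <- x$per_feature$feature[x$per_feature$status_differs]
  cat("  significance status differs for: ",
      if (length(flip)) paste(flip, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}
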