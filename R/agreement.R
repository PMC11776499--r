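# Per-mineral agreement analysis: correlation with CI-based strength
# categories, hemolysis-aware residual outlier screening, relative-error
# Bland-Altman statistics with bootstrap CIs, and the end-to-end report.

#' Relative error between paired measurements
#'
#' `100 * (icpms - standard) / standard`, the percentage difference metric
#' used on the Bland-Altman vertical axis.
#'
#' @param standard standard-method values; strictly positive.
#' @param icpms comparison-method values.
#' @return Relative errors in percent.
#' @export
relative_error <- function(standard, icpms) {
  if (any(standard <= 0))
    panel_error("relative error undefined for standard values <= 0",
                "undefined_statistic")
  100 * (icpms - standard) / standard
}

#' Mean of the two methods
#'
#' The Bland-Altman horizontal coordinate, `(standard + icpms) / 2`.
#'
#' @param standard,icpms paired values.
#' @return Per-subject means.
#' @export
method_mean <- function(standard, icpms) (standard + icpms) / 2

category_from_lower <- function(lo) {
  if (lo >= 0.9) "very strong"
  else if (lo >= 0.7) "strong"
  else if (lo >= 0.4) "moderate"
  else if (lo >= 0.1) "weak"
  else "negligible"
}

#' Correlation between channels with bootstrap CIs
#'
#' Pearson's r and Spearman's rho (average ranks for ties) with percentile
#' bootstrap confidence intervals. The strength category (`very strong` >=
#' 0.9, `strong` >= 0.7, `moderate` >= 0.4, `weak` >= 0.1, else
#' `negligible`) is read from the lower bound of the Spearman CI, so a
#' category claim is one the data support at the confidence level.
#'
#' @param x,y paired numeric vectors, n >= 8, both with dispersion.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return List with `pearson_r`, `pearson_ci`, `spearman_rho`,
#'   `spearman_ci`, `strength_category`.
#' @export
correlate <- function(x, y, B = 2000, seed, level = 0.95) {
  n <- length(x)
  if (length(y) != n) panel_error("x and y lengths differ", "data_error")
  if (n < 8L) panel_error("need at least 8 pairs", "data_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    panel_error("zero variance in a channel", "undefined_statistic")
  if (missing(seed)) panel_error("seed is mandatory", "config_error")
  r <- stats::cor(x, y, method = "pearson")
  rho <- stats::cor(x, y, method = "spearman")
  idx_ci <- function(f) {
    bootstrap_ci(seq_len(n), function(i) f(x[i], y[i]), B = B, seed = seed,
                 level = level)
  }
  r_ci <- idx_ci(function(a, b) stats::cor(a, b, method = "pearson"))
  rho_ci <- idx_ci(function(a, b) stats::cor(a, b, method = "spearman"))
  list(pearson_r = r, pearson_ci = r_ci,
       spearman_rho = rho, spearman_ci = rho_ci,
       strength_category = category_from_lower(rho_ci[["lower"]]))
}

#' Hemolysis-aware residual outlier screening
#'
#' Hemolyzed samples are removed first (their interference is a known
#' cause, not a statistical outlier), then a single Passing-Bablok fit on
#' the remainder flags subjects whose standardized residuals exceed the
#' threshold in absolute value. The regression is never refitted after
#' flagging (single-pass screening).
#'
#' @param panel a [paired_panel()] with at least 8 non-hemolyzed subjects.
#' @param threshold standardized-residual cutoff (default 3).
#' @return List with `hemolyzed_ids`, `residual_outlier_ids`, `z_scores`
#'   (named by retained subject), `threshold`, and `degenerate` (TRUE when
#'   the screening regression could not be fitted, in which case the
#'   residual set is empty).
#' @export
detect_outliers <- function(panel, threshold = 3.0) {
  stopifnot(inherits(panel, "paired_panel"))
  if (threshold <= 0) panel_error("threshold must be positive", "config_error")
  d <- panel$data
  keep <- !d$hemolyzed
  if (sum(keep) < 8L)
    panel_error("need at least 8 non-hemolyzed observations", "data_error")
  hem_ids <- d$subject_id[!keep]
  res <- tryCatch({
    fit <- pb_fit(d$standard_value[keep], d$icpms_value[keep])
    z <- residuals(fit, type = "standardized")
    names(z) <- d$subject_id[keep]
    list(z = z, degenerate = FALSE)
  }, regression_error = function(e) list(z = NULL, degenerate = TRUE))
  out_ids <- if (res$degenerate) character()
             else names(res$z)[abs(res$z) > threshold]
  list(hemolyzed_ids = hem_ids,
       residual_outlier_ids = out_ids,
       z_scores = res$z,
       threshold = threshold,
       degenerate = res$degenerate)
}

#' Relative-error Bland-Altman statistics
#'
#' Computes per-subject relative errors after exclusions, their mean and
#' sample SD, the limits of agreement (mean +/- 1.96 SD), and percentile
#' bootstrap CIs for the mean and both limits. Bootstrap resampling is over
#' subjects, recomputing mean and SD jointly on each resample.
#'
#' @param panel a [paired_panel()].
#' @param exclude subject ids to drop before analysis.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level for the bootstrap intervals.
#' @return List with `n_used`, `mean_re`, `sd_re`, `loa_lower`, `loa_upper`
#'   (all in percent), `mean_ci`, `loa_lower_ci`, `loa_upper_ci`,
#'   `excluded_ids`, and the per-subject `re` and `avg` coordinates.
#' @export
bland_altman <- function(panel, exclude = character(), B = 2000, seed,
                         level = 0.95) {
  stopifnot(inherits(panel, "paired_panel"))
  if (missing(seed)) panel_error("seed is mandatory", "config_error")
  d <- panel$data[!panel$data$subject_id %in% exclude, , drop = FALSE]
  if (nrow(d) < 8L)
    panel_error("need at least 8 observations after exclusions", "data_error")
  re <- relative_error(d$standard_value, d$icpms_value)
  names(re) <- d$subject_id
  m <- mean(re); s <- stats::sd(re)
  n <- length(re)
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      v <- re[sample.int(n, n, replace = TRUE)]
      mb <- mean(v); sb <- stats::sd(v)
      c(mb, mb - 1.96 * sb, mb + 1.96 * sb)
    }, numeric(3)))
  })
  alpha <- 1 - level
  ci <- function(col) {
    q <- percentiles(boot[, col], c(alpha / 2, 1 - alpha / 2))
    c(lower = q[1], upper = q[2])
  }
  list(n_used = n, mean_re = m, sd_re = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       mean_ci = ci(1), loa_lower_ci = ci(2), loa_upper_ci = ci(3),
       excluded_ids = exclude, re = re,
       avg = stats::setNames(method_mean(d$standard_value, d$icpms_value),
                             d$subject_id))
}

#' Run the full agreement analysis for one mineral
#'
#' Reproduces the method-comparison pipeline end to end: Passing-Bablok
#' regression and correlations on all data (outliers included), hemolysis
#' exclusion followed by single-pass standardized-residual outlier
#' screening, Bland-Altman relative-error statistics before and after
#' filtering, and the slope/intercept agreement verdict. Total (ICP-MS)
#' versus inorganic (standard) phosphorus runs through the identical
#' pipeline; its large mean relative error is expected output.
#'
#' @param panel a [paired_panel()].
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param threshold standardized-residual outlier cutoff.
#' @param level confidence level.
#' @return An object of class `"agreement_report"`: list with `mineral`,
#'   `fit` (a [pb_fit()] or NULL when degenerate), `fit_error`,
#'   `correlation`, `outliers`, `ba_pre`, `ba_post`, `verdict`.
#' @examples
#' panels <- simulate_panels(default_panel_config(n = 60, seed = 7))
#' rep <- run_agreement(panels$Cu, B = 200, seed = 7)
#' print(rep)
#' @export
run_agreement <- function(panel, B = 2000, seed, threshold = 3.0,
                          level = 0.95) {
  stopifnot(inherits(panel, "paired_panel"))
  if (missing(seed)) panel_error("seed is mandatory", "config_error")
  d <- panel$data
  seeds <- with_seed(seed, sample.int(2^30, 3))

  fit <- NULL; fit_error <- NULL; verdict <- NULL
  tryCatch({
    fit <- pb_fit(d$standard_value, d$icpms_value, level = level)
    verdict <- agreement_verdict(fit)
  }, serumpanel_error = function(e) fit_error <<- conditionMessage(e))

  correlation <- tryCatch(
    correlate(d$standard_value, d$icpms_value, B = B, seed = seeds[1],
              level = level),
    serumpanel_error = function(e) NULL)

  outliers <- detect_outliers(panel, threshold = threshold)
  ba_pre <- bland_altman(panel, exclude = character(), B = B,
                         seed = seeds[2], level = level)
  ba_post <- bland_altman(panel,
                          exclude = c(outliers$hemolyzed_ids,
                                      outliers$residual_outlier_ids),
                          B = B, seed = seeds[3], level = level)
  structure(
    list(mineral = panel$mineral$name, unit = panel$mineral$unit,
         fit = fit, fit_error = fit_error, correlation = correlation,
         outliers = outliers, ba_pre = ba_pre, ba_post = ba_post,
         verdict = verdict, seed = seed, B = B, threshold = threshold,
         level = level),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement analysis: %s [%s]\n", x$mineral, x$unit))
  if (!is.null(x$fit)) {
    cat(sprintf("  PB fit: y = %s + %s * x; slope CI [%s, %s], intercept CI [%s, %s]\n",
                format(coef(x$fit)["intercept"], digits = digits),
                format(coef(x$fit)["slope"], digits = digits),
                format(x$fit$slope_ci["lower"], digits = digits),
                format(x$fit$slope_ci["upper"], digits = digits),
                format(x$fit$intercept_ci["lower"], digits = digits),
                format(x$fit$intercept_ci["upper"], digits = digits)))
    cat(sprintf("  verdict: %s\n",
                if (x$verdict$agrees) "methods agree"
                else paste(x$verdict$reasons, collapse = "; ")))
  } else {
    cat(sprintf("  PB fit unavailable: %s\n", x$fit_error))
  }
  if (!is.null(x$correlation))
    cat(sprintf("  Spearman rho %s [%s, %s] (%s)\n",
                format(x$correlation$spearman_rho, digits = digits),
                format(x$correlation$spearman_ci[["lower"]], digits = digits),
                format(x$correlation$spearman_ci[["upper"]], digits = digits),
                x$correlation$strength_category))
  cat(sprintf("  outliers: %d hemolyzed excluded, %d residual (|z| > %s)\n",
              length(x$outliers$hemolyzed_ids),
              length(x$outliers$residual_outlier_ids),
              format(x$outliers$threshold)))
  cat(sprintf("  relative error pre-filter:  mean %s%%, LoA [%s%%, %s%%] (n = %d)\n",
              format(x$ba_pre$mean_re, digits = digits),
              format(x$ba_pre$loa_lower, digits = digits),
              format(x$ba_pre$loa_upper, digits = digits), x$ba_pre$n_used))
  cat(sprintf("  relative error post-filter: mean %s%%, LoA [%s%%, %s%%] (n = %d)\n",
              format(x$ba_post$mean_re, digits = digits),
              format(x$ba_post$loa_lower, digits = digits),
              format(x$ba_post$loa_upper, digits = digits), x$ba_post$n_used))
  invisible(x)
}

# flat one-row data.frame for the combined CSV export
agreement_row <- function(x) {
  data.frame(
    mineral = x$mineral,
    slope = if (is.null(x$fit)) NA_real_ else unname(coef(x$fit)["slope"]),
    slope_lower = if (is.null(x$fit)) NA_real_ else unname(x$fit$slope_ci["lower"]),
    slope_upper = if (is.null(x$fit)) NA_real_ else unname(x$fit$slope_ci["upper"]),
    intercept = if (is.null(x$fit)) NA_real_ else unname(coef(x$fit)["intercept"]),
    intercept_lower = if (is.null(x$fit)) NA_real_ else unname(x$fit$intercept_ci["lower"]),
    intercept_upper = if (is.null(x$fit)) NA_real_ else unname(x$fit$intercept_ci["upper"]),
    rho = if (is.null(x$correlation)) NA_real_ else x$correlation$spearman_rho,
    rho_lower = if (is.null(x$correlation)) NA_real_ else unname(x$correlation$spearman_ci["lower"]),
    rho_upper = if (is.null(x$correlation)) NA_real_ else unname(x$correlation$spearman_ci["upper"]),
    mean_re_pre = x$ba_pre$mean_re,
    mean_re_post = x$ba_post$mean_re,
    loa_lower = x$ba_post$loa_lower,
    loa_upper = x$ba_post$loa_upper,
    n_hemolyzed = length(x$outliers$hemolyzed_ids),
    n_residual_outliers = length(x$outliers$residual_outlier_ids),
    stringsAsFactors = FALSE)
}
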