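# ROC evaluation of the comparison method for detecting mineral surplus or
# deficiency defined by the standard method against reference intervals:
# empirical ROC curve, Mann-Whitney AUC, Youden-index cutoff, stratified
# bootstrap confidence intervals.

#' Label surplus or deficiency from the standard-method channel
#'
#' Surplus: positive iff the value is strictly above the upper reference
#' limit. Deficiency: positive iff strictly below the lower limit. Labels
#' depend only on the standard-method channel.
#'
#' @param standard_values standard-method values in the reporting unit.
#' @param definition a [mineral()].
#' @param kind `"surplus"` or `"deficiency"`.
#' @return Integer vector of 0/1 labels.
#' @export
label_condition <- function(standard_values, definition,
                            kind = c("surplus", "deficiency")) {
  stopifnot(inherits(definition, "mineral"))
  kind <- match.arg(kind)
  if (kind == "surplus") as.integer(standard_values > definition$ri_high)
  else as.integer(standard_values < definition$ri_low)
}

#' Case-count eligibility for screening analysis
#'
#' Screening metrics are only stable with enough cases; the default
#' eligibility floor is 10 positives.
#'
#' @param labels 0/1 labels.
#' @param min_cases minimum positive count (default 10).
#' @return List with `eligible` and `n_positive`.
#' @export
check_eligibility <- function(labels, min_cases = 10) {
  npos <- sum(labels == 1)
  list(eligible = npos >= min_cases, n_positive = npos)
}

#' Empirical ROC curve
#'
#' Sweeps all distinct predictor values as thresholds (plus the trivial
#' all-negative end), using `predictor >= threshold` as the positive call.
#' With `direction = "lower"` the predictor is negated before thresholding,
#' so low concentrations call deficiency.
#'
#' @param labels 0/1 labels with both classes present.
#' @param predictor numeric predictor (the comparison-method channel).
#' @param direction `"higher"` (higher predictor is positive) or `"lower"`.
#' @return Data frame with `threshold` (on the original predictor scale;
#'   `Inf`/`-Inf` at the ends), `fpr`, `tpr`, `sens`, `spec`, anchored at
#'   (0,0) and (1,1) and monotone in both coordinates.
#' @export
roc_curve <- function(labels, predictor, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(labels) != length(predictor))
    panel_error("labels and predictor lengths differ", "data_error")
  if (length(unique(labels)) < 2L)
    panel_error("both classes must be present", "data_error")
  s <- if (direction == "higher") predictor else -predictor
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & labels == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & labels == 0) / nneg, numeric(1))
  thr_out <- if (direction == "higher") c(Inf, thr) else c(-Inf, -thr)
  data.frame(threshold = thr_out,
             fpr = c(0, fpr), tpr = c(0, tpr),
             sens = c(0, tpr), spec = 1 - c(0, fpr))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the proportion of
#' (positive, negative) pairs where the positive ranks higher, ties counted
#' one half. This equals the trapezoidal area under the empirical curve.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, predictor, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(unique(labels)) < 2L)
    panel_error("both classes must be present", "data_error")
  s <- if (direction == "higher") predictor else -predictor
  # rank-sum form of the Mann-Whitney U statistic (ties -> average ranks)
  r <- rank(s)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Youden-index cutoff of an ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's thresholds;
#' ties broken by higher sensitivity, then by smaller Euclidean distance to
#' the top-left corner (0, 1).
#'
#' @param curve a data frame from [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(curve) {
  j <- curve$sens + curve$spec - 1
  dist <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  ord <- order(-j, -curve$sens, dist)
  i <- ord[1]
  list(cutoff = curve$threshold[i], sensitivity = curve$sens[i],
       specificity = curve$spec[i], youden_j = j[i])
}

#' Screen a surplus/deficiency condition with bootstrap CIs
#'
#' Runs the full screening evaluation: condition labels from the
#' standard-method channel against the reference interval, comparison
#' method as predictor (negated internally for deficiency so reported
#' cutoffs stay in concentration units with "<= cutoff is positive"
#' semantics), empirical ROC, Mann-Whitney AUC, Youden cutoff, and
#' stratified (class-preserving) percentile bootstrap CIs for AUC, cutoff,
#' sensitivity and specificity. Point estimates come from the full data and
#' are not resampled.
#'
#' @param panel a [paired_panel()].
#' @param kind `"surplus"` or `"deficiency"`.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param min_cases eligibility floor on positives (default 10).
#' @param level confidence level.
#' @return An object of class `"screening_result"`.
#' @examples
#' panels <- simulate_panels(default_panel_config(n = 120, seed = 3))
#' screen_condition(panels$Zn, "deficiency", B = 200, seed = 3)
#' @export
screen_condition <- function(panel, kind = c("surplus", "deficiency"),
                             B = 2000, seed, min_cases = 10, level = 0.95) {
  stopifnot(inherits(panel, "paired_panel"))
  kind <- match.arg(kind)
  if (missing(seed)) panel_error("seed is mandatory", "config_error")
  labels <- label_condition(panel$data$standard_value, panel$mineral, kind)
  predictor <- panel$data$icpms_value
  elig <- check_eligibility(labels, min_cases)
  if (!elig$eligible)
    panel_error(sprintf("ineligible: %d cases of %s %s (minimum %d)",
                        elig$n_positive, panel$mineral$name, kind, min_cases),
                "eligibility_error")
  direction <- if (kind == "surplus") "higher" else "lower"

  curve <- roc_curve(labels, predictor, direction)
  a <- roc_auc(labels, predictor, direction)
  yc <- youden_cutoff(curve)

  pos <- which(labels == 1); neg <- which(labels == 0)
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- c(pos[sample.int(length(pos), replace = TRUE)],
               neg[sample.int(length(neg), replace = TRUE)])
      cb <- roc_curve(labels[idx], predictor[idx], direction)
      yb <- youden_cutoff(cb)
      c(roc_auc(labels[idx], predictor[idx], direction),
        yb$cutoff, yb$sensitivity, yb$specificity)
    }, numeric(4)))
  })
  alpha <- 1 - level
  ci <- function(col) {
    v <- boot[, col][is.finite(boot[, col])]
    q <- percentiles(v, c(alpha / 2, 1 - alpha / 2))
    c(lower = q[1], upper = q[2])
  }
  structure(
    list(mineral = panel$mineral$name, kind = kind,
         direction = if (direction == "higher") "higher-is-positive"
                     else "lower-is-positive",
         n_positive = elig$n_positive,
         n_negative = length(labels) - elig$n_positive,
         auc = a, auc_ci = ci(1),
         cutoff = yc$cutoff, cutoff_ci = ci(2),
         sensitivity = yc$sensitivity, sensitivity_ci = ci(3),
         specificity = yc$specificity, specificity_ci = ci(4),
         youden_j = yc$youden_j, roc_points = curve[, c("fpr", "tpr")],
         curve = curve, seed = seed, B = B, level = level),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, digits = 3, ...) {
  cat(sprintf("Screening: %s %s (%s), %d positive / %d negative\n",
              x$mineral, x$kind, x$direction, x$n_positive, x$n_negative))
  cat(sprintf("  AUC %s [%s, %s]\n", format(x$auc, digits = digits),
              format(x$auc_ci[["lower"]], digits = digits),
              format(x$auc_ci[["upper"]], digits = digits)))
  cat(sprintf("  Youden cutoff %s [%s, %s]: sens %s [%s, %s], spec %s [%s, %s]\n",
              format(x$cutoff, digits = digits),
              format(x$cutoff_ci[["lower"]], digits = digits),
              format(x$cutoff_ci[["upper"]], digits = digits),
              format(x$sensitivity, digits = digits),
              format(x$sensitivity_ci[["lower"]], digits = digits),
              format(x$sensitivity_ci[["upper"]], digits = digits),
              format(x$specificity, digits = digits),
              format(x$specificity_ci[["lower"]], digits = digits),
              format(x$specificity_ci[["upper"]], digits = digits)))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a `"screening_result"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.screening_result <- function(x, ...) {
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(a = 0, b = 1, lty = 2, col = "grey")
  graphics::points(1 - x$specificity, x$sensitivity, col = "red", pch = 19)
  invisible(x)
}
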