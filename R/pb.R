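# Passing-Bablok structural regression: slope as the K-shifted median of all
# pairwise slopes, rank-based confidence intervals, standardized residuals.

#' All pairwise slopes of a scatter, with the Passing-Bablok exclusions
#'
#' Enumerates \eqn{(y_j - y_i)/(x_j - x_i)} over all pairs \eqn{i < j},
#' dropping pairs identical in both coordinates and slopes exactly equal to
#' \eqn{-1} (which carry no information on the structural slope under the
#' method's symmetry argument). Pairs with equal x but unequal y contribute
#' signed infinities, which sorting places at the extremes. `offset_k` counts
#' slopes below \eqn{-1}; the slope estimate is the median of the sorted
#' multiset shifted by this offset.
#'
#' @param x,y numeric vectors of equal length (at least 3 distinct points).
#' @return List with `slopes` (sorted, possibly infinite) and `offset_k`.
#' @export
pairwise_slopes <- function(x, y) {
  n <- length(x)
  if (length(y) != n) panel_error("x and y lengths differ", "data_error")
  if (sum(!duplicated(cbind(x, y))) < 3L)
    panel_error("need at least 3 distinct points", "data_error")
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  dx <- x[j] - x[i]
  dy <- y[j] - y[i]
  keep <- !(dx == 0 & dy == 0)          # identical points carry no slope
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, ifelse(dy > 0, Inf, -Inf), dy / dx)
  s <- s[s != -1]                       # exact -1 slopes are excluded
  list(slopes = sort(s), offset_k = sum(s < -1))
}

#' Fit a Passing-Bablok regression
#'
#' Nonparametric structural regression for method comparison: both variables
#' may carry measurement error, no distributional assumption is made, and
#' the fit is robust to outliers. The slope is the median of all pairwise
#' slopes shifted by the count K of slopes below \eqn{-1}; the intercept is
#' the median of \eqn{y_i - b x_i}. Confidence intervals come from the rank
#' statistics of the slope multiset, using the normal approximation
#' \eqn{C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}} at every sample size.
#'
#' @param x standard-method measurements (explanatory channel).
#' @param y comparison-method measurements (response channel).
#' @param level confidence level for slope and intercept intervals.
#' @return An object of class `"pb_fit"` with components `coefficients`
#'   (`intercept`, `slope`), `slope_ci`, `intercept_ci`, `n_obs`,
#'   `n_pairs_used`, `offset_k`, `level`, and the data (`x`, `y`).
#' @seealso [predict.pb_fit()], [residuals.pb_fit()], [agreement_verdict()]
#' @examples
#' set.seed(1)
#' x <- runif(30, 80, 120)
#' fit <- pb_fit(x, 0.95 * x * (1 + rnorm(30, 0, 0.03)))
#' coef(fit)
#' confint(fit)
#' @export
pb_fit <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) panel_error("need at least 3 observations", "data_error")
  if (length(unique(x)) < 2L)
    panel_error("explanatory channel shows no dispersion; regression undefined",
                "regression_error")
  ps <- pairwise_slopes(x, y)
  s <- ps$slopes
  k <- ps$offset_k
  N <- length(s)
  if (N == 0L)
    panel_error("no informative pairwise slopes", "regression_error")

  at <- function(idx) s[min(max(idx, 1L), N)]
  b <- if (N %% 2L == 1L) at((N + 1L) %/% 2L + k)
       else (at(N %/% 2L + k) + at(N %/% 2L + 1L + k)) / 2
  if (!is.finite(b))
    panel_error("slope estimate is not finite (degenerate configuration)",
                "regression_error")

  z <- stats::qnorm(1 - (1 - level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round_half_away((N - C) / 2, 0)
  m2 <- N - m1 + 1
  b_lo <- at(m1 + k)
  b_hi <- at(m2 + k)

  a <- stats::median(y - b * x)
  # intercept bounds pair with the opposite slope bounds
  a_lo <- stats::median(y - b_hi * x)
  a_hi <- stats::median(y - b_lo * x)

  structure(
    list(coefficients = c(intercept = a, slope = b),
         slope_ci = c(lower = b_lo, upper = b_hi),
         intercept_ci = c(lower = a_lo, upper = a_hi),
         n_obs = n, n_pairs_used = N, offset_k = k,
         level = level, x = x, y = y),
    class = "pb_fit")
}

#' @export
coef.pb_fit <- function(object, ...) object$coefficients

#' @export
confint.pb_fit <- function(object, parm = c("intercept", "slope"),
                           level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  ci <- rbind(intercept = object$intercept_ci, slope = object$slope_ci)
  ci[parm, , drop = FALSE]
}

#' Predict from a Passing-Bablok fit
#'
#' @param object a [pb_fit()] object.
#' @param newdata numeric vector of standard-method values; defaults to the
#'   fitted data.
#' @param ... unused.
#' @return Predicted comparison-method values `a + b * newdata`.
#' @export
predict.pb_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  unname(object$coefficients["intercept"] + object$coefficients["slope"] * x)
}

#' Residuals of a Passing-Bablok fit
#'
#' Raw residuals are \eqn{e_i = y_i - (a + b x_i)}. Standardized residuals
#' are mean-centred and scaled by the sample standard deviation (n-1
#' denominator); when the residual variance is zero they are defined as 0.
#' Observations with `|z| > 3` are the conventional outlier flags in
#' method-comparison screening.
#'
#' @param object a [pb_fit()] object.
#' @param type `"standardized"` (default) or `"raw"`.
#' @param ... unused.
#' @return Numeric vector of residuals.
#' @export
residuals.pb_fit <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  e <- object$y - predict(object)
  if (type == "raw") return(e)
  s <- stats::sd(e)
  if (!is.finite(s) || s == 0) return(rep(0, length(e)))
  (e - mean(e)) / s
}

#' Does a fit indicate agreement between methods?
#'
#' Methods are judged interchangeable on the regression scale when the
#' confidence interval of the slope contains 1 and that of the intercept
#' contains 0.
#'
#' @param fit a [pb_fit()] object.
#' @return List with `agrees` (logical) and `reasons` (character vector of
#'   failed criteria, empty when agreeing).
#' @export
agreement_verdict <- function(fit) {
  stopifnot(inherits(fit, "pb_fit"))
  reasons <- character()
  if (!(fit$slope_ci["lower"] <= 1 && 1 <= fit$slope_ci["upper"]))
    reasons <- c(reasons, "slope CI excludes 1")
  if (!(fit$intercept_ci["lower"] <= 0 && 0 <= fit$intercept_ci["upper"]))
    reasons <- c(reasons, "intercept CI excludes 0")
  list(agrees = length(reasons) == 0L, reasons = reasons)
}

#' @export
print.pb_fit <- function(x, digits = 4, ...) {
  cat("Passing-Bablok regression\n")
  cat(sprintf("  y = %s + %s * x   (n = %d)\n",
              format(x$coefficients["intercept"], digits = digits),
              format(x$coefficients["slope"], digits = digits), x$n_obs))
  invisible(x)
}

#' @export
summary.pb_fit <- function(object, ...) {
  v <- agreement_verdict(object)
  structure(list(fit = object, verdict = v), class = "summary.pb_fit")
}

#' @export
print.summary.pb_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  lv <- format(100 * f$level)
  cat(sprintf("  slope     %s  %s%% CI [%s, %s]\n",
              format(f$coefficients["slope"], digits = digits), lv,
              format(f$slope_ci["lower"], digits = digits),
              format(f$slope_ci["upper"], digits = digits)))
  cat(sprintf("  intercept %s  %s%% CI [%s, %s]\n",
              format(f$coefficients["intercept"], digits = digits), lv,
              format(f$intercept_ci["lower"], digits = digits),
              format(f$intercept_ci["upper"], digits = digits)))
  cat(sprintf("  pairwise slopes used: %d (offset K = %d)\n",
              f$n_pairs_used, f$offset_k))
  cat(if (x$verdict$agrees) "  methods agree (slope CI covers 1, intercept CI covers 0)\n"
      else paste0("  methods disagree: ",
                  paste(x$verdict$reasons, collapse = "; "), "\n"))
  invisible(x)
}

#' Scatter plot of a Passing-Bablok fit
#'
#' @param x a [pb_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pb_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "standard method", ylab = "comparison method",
                 ...)
  graphics::abline(a = x$coefficients["intercept"], b = x$coefficients["slope"],
                   col = "blue")
  graphics::abline(a = 0, b = 1, lty = 2, col = "red")
  invisible(x)
}
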