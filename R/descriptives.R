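# Robust descriptive statistics for non-Gaussian laboratory panels:
# percentiles, quantile deviation, quartile coefficient of dispersion,
# moment-based shape, bootstrap confidence intervals, and the full
# per-mineral summary row.

#' Empirical percentiles
#'
#' Linear interpolation between closest order statistics (the common
#' "type 7" convention of [stats::quantile()]).
#'
#' @param values non-empty numeric vector.
#' @param probs probabilities in \[0, 1\].
#' @return Quantiles, monotone in `probs`.
#' @export
percentiles <- function(values, probs) {
  if (length(values) == 0L) panel_error("empty input", "data_error")
  if (any(probs < 0 | probs > 1)) panel_error("probs outside [0,1]", "data_error")
  unname(stats::quantile(values, probs, type = 7, names = FALSE))
}

#' Quartile coefficient of dispersion
#'
#' QCD = (Q3 - Q1)/(Q3 + Q1), a unit-free robust measure of relative
#' variability suited to skewed laboratory distributions.
#'
#' @param q1,q3 first and third quartiles, `q1 <= q3`, `q1 + q3 > 0`.
#' @return Dimensionless QCD.
#' @export
qcd <- function(q1, q3) {
  if (any(q1 > q3)) panel_error("q1 must not exceed q3", "data_error")
  if (any(q1 + q3 <= 0))
    panel_error("QCD undefined when q1 + q3 <= 0", "undefined_statistic")
  (q3 - q1) / (q3 + q1)
}

#' Quantile deviation
#'
#' QD = (Q3 - Q1)/2, a robust absolute variability measure in the unit of
#' measurement.
#'
#' @param q1,q3 first and third quartiles, `q1 <= q3`.
#' @return QD in the unit of the data.
#' @export
quantile_deviation <- function(q1, q3) {
  if (any(q1 > q3)) panel_error("q1 must not exceed q3", "data_error")
  (q3 - q1) / 2
}

#' Moment-based shape of a sample
#'
#' Fisher skewness \eqn{g_1 = m_3 / m_2^{3/2}} and excess kurtosis
#' \eqn{g_2 = m_4 / m_2^2 - 3} from central sample moments (no bias
#' adjustment); a Gaussian sample gives values near (0, 0).
#'
#' @param values numeric vector, n >= 3 with nonzero variance.
#' @return List with `skewness` and `excess_kurtosis`.
#' @export
moment_shape <- function(values) {
  n <- length(values)
  if (n < 3L) panel_error("need at least 3 values", "data_error")
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0)
    panel_error("zero variance: shape undefined", "undefined_statistic")
  list(skewness = mean(d^3) / m2^1.5,
       excess_kurtosis = mean(d^4) / m2^2 - 3)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap: `B` resamples with replacement, percentile
#' interval of the statistic. If the statistic errors on a resample (for
#' example an undefined QCD) the resample is redrawn, up to 100 attempts.
#'
#' @param values non-empty numeric vector to resample.
#' @param statistic function of a numeric vector returning a scalar.
#' @param B number of resamples (>= 200).
#' @param seed integer seed; the global RNG state is left untouched.
#' @param level confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, statistic, B = 2000, seed, level = 0.95) {
  if (length(values) == 0L) panel_error("empty input", "data_error")
  if (B < 200) panel_error("B must be at least 200", "config_error")
  if (missing(seed)) panel_error("seed is mandatory", "config_error")
  n <- length(values)
  stats_out <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in 1:100) {
        v <- values[sample.int(n, n, replace = TRUE)]
        out <- tryCatch(statistic(v), error = function(e) NULL)
        if (!is.null(out) && is.finite(out)) return(out)
      }
      panel_error("statistic undefined on 100 consecutive resamples",
                  "undefined_statistic")
    }, numeric(1))
  })
  alpha <- 1 - level
  ci <- percentiles(stats_out, c(alpha / 2, 1 - alpha / 2))
  c(lower = ci[1], upper = ci[2])
}

#' Summarise one measurement channel of a panel
#'
#' Produces the full descriptive row used for non-Gaussian serum panels:
#' extremes, 5th/25th/50th/75th/95th percentiles, quantile deviation, QCD
#' with bootstrap CI, mean/SD/CV (CV with bootstrap CI), moment-based
#' skewness and excess kurtosis, and the percentages of subjects below and
#' above the reference interval.
#'
#' @param panel a [paired_panel()].
#' @param channel `"standard"` or `"icpms"`.
#' @param B bootstrap resamples for the QCD and CV intervals.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level.
#' @return An object of class `"mineral_summary"` (a list of the fields
#'   above plus `mineral`, `unit`, `n`).
#' @export
summarize_channel <- function(panel, channel = c("standard", "icpms"),
                              B = 2000, seed, level = 0.95) {
  stopifnot(inherits(panel, "paired_panel"))
  channel <- match.arg(channel)
  v <- if (channel == "standard") panel$data$standard_value
       else panel$data$icpms_value
  n <- length(v)
  if (n < 8L) panel_error("need at least 8 observations", "data_error")
  if (missing(seed)) panel_error("seed is mandatory", "config_error")

  q <- percentiles(v, c(0.05, 0.25, 0.50, 0.75, 0.95))
  def <- panel$mineral
  qcd_stat <- function(x) {
    qq <- percentiles(x, c(0.25, 0.75)); qcd(qq[1], qq[2])
  }
  cv_stat <- function(x) stats::sd(x) / mean(x)
  seeds <- with_seed(seed, sample.int(2^30, 2))
  structure(
    list(mineral = def$name, unit = def$unit, channel = channel, n = n,
         min = min(v), p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
         p95 = q[5], max = max(v),
         qd = quantile_deviation(q[2], q[4]),
         qcd = qcd(q[2], q[4]),
         qcd_ci = bootstrap_ci(v, qcd_stat, B, seeds[1], level),
         mean = mean(v), sd = stats::sd(v),
         cv = cv_stat(v),
         cv_ci = bootstrap_ci(v, cv_stat, B, seeds[2], level),
         skewness = moment_shape(v)$skewness,
         excess_kurtosis = moment_shape(v)$excess_kurtosis,
         pct_below_llr = 100 * sum(v < def$ri_low) / n,
         pct_above_ulr = 100 * sum(v > def$ri_high) / n),
    class = "mineral_summary")
}

#' @export
print.mineral_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<mineral_summary> %s [%s] (%s channel), n = %d\n",
              x$mineral, x$unit, x$channel, x$n))
  cat(sprintf("  median %s (IQR %s-%s)  QD %s  QCD %s [%s, %s]\n",
              format(x$p50, digits = digits), format(x$p25, digits = digits),
              format(x$p75, digits = digits), format(x$qd, digits = digits),
              format(x$qcd, digits = digits),
              format(x$qcd_ci["lower"], digits = digits),
              format(x$qcd_ci["upper"], digits = digits)))
  cat(sprintf("  skewness %s  excess kurtosis %s  below/above RI %s%% / %s%%\n",
              format(x$skewness, digits = digits),
              format(x$excess_kurtosis, digits = digits),
              format(x$pct_below_llr, digits = digits),
              format(x$pct_above_ulr, digits = digits)))
  invisible(x)
}

# flat one-row data.frame used by the CSV export (Table-style column order)
summary_row <- function(s) {
  data.frame(mineral = s$mineral, unit = s$unit, channel = s$channel,
             n = s$n, min = s$min, p5 = s$p5, p25 = s$p25, p50 = s$p50,
             p75 = s$p75, p95 = s$p95, max = s$max, qd = s$qd, qcd = s$qcd,
             qcd_lower = unname(s$qcd_ci["lower"]),
             qcd_upper = unname(s$qcd_ci["upper"]),
             mean = s$mean, sd = s$sd, cv = s$cv,
             cv_lower = unname(s$cv_ci["lower"]),
             cv_upper = unname(s$cv_ci["upper"]),
             skewness = s$skewness, excess_kurtosis = s$excess_kurtosis,
             pct_below_llr = s$pct_below_llr,
             pct_above_ulr = s$pct_above_ulr,
             stringsAsFactors = FALSE)
}
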