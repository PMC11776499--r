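---
title: "Method comparison for serum mineral panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method comparison for serum mineral panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumpanel)
```

## The problem

A routine clinical laboratory reports serum Na and K from ion-selective
electrodes, Ca, P and Mg from enzymatic assays, and Fe, Zn and Cu from
colorimetric chemistry — one analyte per channel, each with its own
reference interval and reporting precision. ICP-MS measures the whole
eight-element panel at once. Whether ICP-MS values can be read against the
routine assays' reference intervals is a method-comparison question, and
serum minerals make it statistically awkward in three ways:

1. **Non-Gaussian, tightly regulated distributions.** Sodium varies by a
   couple of percent across healthy subjects; iron varies severalfold and
   is right-skewed. Parametric regression and Gaussian summaries mislead
   at both extremes, so the package leans on quartile-based dispersion
   (QD, QCD), rank correlation, and the nonparametric Passing–Bablok fit.
2. **Structurally different analytes.** The routine phosphorus assay
   measures inorganic phosphate; ICP-MS measures total phosphorus,
   roughly 3.5 times higher since about 70% of circulating phosphorus is
   organic. The comparison is still informative, but its "bias" is a
   fraction difference, not an instrument error.
3. **Identifiable interference.** Hemolysis releases erythrocyte contents
   — dramatically iron, occasionally potassium — into serum, inflating the
   ICP-MS channel; sporadic contamination (e.g. from zinc-bearing
   consumables) does the same for zinc. These are known causes, so the
   pipeline excludes visually hemolyzed sera *before* statistical outlier
   screening rather than letting them masquerade as method disagreement.

## The regression model

`pb_fit()` implements the classical Passing–Bablok structural regression:
both channels carry measurement error, no error distribution is assumed,
and up to ~30% of aberrant pairs cannot break the estimate. With pairwise
slopes $S_{ij} = (y_j - y_i)/(x_j - x_i)$ over all $i<j$:

* pairs identical in both coordinates are dropped; slopes exactly $-1$
  are excluded; ties in $x$ with unequal $y$ contribute signed infinities
  kept at the ends of the ordering (ties are common here because the
  standard channel is rounded to 0 or 1 decimals, giving the scatter its
  discrete look);
* the slope is the median of the sorted multiset *shifted by*
  $K = \#\{S_{ij} < -1\}$, which removes the small-sample bias toward 0
  for positive relationships (even counts average the two central
  values);
* the slope CI takes order statistics at $M_1 = \mathrm{round}((N-C)/2)$
  and $M_2 = N - M_1 + 1$, both shifted by $K$, with
  $C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}$. The normal approximation is
  used at every $n$ (the intended use is cohort-sized panels, $n \approx
  282$; exact small-sample tables are not implemented). $M_1$ rounds half
  away from zero.
* the intercept is $\mathrm{median}(y_i - b x_i)$; its CI bounds reuse the
  *opposite* slope bounds, $\mathrm{median}(y_i - b_{hi} x_i)$ to
  $\mathrm{median}(y_i - b_{lo} x_i)$.

Two algebraic cautions verified by the test suite: the $-1$ exclusion and
the $K$ offset are not scale invariant, so exact scale equivariance (and
the slope-inversion symmetry under swapping axes) holds only when every
pairwise slope lies on one side of $-1$ — comfortably true for positive
concentration scatters, not for arbitrary data. Standardized residuals are
mean-centred and scaled by the sample SD ($n-1$); with zero residual
variance they are defined as 0. Mean-centring is a deliberate choice — a
raw-residual scaling would shift all z-scores when the intercept is
slightly off — and the $|z|>3$ screen is two-sided, since underestimation
outliers occur as well.

## The agreement pipeline

`run_agreement()` mirrors standard practice:

* regression and correlations are computed on **all** data, outliers
  included (robust fits tolerate them, and excluding data a priori biases
  the comparison);
* outlier screening excludes hemolyzed sera, fits once on the remainder,
  flags $|z| > 3$, and never refits — a single filtering pass. Iterative
  refitting would progressively tighten the SD and manufacture outliers;
* Bland–Altman statistics use the **relative** error
  $100(\mathrm{ICPMS}-\mathrm{std})/\mathrm{std}$ because analytical error
  for these assays is concentration-proportional; limits of agreement are
  mean $\pm 1.96 \cdot$ SD, reported before and after filtering;
* bootstrap CIs (percentile, $B = 2000$ by default, explicit seed
  required) resample subjects, recomputing mean and SD jointly for the
  limits. The correlation strength category (very strong ≥ 0.9, strong
  ≥ 0.7, moderate ≥ 0.4, weak ≥ 0.1) is read from the *lower bound* of
  the Spearman CI, so a category is a claim the data support at the
  confidence level rather than a point-estimate label.
* phosphorus runs through the identical code path; its ~250% mean
  relative error is a finding, not an error state.

A known limitation, documented rather than patched: when several strong
outliers land in one panel they inflate the common residual SD, and a mild
outlier (zinc contamination below about twofold) can fall under the
$|z| = 3$ line — the classical masking weakness of single-pass residual
screens. The tests pin the behaviour: at-least-twofold contamination is
always flagged; milder multipliers almost always (aggregate recall ≈ 0.96
across seeds at $n = 282$). Robust alternatives (MAD-based scaling,
iterated screening) were deliberately not substituted, to keep the
screening rule exactly the conventional one.

## ROC screening

`screen_condition()` asks a deployment question: using ICP-MS alone, can
you find the subjects the routine assay would call deficient (below the
reference interval) or in surplus (above it)? Labels come only from the
standard channel, the predictor only from ICP-MS; the empirical ROC sweeps
all distinct predictor values; AUC is the Mann–Whitney statistic (ties
half-weighted), identical to the trapezoidal area. The Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$ picks the cutoff; ties break
toward higher sensitivity (a screening test prefers not to miss cases),
then toward the point closest to (0, 1). For deficiency the predictor is
negated internally so the reported cutoff stays in concentration units
with "≤ cutoff ⇒ positive" semantics. Bootstrap CIs are stratified
(resampling within cases and controls separately) so low-prevalence
conditions never produce single-class resamples; point estimates are
computed once on the full data and are not resampled. Conditions with
fewer than 10 cases are refused as ineligible rather than reported with
unstable CIs.

## What the synthetic generator emulates — and what it does not

No cohort data ship with the package, so `simulate_panels()` generates
panels with the structure the analysis assumes. Per mineral, a true
concentration $T$ is drawn — lognormal for Fe and Zn (right-skewed),
normal truncated at 0 for the rest — with medians and spreads calibrated
to a screening cohort's quartiles (normal sd $= \mathrm{IQR}/(2 \Phi^{-1}(0.75))$,
lognormal $\sigma = \log(Q_3/Q_1)/(2\Phi^{-1}(0.75))$):
Na 141 (140–142) mmol/L, K 4.3 (4.1–4.5), Ca 9.6 (9.4–9.8) mg/dL,
inorganic P 3.5 (3.2–3.8), Mg 2.1 (2.0–2.1), Fe 100 (77–121) μg/dL,
Zn 79 (72–89), Cu 92 (83–102). The zinc median sitting just under its
80 μg/dL lower reference limit reproduces the striking ~52% deficiency
prevalence such cohorts show.

The standard channel is $T(1+\varepsilon)$, $\varepsilon \sim N(0, 0.01)$,
rounded half-away-from-zero to the assay's reporting precision (0 decimals
for Na/Fe/Zn/Cu, 1 for K/Ca/P/Mg) — the rounding is what produces the
discrete scatter and x-ties the regression must tolerate. The ICP-MS
channel is $\beta T (1+\varepsilon')$, $\varepsilon' \sim N(0, 0.03)$,
with proportional biases matching observed headline figures:
$\beta = 0.97$ for Na/K/Ca/Mg, $1.05$ for Fe, $1.00$ for Zn, $0.81$ for
Cu. For phosphorus the ICP-MS channel carries total phosphorus,
$3.5\,T(1+\eta)$ with $\eta \sim N(0, 0.12)$ — the 3.5 is the measured
total/inorganic ratio (the physiology remark that inorganic phosphate is
~30% of the total would give 3.3; the measured ratio was preferred as the
calibration target). Hemolysis strikes each subject with probability
6/282, adding U(50, 300) μg/dL to ICP-MS iron and, with probability 1/6,
U(0.5, 1.5) mmol/L to potassium; zinc contamination hits 1.5% of subjects
with a U(1.5, 3) multiplier. Spike magnitudes are set so that planted
outliers are (nearly always, see above) detectable at the default noise,
while remaining physiologically plausible for mild hemolysis. Everything
is driven by one seed and provenance tags record the ground truth, so
recall of the screening rules is testable.

What the generator does **not** emulate: instrument drift, isobaric
interference, carry-over, calibration-curve chemistry, correlated
biological structure across minerals (each element is drawn
independently), severity differences between hemolysis events, or
non-hemolytic iron outliers. Passing tests therefore demonstrate that the
statistical machinery recovers known structure of this kind — not that
real paired panels contain no other pathology.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation of order statistics
  (`stats::quantile` type 7) throughout; published QCD/QD worked examples
  are phrased on printed quartiles, so the estimator choice does not
  affect them.
* Skewness/kurtosis are the moment estimators $g_1, g_2$ (no bias
  adjustment).
* Reporting rounding is half-away-from-zero, the clinical convention
  (base R's `round` would report 99.5 μg/dL as 100 either way, but 100.5
  as 100).
* Reference-interval flagging treats boundary values as within (the
  deficiency/surplus definitions are strict inequalities).
* Bootstrap resamples on which a statistic is undefined (e.g. QCD with a
  zero denominator) are redrawn, up to 100 attempts, then error.
* Degenerate regressions (no dispersion in the standard channel — a real
  hazard for sodium, whose biological range spans a handful of reporting
  units) raise a classed `regression_error`; `run_agreement()` and the
  command-line `compare` record the failure and carry on with the other
  minerals.
* All randomized routines take an explicit seed and restore the caller's
  RNG state; identical inputs give byte-identical reports (no timestamps
  in serialized output).

## Problem sizes in the test suite

The suite exercises calibration at $n = 1000$ (generator medians within
2%), interval calibration with 500 replicates at $n = 282$ (the slope CI
covers the generating slope at 94–95%), Bland–Altman coverage at
$n = 5000$ (95% ± 1% of points inside the limits), and exhaustive-oracle
equivalence on 200 small instances ($n \le 12$) for the regression and 60
($n \le 50$) for the AUC. These sizes give stable checks in seconds on a
laptop while matching the cohort scale the pipeline targets.
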