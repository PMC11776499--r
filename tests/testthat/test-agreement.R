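test_that("relative error is the percentage difference and inverts exactly", {
  expect_equal(relative_error(100, 95), -5.0)
  expect_equal(relative_error(7.3, 7.3), 0)
  expect_equal(relative_error(3.5, 11.8), 100 * (11.8 - 3.5) / 3.5)
  std <- runif(50, 1, 200); icp <- runif(50, 1, 200)
  re <- relative_error(std, icp)
  expect_equal(std * (1 + re / 100), icp)
  expect_error(relative_error(0, 5), class = "undefined_statistic")
  expect_error(relative_error(-2, 5), class = "undefined_statistic")
})

test_that("method mean is the Bland-Altman abscissa", {
  expect_equal(method_mean(100, 95), 97.5)
  expect_equal(method_mean(0, 0), 0)
  expect_equal(method_mean(3.5, 11.8), 7.65)
})

test_that("correlation categories derive from the Spearman CI lower bound", {
  x <- seq_len(40)
  r <- correlate(x, x + 0.001 * x^2, B = 300, seed = 1)
  expect_equal(r$pearson_r, cor(x, x + 0.001 * x^2))
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$strength_category, "very strong")
  # monotone nonlinear: rho stays 1, r drops below it
  y <- exp(seq(0, 5, length.out = 40))
  r2 <- correlate(seq_len(40), y, B = 300, seed = 1)
  expect_equal(r2$spearman_rho, 1)
  expect_lt(r2$pearson_r, 1)
  # independent channels at large n land in negligible
  set.seed(3)
  r3 <- correlate(rnorm(400), rnorm(400), B = 300, seed = 2)
  expect_lt(abs(r3$spearman_rho), 0.15)
  expect_equal(r3$strength_category, "negligible")
  expect_error(correlate(rep(1, 20), rnorm(20), B = 300, seed = 1),
               class = "undefined_statistic")
  # the category rule is monotone in the lower bound
  cats <- vapply(c(-0.2, 0.15, 0.5, 0.8, 0.95),
                 serumpanel:::category_from_lower, "")
  expect_equal(cats, c("negligible", "weak", "moderate", "strong",
                       "very strong"))
})

test_that("outlier screening removes hemolyzed first, then flags |z| > 3 once", {
  def <- default_minerals()$Zn
  clean <- paired_panel(def, sprintf("s%02d", 1:20), 70 + (1:20), 70 + (1:20))
  o <- detect_outliers(clean)
  expect_identical(o$hemolyzed_ids, character(0))
  expect_identical(o$residual_outlier_ids, character(0))

  # at least twofold contamination always stands clear of the residual
  # noise; milder multipliers can be masked when several outliers inflate
  # the residual SD together, so the universal claim is on the strong ones
  n_strong <- 0
  for (seed in c(77, 78, 79)) {
    panels <- simulate_panels(default_panel_config(n = 400, seed = seed))
    d <- panels$Zn$data
    oz <- detect_outliers(panels$Zn)
    strong <- d$subject_id[d$provenance == "contamination" & !d$hemolyzed &
                             d$icpms_value / d$standard_value >= 2]
    n_strong <- n_strong + length(strong)
    expect_true(all(strong %in% oz$residual_outlier_ids))
    # hemolyzed never reappear in the residual set
    of <- detect_outliers(panels$Fe)
    expect_length(intersect(of$hemolyzed_ids, of$residual_outlier_ids), 0)
    expect_false(any(of$hemolyzed_ids %in% names(of$z_scores)))
  }
  expect_gt(n_strong, 0)
})

test_that("Bland-Altman statistics honour the 1.96 limits-of-agreement rule", {
  def <- default_minerals()$Cu
  ids <- sprintf("s%02d", 1:12)
  same <- paired_panel(def, ids, 90 + (1:12), 90 + (1:12))
  ba <- bland_altman(same, B = 300, seed = 1)
  expect_equal(ba$mean_re, 0)
  expect_equal(ba$sd_re, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)

  prop <- paired_panel(def, ids, 90 + (1:12), 0.9 * (90 + (1:12)))
  ba <- bland_altman(prop, B = 300, seed = 1)
  expect_equal(ba$mean_re, -10)
  expect_equal(ba$sd_re, 0)

  expect_error(bland_altman(same, exclude = ids[1:6], B = 300, seed = 1),
               class = "data_error")
  expect_identical(bland_altman(prop, B = 300, seed = 9),
                   bland_altman(prop, B = 300, seed = 9))
})

test_that("limits of agreement contain about 95% of Gaussian relative errors", {
  def <- default_minerals()$Cu
  n <- 5000
  set.seed(6)
  std <- rep(100, n)
  icp <- std * (1 + rnorm(n, 0, 0.05))
  p <- paired_panel(def, sprintf("s%05d", 1:n), std, icp)
  ba <- bland_altman(p, B = 300, seed = 2)
  inside <- mean(ba$re >= ba$loa_lower & ba$re <= ba$loa_upper)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
})

test_that("the full agreement pipeline is deterministic and coherent", {
  panels <- simulate_panels(default_panel_config(n = 282, seed = 1))
  r1 <- run_agreement(panels$Zn, B = 300, seed = 4)
  r2 <- run_agreement(panels$Zn, B = 300, seed = 4)
  expect_identical(r1, r2)
  # bookkeeping: post n = pre n - hemolyzed - residual outliers
  expect_equal(r1$ba_post$n_used,
               r1$ba_pre$n_used - length(r1$outliers$hemolyzed_ids) -
                 length(r1$outliers$residual_outlier_ids))
  # removing |z|>3 points cannot widen the relative-error spread here
  expect_lte(r1$ba_post$sd_re, r1$ba_pre$sd_re)
  # planted outliers make the iron and zinc limits narrower after filtering
  for (nm in c("Fe", "Zn")) {
    r <- run_agreement(panels[[nm]], B = 300, seed = 4)
    width <- function(ba) ba$loa_upper - ba$loa_lower
    expect_lt(width(r$ba_post), width(r$ba_pre))
  }
})

test_that("a noise-free identity panel yields agreement with nothing flagged", {
  def <- default_minerals()$Mg
  v <- seq(1.8, 2.5, length.out = 15)
  p <- paired_panel(def, sprintf("s%02d", 1:15), v, v)
  r <- run_agreement(p, B = 300, seed = 1)
  expect_true(r$verdict$agrees)
  expect_equal(r$ba_post$mean_re, 0)
  expect_length(r$outliers$residual_outlier_ids, 0)
})

test_that("phosphorus flows through the same pipeline with its large bias", {
  panels <- simulate_panels(default_panel_config(n = 282, seed = 1))
  r <- run_agreement(panels$P, B = 300, seed = 4)
  expect_gt(r$ba_post$mean_re, 200)   # total vs inorganic phosphorus
  expect_false(r$verdict$agrees)
})
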