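test_that("condition labels read only the standard channel against the RI", {
  zn <- default_minerals()$Zn
  k <- default_minerals()$K
  expect_equal(label_condition(c(75, 85), zn, "deficiency"), c(1L, 0L))
  expect_equal(label_condition(c(90, 100, 120), zn, "deficiency"), c(0L, 0L, 0L))
  expect_equal(label_condition(4.9, k, "surplus"), 1L)
  expect_equal(label_condition(4.8, k, "surplus"), 0L)   # boundary is within
})

test_that("eligibility needs the minimum positive count", {
  expect_false(check_eligibility(c(rep(1, 9), rep(0, 50)))$eligible)
  expect_true(check_eligibility(c(rep(1, 135), rep(0, 147)))$eligible)
  expect_false(check_eligibility(rep(0, 40))$eligible)
  expect_equal(check_eligibility(c(1, 1, 0))$n_positive, 2)
})

test_that("the empirical ROC curve is anchored and monotone", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    pred <- round(runif(n, 0, 10), sample(0:2, 1))
    dir <- sample(c("higher", "lower"), 1)
    cur <- roc_curve(labels, pred, dir)
    expect_equal(cur$fpr[1], 0); expect_equal(cur$tpr[1], 0)
    expect_equal(cur$fpr[nrow(cur)], 1); expect_equal(cur$tpr[nrow(cur)], 1)
    expect_false(is.unsorted(cur$fpr)); expect_false(is.unsorted(cur$tpr))
  }
  # perfect separation passes through (0, 1)
  cur <- roc_curve(c(1, 1, 0, 0), c(9, 8, 2, 1), "higher")
  expect_true(any(cur$fpr == 0 & cur$tpr == 1))
  expect_error(roc_curve(rep(1, 5), 1:5), class = "data_error")
})

test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 2, 3, 1), "higher"), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(9, 8, 2, 1), "higher"), 1.0)
  # constant predictor: every pair ties -> 0.5
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(3, 4), "higher"), 0.5)
  # label flip complements
  l <- c(1, 1, 0, 0, 1); p <- c(4, 2, 3, 1, 5)
  expect_equal(roc_auc(1 - l, p, "higher"), 1 - roc_auc(l, p, "higher"))
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    pred <- round(runif(n, 0, 10), sample(0:1, 1))
    expect_equal(roc_auc(labels, pred, "higher"), oracle_auc(labels, pred))
    expect_equal(roc_auc(labels, pred, "lower"), oracle_auc(labels, -pred))
    # trapezoid under the empirical curve agrees too
    cur <- roc_curve(labels, pred, "higher")
    trap <- sum(diff(cur$fpr) * (head(cur$tpr, -1) + tail(cur$tpr, -1)) / 2)
    expect_equal(trap, oracle_auc(labels, pred))
  }
})

test_that("AUC agrees with pROC on a nontrivial instance", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- rbinom(80, 1, 0.4)
  labels[1:2] <- c(0, 1)
  pred <- rnorm(80) + labels
  expect_equal(roc_auc(labels, pred, "higher"),
               as.numeric(pROC::auc(pROC::roc(labels, pred, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the Youden cutoff maximizes J with the stated tie-breaks", {
  cur <- roc_curve(c(1, 1, 0, 0), c(9, 8, 2, 1), "higher")
  y <- youden_cutoff(cur)
  expect_equal(y$youden_j, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  # constant predictor: diagonal curve, J = 0, first threshold by tie rule
  cur <- roc_curve(c(1, 0, 1, 0), rep(3, 4), "higher")
  y <- youden_cutoff(cur)
  expect_equal(y$youden_j, 0)
  expect_equal(y$sensitivity, 1)   # higher sensitivity wins the tie
  # 4-point example: enumerate thresholds by hand
  cur <- roc_curve(c(1, 1, 0, 0), c(4, 2, 3, 1), "higher")
  js <- cur$sens + cur$spec - 1
  y <- youden_cutoff(cur)
  expect_equal(y$youden_j, max(js))
  # J = 0.5 at thresholds 4 (sens .5, spec 1) and 2 (sens 1, spec .5);
  # the higher-sensitivity tie-break picks 2
  expect_equal(y$cutoff, 2)
  expect_equal(y$sensitivity, 1)
})

test_that("screening returns calibrated results on the synthetic zinc panel", {
  panels <- simulate_panels(default_panel_config(n = 282, seed = 1))
  s <- screen_condition(panels$Zn, "deficiency", B = 300, seed = 5)
  expect_s3_class(s, "screening_result")
  expect_gte(s$auc, 0.9)
  expect_equal(s$direction, "lower-is-positive")
  expect_gte(s$n_positive, 10)
  expect_true(all(s$roc_points$fpr >= 0 & s$roc_points$tpr <= 1))
  # labels from the standard channel only: perturbing ICP-MS leaves labels
  # unchanged, perturbing the standard channel leaves the predictor ranking
  p2 <- panels$Zn
  p2$data$icpms_value <- p2$data$icpms_value + 1000
  s2 <- screen_condition(p2, "deficiency", B = 300, seed = 5)
  expect_equal(s2$n_positive, s$n_positive)
  # cutoff is reported in concentration units within the observed range
  expect_gte(s$cutoff, min(panels$Zn$data$icpms_value))
  expect_lte(s$cutoff, max(panels$Zn$data$icpms_value))
})

test_that("seed changes move only the bootstrap intervals", {
  panels <- simulate_panels(default_panel_config(n = 282, seed = 1))
  a <- screen_condition(panels$Zn, "deficiency", B = 300, seed = 5)
  b <- screen_condition(panels$Zn, "deficiency", B = 300, seed = 6)
  expect_identical(a$auc, b$auc)
  expect_identical(a$cutoff, b$cutoff)
  expect_identical(a$sensitivity, b$sensitivity)
  expect_false(identical(a$auc_ci, b$auc_ci))
})

test_that("ineligible conditions raise a named eligibility error", {
  def <- default_minerals()$Zn
  v <- c(75, 76, 78, seq(90, 120, length.out = 17))
  p <- paired_panel(def, sprintf("s%02d", 1:20), v, v)
  err <- tryCatch(screen_condition(p, "deficiency", B = 300, seed = 1),
                  eligibility_error = function(e) e)
  expect_s3_class(err, "eligibility_error")
  expect_match(conditionMessage(err), "3 cases")
  # perfect separation gives a degenerate AUC interval at 1
  sep <- paired_panel(def, sprintf("s%02d", 1:30),
                      c(rep(75, 12), rep(100, 18)),
                      c(seq(40, 62, length.out = 12),
                        seq(90, 120, length.out = 18)))
  s <- screen_condition(sep, "deficiency", B = 300, seed = 2)
  expect_equal(unname(s$auc_ci), c(1, 1))
  expect_equal(s$auc, 1)
})
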