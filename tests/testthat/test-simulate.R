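test_that("default config carries the calibrated panel conditions", {
  cfg <- default_panel_config(n = 282, seed = 1)
  expect_equal(cfg$conc$Na$median, 141)
  expect_equal(cfg$conc$P$median, 3.5)
  expect_equal(cfg$hemolysis$rate, 6 / 282)
  expect_equal(cfg$bias$Cu$beta, 0.81)
  expect_equal(cfg$bias$Fe$beta, 1.05)
  expect_equal(cfg$phosphorus$total_factor, 3.5)
  expect_equal(default_panel_config(n = 10, seed = 7)$n, 10L)
  expect_error(default_panel_config(n = 9, seed = 1), class = "config_error")
})

test_that("identical configs generate identical panels, different seeds differ", {
  a <- simulate_panels(default_panel_config(n = 40, seed = 123))
  b <- simulate_panels(default_panel_config(n = 40, seed = 123))
  c <- simulate_panels(default_panel_config(n = 40, seed = 124))
  expect_identical(a, b)
  expect_false(identical(a$Na$data$standard_value, c$Na$data$standard_value))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(simulate_panels(default_panel_config(n = 20, seed = 9)))
  expect_identical(runif(3), before)
})

noise_free_config <- function(n, seed) {
  minerals <- default_minerals()
  conc <- default_panel_config(n = n, seed = seed)$conc
  bias <- lapply(minerals, function(m) bias_model(0, 1, 0, 0))
  generator_config(n, seed, minerals, conc, bias,
                   phosphorus = list(total_factor = 3.5, fraction_noise_sd = 0),
                   round_standard = FALSE)
}

test_that("noise-free identity config makes the channels equal off phosphorus", {
  p <- simulate_panels(noise_free_config(30, 11))
  for (nm in setdiff(names(p), "P"))
    expect_equal(p[[nm]]$data$icpms_value, p[[nm]]$data$standard_value)
  expect_equal(p$P$data$icpms_value, 3.5 * p$P$data$standard_value)
})

test_that("standard-channel medians calibrate to the panel targets at n=1000", {
  targets <- c(Na = 141, K = 4.3, Ca = 9.6, P = 3.5, Mg = 2.1,
               Fe = 100, Zn = 79, Cu = 92)
  p <- simulate_panels(default_panel_config(n = 1000, seed = 31))
  for (nm in names(targets)) {
    med <- median(p[[nm]]$data$standard_value)
    # within 2%; integer reporting makes the iron median move in 1% steps
    expect_lte(abs(med - targets[[nm]]) / targets[[nm]], 0.02)
  }
})

test_that("iron and zinc channels are right-skewed", {
  p <- simulate_panels(default_panel_config(n = 1000, seed = 17))
  expect_gt(moment_shape(p$Fe$data$icpms_value)$skewness, 0)
  expect_gt(moment_shape(p$Fe$data$standard_value)$skewness, 0)
  expect_gt(moment_shape(p$Zn$data$standard_value)$skewness, 0)
})

test_that("hemolysis frequency stays in the binomial range of its rate", {
  # 95% binomial bounds for n=282, p=6/282: qbinom gives [2, 11] successes
  lo <- qbinom(0.025, 282, 6 / 282)
  hi <- qbinom(0.975, 282, 6 / 282)
  p <- simulate_panels(default_panel_config(n = 282, seed = 1))
  h <- sum(p$Fe$data$hemolyzed)
  expect_gte(h, lo)
  expect_lte(h, hi)
  # the flag is identical across the panel's minerals
  expect_identical(p$Fe$data$hemolyzed, p$Na$data$hemolyzed)
})

test_that("planted provenance is recoverable for recall bookkeeping", {
  p <- simulate_panels(default_panel_config(n = 600, seed = 8))
  hem <- p$Fe$data$subject_id[p$Fe$data$hemolyzed]
  expect_true(all(p$Fe$data$provenance[p$Fe$data$hemolyzed] %in%
                    c("hemolysis", "contamination")))
  contam <- p$Zn$data$subject_id[p$Zn$data$provenance == "contamination"]
  expect_gt(length(hem), 0)
  expect_gt(length(contam), 0)
  # hemolyzed iron really is spiked upward relative to the bias line
  clean <- !p$Fe$data$hemolyzed
  re_clean <- p$Fe$data$icpms_value[clean] / p$Fe$data$standard_value[clean]
  re_hem <- p$Fe$data$icpms_value[!clean] / p$Fe$data$standard_value[!clean]
  expect_gt(min(re_hem), max(re_clean))
})

test_that("generator config round-trips through JSON to identical panels", {
  cfg <- default_panel_config(n = 25, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_config_json(cfg, path)
  cfg2 <- read_config_json(path)
  expect_identical(simulate_panels(cfg), simulate_panels(cfg2))
})

test_that("generator config validation rejects broken inputs", {
  m <- default_minerals()
  cfg <- default_panel_config(n = 20, seed = 1)
  expect_error(generator_config(20, 1, m, cfg$conc, cfg$bias,
                                hemolysis = list(rate = 1.2, fe_spike = c(0, 0),
                                                 k_spike = c(0, 0),
                                                 k_spike_prob = 0)),
               class = "config_error")
  expect_error(generator_config(20, 1, m, cfg$conc[-1], cfg$bias),
               class = "config_error")
  expect_error(conc_model("normal", -5, 1), class = "config_error")
  expect_error(bias_model(beta = 0), class = "config_error")
})
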