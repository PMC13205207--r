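test_that("default parameter set carries the published base-case inputs", {
  p <- base_params()
  expect_equal(p$whtr_positivity, 0.226)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$horizon_years, 10L)
  expect_equal(p$cohort_size, 100000L)
  expect_equal(unname(p$wtp_thresholds), c(30584.0, 71415.5))

  expect_equal(p$tests$ultrasound$se$mean, 0.52)
  expect_equal(p$tests$ultrasound$sp$mean, 0.96)
  expect_equal(p$tests$fibroscan$se$mean, 0.72)
  expect_equal(p$tests$fibroscan$sp$mean, 0.98)
  expect_equal(p$tests$mri_pdff$se$mean, 0.95)
  expect_equal(p$tests$mri_pdff$sp$mean, 0.92)

  expect_equal(unname(p$initial_stage_distribution),
               c(0.885, 0.052, 0.035, 0.016, 0.012))
  expect_equal(sum(p$initial_stage_distribution), 1, tolerance = 1e-12)

  expect_equal(p$costs$routine_exam, 2.9)
  expect_equal(p$costs$mri_pdff, 87.0)
  expect_equal(p$costs$program_fixed_annual, 10.5)
  expect_equal(p$costs$program_variable_annual, 21.7)

  expect_equal(p$utilities$F0$mean, 0.95)
  expect_equal(p$utilities$F1$mean, p$utilities$F2$mean)
  expect_equal(p$utilities$F4$mean, 0.66)
  expect_equal(p$utilities$F4$ci_low, 0.49)

  expect_equal(p$transitions$boys$F0_F1$mean, 0.004)
  expect_equal(p$transitions$boys$F3_F4$mean, 0.034)
  expect_equal(p$transitions$girls$F1_F2$mean, 0.028)
  expect_equal(p$transitions$regression, 0.06)
  expect_equal(p$transitions$regression_tx, 0.277)
  expect_equal(p$transitions$response_rate, 0.40)
})

test_that("beta_from_ci is a method-of-moments fit with the analytic mean", {
  # independent re-derivation of the closed form for the FibroScan SE row
  m <- 0.72; lo <- 0.64; hi <- 0.79
  sigma <- (hi - lo) / (2 * qnorm(0.975))
  nu <- m * (1 - m) / sigma^2 - 1
  expected <- c(alpha = m * nu, beta = (1 - m) * nu)

  fit <- beta_from_ci(m, lo, hi)
  expect_equal(fit, expected)
  expect_true(all(fit > 0))
  # analytic mean of the fitted Beta recovers the input mean
  expect_equal(unname(fit["alpha"] / sum(fit)), m)
  # and so does numeric integration of the fitted density
  mean_int <- integrate(function(x) x * dbeta(x, fit["alpha"], fit["beta"]),
                        0, 1)$value
  expect_equal(mean_int, m, tolerance = 1e-6)
})

test_that("degenerate and over-dispersed intervals are rejected as Beta fits", {
  expect_error(beta_from_ci(0.5, 0.5, 0.5), class = "masldcea_fixed_value")
  # interval so wide the implied variance exceeds mean*(1-mean)
  expect_error(beta_from_ci(0.02, 0, 0.9), class = "masldcea_invalid_beta")
  expect_error(beta_from_ci(0.5, 0.6, 0.9))  # mean below ci_low
})

test_that("every default beta-kind input has a valid, well-centred fit", {
  p <- base_params()
  uvs <- list(p$tests$ultrasound$se, p$tests$ultrasound$sp,
              p$tests$fibroscan$se, p$tests$fibroscan$sp,
              p$tests$mri_pdff$se, p$tests$mri_pdff$sp,
              p$utilities$F0, p$utilities$F1, p$utilities$F3, p$utilities$F4,
              p$transitions$boys$F0_F1, p$transitions$boys$F1_F2,
              p$transitions$boys$F3_F4, p$transitions$girls$F0_F1,
              p$transitions$girls$F1_F2, p$transitions$girls$F3_F4)
  set.seed(101)
  for (uv in uvs) {
    fit <- beta_from_ci(uv$mean, uv$ci_low, uv$ci_high)
    expect_true(all(fit > 0))
    draws <- rbeta(1e5, fit[["alpha"]], fit[["beta"]])
    expect_lt(abs(mean(draws) - uv$mean), 0.001)
    qs <- quantile(draws, c(0.025, 0.975))
    expect_lt(qs[[1]], uv$mean)
    expect_gt(qs[[2]], uv$mean)
  }
})

test_that("config loading falls back to defaults and validates overrides", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(as_config_list(load_config(empty)),
               as_config_list(base_params()))

  one <- withr::local_tempfile(fileext = ".yaml")
  writeLines("discount_rate: 0.05", one)
  p <- load_config(one)
  expect_equal(p$discount_rate, 0.05)
  p$discount_rate <- 0.03
  expect_equal(as_config_list(p), as_config_list(base_params()))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("utilities:", "  F0:", "    mean: 1.2"), bad)
  expect_error(load_config(bad), "utilities")

  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_parameter: 3", unk)
  expect_warning(load_config(unk), "unknown config key")

  expect_error(load_config(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("parameter sets round-trip through the YAML config format", {
  p <- base_params()
  p$discount_rate <- 0.041
  p$transitions$boys$F1_F2 <- uncertain_value(0.031, 0.02, 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(p, path)
  p2 <- load_config(path)
  expect_equal(as_config_list(p2), as_config_list(p), tolerance = 1e-12)
})

test_that("drawing from a fixed input returns its point mass", {
  expect_equal(draw_value(uncertain_value(0.06), 5), rep(0.06, 5))
})
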