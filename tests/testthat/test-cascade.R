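test_that("second-stage classification follows the 2x2 decomposition", {
  expect_equal(classify_second_stage(0.3, 1, 1),
               c(tp = 0.3, fn = 0, fp = 0, tn = 0.7))
  # FibroScan performance at 30% prevalence: direct arithmetic
  expect_equal(classify_second_stage(0.3, 0.72, 0.98),
               c(tp = 0.216, fn = 0.084, fp = 0.014, tn = 0.686))
  # disease-free population
  expect_equal(classify_second_stage(0, 0.95, 0.92),
               c(tp = 0, fn = 0, fp = 0.08, tn = 0.92))
  expect_equal(sum(classify_second_stage(0.13, 0.52, 0.96)), 1)
})

test_that("no-screening strategy leaves the cohort unscreened at zero cost", {
  cc <- run_cascade("S4", flat_prev_params(0.08), age = 10)
  expect_equal(unname(cc$arms[c("tp", "fp", "tn", "fn")]), rep(0, 4))
  expect_equal(cc$arms[["whtr_neg_diseased"]], 0.08)
  expect_equal(cc$one_off_cost_per_child, 0)
  expect_equal(cc$responder_fraction, 0)
  expect_equal(sum(cc$arms), 1)
})

test_that("cascade chains conditional prevalence through the second stage", {
  p <- flat_prev_params(0.08)
  cc <- run_cascade("S2", p, age = 10)
  cond <- 0.08 / 0.226                       # 0.3540 among WHtR-positives
  cls <- classify_second_stage(cond, 0.72, 0.98)
  expect_equal(cc$arms[["tp"]], unname(cls[["tp"]]) * 0.226)
  expect_equal(cc$arms[["fn"]], unname(cls[["fn"]]) * 0.226)
  expect_equal(cc$arms[["fp"]], unname(cls[["fp"]]) * 0.226)
  expect_equal(cc$arms[["whtr_neg_diseased"]], 0)   # stage-1 sensitivity 1
  expect_equal(cc$one_off_cost_per_child, 2.9 + 0.226 * (13.0 + 22.5))
  # perfect second stage recovers the full prevalence as TP
  pp <- set_param_value(set_param_value(p, "tests.ultrasound.se", 1),
                        "tests.ultrasound.sp", 1)
  cp <- run_cascade("S1", pp, age = 10)
  expect_equal(cp$arms[["tp"]], 0.08)
  expect_equal(cp$arms[["fn"]] + cp$arms[["fp"]], 0)
})

test_that("arm fractions are conserved and consistent across random inputs", {
  p0 <- base_params()
  set.seed(202)
  for (i in 1:50) {
    prev <- runif(1, 0, 0.15)
    p <- default_parameters(prevalence_by_age = setNames(rep(prev, 9), 6:14))
    p$whtr_positivity <- runif(1, max(prev, 0.16), 0.5)
    p$whtr_stage1_sensitivity <- runif(1, 0.5, 1)
    strat <- sample(c("S1", "S2", "S3", "S4"), 1)
    cc <- run_cascade(strat, p, age = sample(6:14, 1))
    expect_equal(sum(cc$arms), 1, tolerance = 1e-12)
    expect_true(all(cc$arms >= -1e-15))
    expect_equal(cc$arms[["tp"]] + cc$arms[["fn"]] +
                   cc$arms[["whtr_neg_diseased"]], prev)
  }
})

test_that("responder fraction is monotone in test and program performance", {
  p <- flat_prev_params(0.08)
  resp <- function(se) {
    run_cascade("S1", set_param_value(p, "tests.ultrasound.se", se),
                10)$responder_fraction
  }
  ses <- seq(0.3, 1, by = 0.1)
  expect_true(all(diff(vapply(ses, resp, 1)) > 0))

  base <- run_cascade("S1", p, 10)
  rhos <- seq(0, 1, by = 0.25)
  resp_rho <- vapply(rhos, function(r) {
    pr <- p; pr$transitions$response_rate <- r
    run_cascade("S1", pr, 10)$responder_fraction
  }, 1)
  expect_true(all(diff(resp_rho) >= 0))

  fp_at <- function(sp) {
    run_cascade("S1", set_param_value(p, "tests.ultrasound.sp", sp),
                10)$arms[["fp"]]
  }
  expect_true(all(diff(vapply(c(0.8, 0.9, 0.96, 1), fp_at, 1)) < 0))
})

test_that("incompatible stage-1 settings raise a configuration error", {
  p <- flat_prev_params(0.30)   # 0.30 / 0.226 > 1
  expect_error(run_cascade("S2", p, 10), "incompatible")
  expect_error(run_cascade("S2", base_params(), age = 5), "outside the modelled range")
})

test_that("management assignment splits true positives by response", {
  p <- flat_prev_params(0.08)
  cc <- run_cascade("S2", p, 10)
  sl <- assign_management(cc, p)
  expect_equal(sum(sl$fraction), 1)
  expect_equal(sl$fraction[sl$arm == "tp_responder"], cc$arms[["tp"]] * 0.4)

  sl0 <- assign_management(cc, p, response_rate = 0)
  expect_equal(sl0$fraction[sl0$arm == "tp_responder"], 0)
  sl1 <- assign_management(cc, p, response_rate = 1)
  expect_equal(sl1$fraction[sl1$arm == "tp_responder"], cc$arms[["tp"]])
  # diseased slices all start from the initial stage distribution (engine
  # contract); every intervention slice is a responder
  expect_equal(sl$regime[sl$arm == "tp_responder"], "intervention")
  expect_true(all(is.na(sl$regime[!sl$diseased])))
})

test_that("with no responders a screening strategy matches no screening in QALYs", {
  p <- flat_prev_params(0.08)
  p$transitions$response_rate <- 0
  s1 <- run_strategy("S1", p)
  s4 <- run_strategy("S4", p)
  expect_equal(s1$total_qaly, s4$total_qaly)
  expect_gt(s1$total_cost, s4$total_cost)   # screening costs remain
})
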