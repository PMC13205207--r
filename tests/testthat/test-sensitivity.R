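# a flat prevalence profile keeps the sensitivity runs cheap to reason about
sens_params <- function() flat_prev_params(0.08)

test_that("one-way analysis over a zero-width range produces zero swing", {
  p <- sens_params()
  p$tests$fibroscan$sp <- uncertain_value(0.98)   # collapse the interval
  tab <- one_way(p, ids = "tests.fibroscan.sp")
  expect_equal(tab$swing, rep(0, 3))
  expect_equal(tab$icur_low, tab$icur_high)
})

test_that("raising the F1/F2 utility raises the ICUR against no screening", {
  tab <- one_way(sens_params(), ids = "utilities.F1F2")
  s2 <- tab[tab$strategy == "S2", ]
  expect_equal(s2$high, 0.92)
  expect_gt(s2$icur_high, s2$icur_base)   # less to gain when F1/F2 feel better
  expect_lt(s2$icur_low, s2$icur_base)
})

test_that("the ICUR against no screening is nonincreasing in the response rate", {
  p <- sens_params()
  icur_at <- function(rho) {
    sc <- scenario_config(response_rate = rho)
    icur(run_strategy("S2", p, sc), run_strategy("S4", p, sc))$icur
  }
  vals <- vapply(c(0.3, 0.4, 0.7, 1.0), icur_at, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("tornado entries are independent of parameter ordering", {
  p <- sens_params()
  ids <- c("utilities.F4", "tests.fibroscan.se", "costs.fibroscan")
  a <- one_way(p, ids = ids)
  b <- one_way(p, ids = rev(ids))
  a <- a[order(a$param, a$strategy), ]; rownames(a) <- NULL
  b <- b[order(b$param, b$strategy), ]; rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("scenario suite reproduces the expected qualitative shifts", {
  p <- sens_params()
  tab <- run_scenarios(p, list(base = scenario_config(),
                               discount_0 = scenario_config(discount_rate = 0),
                               discount_5 = scenario_config(discount_rate = 0.05),
                               response_100 = scenario_config(response_rate = 1),
                               horizon_1 = scenario_config(horizon = 1)))
  base <- tab[tab$scenario == "base", ]
  d0 <- tab[tab$scenario == "discount_0", ]
  expect_true(all(d0$total_qaly >= base$total_qaly))
  d5 <- tab[tab$scenario == "discount_5", ]
  expect_true(all(d5$total_qaly <= base$total_qaly))

  # full response lowers every screening ICUR
  r100 <- tab[tab$scenario == "response_100" & tab$strategy != "S4", ]
  expect_true(all(r100$icur_vs_ref < base$icur_vs_ref[base$strategy != "S4"]))

  # a 1-year horizon front-loads costs: no strategy is cost-effective
  h1 <- tab[tab$scenario == "horizon_1" & tab$strategy != "S4", ]
  expect_true(all(h1$icur_vs_ref > 71415.5))
  expect_true(all(!h1$ce_wtp1 & !h1$ce_wtp2))
})

test_that("two-way analysis overrides only the named test", {
  p <- sens_params()
  # identity cell: grid at the base-case operating point reproduces the
  # base-case pairwise ICUR
  cell <- two_way(p, "ultrasound", se_grid = 0.52, sp_grid = 0.96,
                  wtp = 30584)
  res <- lapply(c("S1", "S2", "S3", "S4"), function(s) run_strategy(s, p))
  names(res) <- c("S1", "S2", "S3", "S4")
  expect_equal(cell$icur_s2_s1, icur(res$S2, res$S1)$icur)
  expect_equal(cell$icur_s1_s4, icur(res$S1, res$S4)$icur)

  # ICUR(S1 vs S4) falls monotonically in ultrasound sensitivity at fixed sp
  sweep <- two_way(p, "ultrasound", se_grid = c(0.41, 0.52, 0.64, 0.8, 1),
                   sp_grid = 0.96, wtp = 30584)
  expect_true(all(diff(sweep$icur_s1_s4) < 0))
  # the perfect-test corner gives S1 its best ICUR over the sweep
  expect_equal(which.min(sweep$icur_s1_s4), nrow(sweep))
})

test_that("PSA is reproducible and collapses to the base case when degenerate", {
  p <- sens_params()
  a <- run_psa(p, n_iter = 15, seed = 42)
  b <- run_psa(p, n_iter = 15, seed = 42)
  expect_identical(a$results, b$results)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(p, n_iter = 15, seed = 43)
  expect_false(identical(a$results, c2$results))

  pd <- fix_parameters(p)
  deg <- run_psa(pd, n_iter = 5, seed = 1)
  bc <- run_base_case(pd)
  for (s in c("S1", "S2", "S3", "S4")) {
    expect_equal(unname(deg$cost[, s]), rep(bc$results[[s]]$total_cost, 5))
    expect_equal(unname(deg$qaly[, s]), rep(bc$results[[s]]$total_qaly, 5))
  }
})

test_that("acceptability curves are proper probabilities that partition iterations", {
  p <- sens_params()
  psa <- run_psa(p, n_iter = 40, seed = 7)
  cc <- ceac(psa, wtp_grid = seq(0, 100000, by = 10000))
  expect_true(all(cc$p_optimal >= 0 & cc$p_optimal <= 1))
  sums <- as.numeric(tapply(cc$p_optimal, cc$wtp, sum))
  expect_equal(sums, rep(1, length(sums)))
  # zero value of health: the zero-cost reference is optimal everywhere
  at0 <- cc[cc$wtp == 0, ]
  expect_equal(at0$p_optimal[at0$strategy == "S4"], 1)
  # very large WTP: the per-iteration QALY maximiser wins
  cc_big <- ceac(psa, wtp_grid = 1e9)
  winner <- colnames(psa$qaly)[apply(psa$qaly, 1, which.max)]
  for (s in unique(winner)) {
    expect_equal(cc_big$p_optimal[cc_big$strategy == s], mean(winner == s))
  }
})
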