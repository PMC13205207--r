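#' Registry of variable parameters for sensitivity analyses
#'
#' Enumerates every model input varied in one-way analysis with its bounds:
#' parameters carrying a printed 95\% interval use the interval endpoints;
#' parameters without an interval use +/-20\% (probabilities capped at 1);
#' the lifestyle-program response rate uses its declared 0.30-1.00 range.
#' Utilities of F1 and F2 come from a single source and are varied jointly
#' as one entry.
#'
#' @param params A `masld_params` parameter set.
#' @return A data.frame with columns `id`, `low`, `high`, `base`.
#' @export
param_registry <- function(params) {
  rows <- list()
  add <- function(id, base, low, high) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, base = base,
                                             low = low, high = high,
                                             stringsAsFactors = FALSE)
  }
  for (tn in names(params$tests)) {
    for (fld in c("se", "sp")) {
      uv <- params$tests[[tn]][[fld]]
      add(paste0("tests.", tn, ".", fld), uv$mean, uv$ci_low, uv$ci_high)
    }
  }
  u <- params$utilities
  add("utilities.F0", u$F0$mean, u$F0$ci_low, u$F0$ci_high)
  add("utilities.F1F2", u$F1$mean, u$F1$ci_low, u$F1$ci_high)
  add("utilities.F3", u$F3$mean, u$F3$ci_low, u$F3$ci_high)
  add("utilities.F4", u$F4$mean, u$F4$ci_low, u$F4$ci_high)
  for (sex in c("boys", "girls")) {
    for (k in names(params$transitions[[sex]])) {
      uv <- params$transitions[[sex]][[k]]
      add(paste0("transitions.", sex, ".", k), uv$mean, uv$ci_low, uv$ci_high)
    }
  }
  pm20 <- function(x, cap1 = FALSE) {
    c(low = 0.8 * x, high = if (cap1) min(1.2 * x, 1) else 1.2 * x)
  }
  b <- pm20(params$whtr_positivity, cap1 = TRUE)
  add("whtr_positivity", params$whtr_positivity, b[["low"]], b[["high"]])
  b <- pm20(params$whtr_stage1_sensitivity, cap1 = TRUE)
  add("whtr_stage1_sensitivity", params$whtr_stage1_sensitivity,
      b[["low"]], b[["high"]])
  b <- pm20(params$transitions$regression, cap1 = TRUE)
  add("transitions.regression", params$transitions$regression,
      b[["low"]], b[["high"]])
  b <- pm20(params$transitions$regression_tx, cap1 = TRUE)
  add("transitions.regression_tx", params$transitions$regression_tx,
      b[["low"]], b[["high"]])
  add("transitions.response_rate", params$transitions$response_rate, 0.30, 1.00)
  for (ck in names(params$costs)) {
    b <- pm20(params$costs[[ck]])
    add(paste0("costs.", ck), params$costs[[ck]], b[["low"]], b[["high"]])
  }
  do.call(rbind, rows)
}

#' Set a registry parameter's point estimate
#'
#' Returns a modified parameter set with the named input's point estimate
#' replaced (uncertain inputs become fixed at the new value; `utilities.F1F2`
#' sets both stages jointly). Structural validity is checked by the engine at
#' run time, not here, so sensitivity bounds that break a structural
#' invariant surface as run-time errors.
#'
#' @param params A `masld_params` parameter set.
#' @param id A registry id from [param_registry()].
#' @param value New point estimate.
#' @return The modified parameter set.
#' @export
set_param_value <- function(params, id, value) {
  if (id == "utilities.F1F2") {
    params$utilities$F1 <- uncertain_value(value)
    params$utilities$F2 <- uncertain_value(value)
    return(params)
  }
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  node <- params
  for (p in parts[-length(parts)]) {
    node <- node[[p]]
    if (is.null(node)) stop(sprintf("unknown parameter id '%s'", id), call. = FALSE)
  }
  leaf <- parts[length(parts)]
  target <- node[[leaf]]
  if (is.null(target)) stop(sprintf("unknown parameter id '%s'", id), call. = FALSE)
  new_leaf <- if (is_uncertain_value(target)) uncertain_value(value) else value
  expr <- paste0("params", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- new_leaf")))
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full pipeline with each registry parameter set to its lower
#' and upper bound in turn, all else held at base case, and records the ICUR
#' of each screening strategy against the no-screening reference. Entries
#' are sorted by ICUR swing (largest first). Bounds that violate a
#' structural invariant are skipped with a warning.
#'
#' @param params A `masld_params` parameter set.
#' @param ids Registry ids to vary (default: all).
#' @param scenario A [scenario_config()].
#' @param cohort Optional pre-generated cohort.
#' @return A data.frame (class `tornado_table`), one row per (parameter,
#'   strategy): `param`, `strategy`, `low`, `high`, `icur_low`, `icur_high`,
#'   `icur_base`, `swing`.
#' @export
one_way <- function(params, ids = NULL, scenario = scenario_config(),
                    cohort = NULL) {
  reg <- param_registry(params)
  if (!is.null(ids)) reg <- reg[reg$id %in% ids, , drop = FALSE]
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                          ages = as.integer(names(params$prevalence_by_age)),
                                          prop_boys = params$prop_boys))
  }
  icurs_vs_ref <- function(p) {
    res <- lapply(all_strategies(), run_strategy, params = p,
                  scenario = scenario, cohort = cohort)
    names(res) <- vapply(res, `[[`, "", "strategy")
    vapply(c("S1", "S2", "S3"),
           function(s) icur(res[[s]], res$S4)$icur, numeric(1))
  }
  base_icur <- icurs_vs_ref(params)
  out <- list()
  for (i in seq_len(nrow(reg))) {
    lo_hi <- lapply(c(reg$low[i], reg$high[i]), function(v) {
      tryCatch(icurs_vs_ref(set_param_value(params, reg$id[i], v)),
               error = function(e) {
                 warning(sprintf("one_way: bound %g of '%s' skipped (%s)",
                                 v, reg$id[i], conditionMessage(e)),
                         call. = FALSE)
                 rep(NA_real_, 3)
               })
    })
    out[[i]] <- data.frame(param = reg$id[i], strategy = c("S1", "S2", "S3"),
                           low = reg$low[i], high = reg$high[i],
                           icur_low = lo_hi[[1]], icur_high = lo_hi[[2]],
                           icur_base = base_icur,
                           swing = abs(lo_hi[[2]] - lo_hi[[1]]),
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-ifelse(is.na(tab$swing), -Inf, tab$swing)), ]
  rownames(tab) <- NULL
  class(tab) <- c("tornado_table", "data.frame")
  tab
}

#' Default scenario suite
#'
#' Discount rate at 0\% and 5\%; response rate at its 30\% and 100\% bounds;
#' the reduced advanced-fibrosis response; the adolescent transition
#' modifier; and 1- and 5-year horizons.
#'
#' @return Named list of [scenario_config()]s (including the base case).
#' @export
default_scenarios <- function() {
  list(base = scenario_config(),
       discount_0 = scenario_config(discount_rate = 0),
       discount_5 = scenario_config(discount_rate = 0.05),
       response_30 = scenario_config(response_rate = 0.30),
       response_100 = scenario_config(response_rate = 1.00),
       advanced_response_75 = scenario_config(advanced_response = TRUE),
       adolescent_transitions = scenario_config(adolescent_modifier = TRUE),
       horizon_1 = scenario_config(horizon = 1),
       horizon_5 = scenario_config(horizon = 5))
}

#' Scenario analysis
#'
#' One full pipeline run per scenario; reports each strategy's incremental
#' cost and QALYs versus no screening, its ICUR, whether it is cost-effective
#' (ICUR <= WTP) at each configured threshold, and the frontier-optimal
#' strategy per scenario.
#'
#' @param params A `masld_params` parameter set.
#' @param scenarios Named list of [scenario_config()]s.
#' @return A data.frame, one row per (scenario, strategy).
#' @export
run_scenarios <- function(params, scenarios = default_scenarios()) {
  cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                        ages = as.integer(names(params$prevalence_by_age)),
                                        prop_boys = params$prop_boys))
  wtp <- params$wtp_thresholds
  out <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    res <- lapply(all_strategies(), run_strategy, params = params,
                  scenario = sc, cohort = cohort)
    names(res) <- vapply(res, `[[`, "", "strategy")
    opt <- vapply(wtp, function(w) frontier(res, w)$optimal, "")
    for (s in c("S1", "S2", "S3", "S4")) {
      ic <- icur(res[[s]], res$S4)
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, strategy = s,
        cost_million = (res[[s]]$total_cost - res$S4$total_cost) / 1e6,
        inc_qaly = res[[s]]$total_qaly - res$S4$total_qaly,
        total_qaly = res[[s]]$total_qaly,
        icur_vs_ref = if (s == "S4") NA_real_ else ic$icur,
        ce_wtp1 = if (s == "S4") NA else !is.na(ic$icur) && ic$icur <= wtp[[1]],
        ce_wtp2 = if (s == "S4") NA else !is.na(ic$icur) && ic$icur <= wtp[[2]],
        optimal_wtp1 = s == opt[[1]], optimal_wtp2 = s == opt[[2]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-way sensitivity analysis on a test's sensitivity and specificity
#'
#' For each (se, sp) grid cell, only the named second-stage test's
#' performance is overridden (comparator tests stay at base case); the full
#' pipeline runs and the WTP-optimal strategy and all pairwise ICURs are
#' recorded, yielding a dominance map over diagnostic performance.
#'
#' @param params A `masld_params` parameter set.
#' @param test `"ultrasound"`, `"fibroscan"` or `"mri_pdff"`.
#' @param se_grid,sp_grid Numeric grids in `[0, 1]`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A long-format data.frame: `test`, `se`, `sp`, `optimal`, and
#'   pairwise ICUR columns (`icur_s1_s4`, ..., `icur_s3_s2`).
#' @export
two_way <- function(params, test = c("ultrasound", "fibroscan", "mri_pdff"),
                    se_grid, sp_grid, wtp = params$wtp_thresholds[[1]]) {
  test <- match.arg(test)
  .assert_prob(c(se_grid, sp_grid), "two_way grid")
  cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                        ages = as.integer(names(params$prevalence_by_age)),
                                        prop_boys = params$prop_boys))
  grid <- expand.grid(se = se_grid, sp = sp_grid, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  pairs <- list(c("S1", "S4"), c("S2", "S4"), c("S3", "S4"),
                c("S2", "S1"), c("S3", "S1"), c("S3", "S2"))
  for (i in seq_len(nrow(grid))) {
    p <- set_param_value(params, paste0("tests.", test, ".se"), grid$se[i])
    p <- set_param_value(p, paste0("tests.", test, ".sp"), grid$sp[i])
    res <- lapply(all_strategies(), run_strategy, params = p, cohort = cohort)
    names(res) <- vapply(res, `[[`, "", "strategy")
    icurs <- vapply(pairs, function(pr) icur(res[[pr[1]]], res[[pr[2]]])$icur,
                    numeric(1))
    names(icurs) <- vapply(pairs, function(pr)
      paste0("icur_", tolower(pr[1]), "_", tolower(pr[2])), "")
    out[[i]] <- cbind(data.frame(test = test, se = grid$se[i], sp = grid$sp[i],
                                 optimal = frontier(res, wtp)$optimal,
                                 stringsAsFactors = FALSE),
                      as.data.frame(as.list(icurs)))
  }
  do.call(rbind, out)
}

## ---- probabilistic sensitivity analysis --------------------------------

psa_draw_ids <- function() {
  c("tests.ultrasound.se", "tests.ultrasound.sp",
    "tests.fibroscan.se", "tests.fibroscan.sp",
    "tests.mri_pdff.se", "tests.mri_pdff.sp",
    "utilities.F0", "utilities.F1F2", "utilities.F3", "utilities.F4",
    "transitions.boys.F0_F1", "transitions.boys.F1_F2",
    "transitions.boys.F2_F3", "transitions.boys.F3_F4",
    "transitions.girls.F0_F1", "transitions.girls.F1_F2",
    "transitions.girls.F2_F3", "transitions.girls.F3_F4")
}

psa_uv_for_id <- function(params, id) {
  if (id == "utilities.F1F2") return(params$utilities$F1)
  node <- params
  for (p in strsplit(id, ".", fixed = TRUE)[[1]]) node <- node[[p]]
  node
}

# one row per iteration, one column per beta-kind parameter; invalid rows
# (progression + regression > 1 in any state) are redrawn
psa_draw_matrix <- function(params, n_iter, seed) {
  ids <- psa_draw_ids()
  set.seed(seed)
  draw_rows <- function(n) {
    m <- vapply(ids, function(id) draw_value(psa_uv_for_id(params, id), n),
                numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, ids))
    m
  }
  valid <- function(m) {
    reg_max <- max(params$transitions$regression, params$transitions$regression_tx)
    prog_cols <- grepl("^transitions\\.", colnames(m))
    apply(m[, prog_cols, drop = FALSE] + reg_max <= 1, 1, all)
  }
  draws <- draw_rows(n_iter)
  redrawn <- 0L
  bad <- which(!valid(draws))
  while (length(bad)) {
    redrawn <- redrawn + length(bad)
    draws[bad, ] <- draw_rows(length(bad))
    bad <- bad[!valid(draws[bad, , drop = FALSE])]
  }
  attr(draws, "redrawn") <- redrawn
  draws
}

# materialise one PSA draw into a parameter set (no utility-ordering check:
# draws are sampled independently apart from the shared F1/F2 utility)
apply_psa_draw <- function(params, draw) {
  for (id in names(draw)) params <- set_param_value(params, id, draw[[id]])
  params
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation (default 1000 iterations): every beta-kind
#' parameter is drawn independently from its [beta_from_ci()] fit (costs and
#' other interval-free inputs stay fixed; no parameter correlations are
#' modelled; F1 and F2 utilities are one shared draw), all four strategies
#' are run on the common draw, and the per-iteration costs and QALYs are
#' recorded. Structurally invalid draws (progression + regression exceeding
#' 1) are redrawn and counted. Fully reproducible from `seed`.
#'
#' @param params A `masld_params` parameter set.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer seed.
#' @param cohort_size Optional cohort-size override.
#' @param scenario A [scenario_config()].
#' @return An object of class `psa_result`: `draws` (n_iter x parameters),
#'   `results` (long data.frame: iteration, strategy, cost, qaly),
#'   `n_iter`, `seed`, `redrawn`.
#' @export
run_psa <- function(params, n_iter = 1000L, seed = 1L, cohort_size = NULL,
                    scenario = scenario_config()) {
  if (!is.null(cohort_size)) params$cohort_size <- cohort_size
  cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                        ages = as.integer(names(params$prevalence_by_age)),
                                        prop_boys = params$prop_boys))
  draws <- psa_draw_matrix(params, n_iter, seed)
  strat <- all_strategies()
  cost <- matrix(0, n_iter, 4, dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
  qaly <- cost
  for (it in seq_len(n_iter)) {
    p_it <- apply_psa_draw(params, draws[it, ])
    for (s in strat) {
      r <- run_strategy(s, p_it, scenario = scenario, cohort = cohort)
      cost[it, r$strategy] <- r$total_cost
      qaly[it, r$strategy] <- r$total_qaly
    }
  }
  results <- data.frame(
    iteration = rep(seq_len(n_iter), each = 4L),
    strategy = rep(c("S1", "S2", "S3", "S4"), times = n_iter),
    cost = as.vector(t(cost)), qaly = as.vector(t(qaly)),
    stringsAsFactors = FALSE)
  structure(list(draws = as.data.frame(draws), results = results,
                 cost = cost, qaly = qaly, n_iter = n_iter, seed = seed,
                 redrawn = attr(draws, "redrawn")),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d, %d redraws)\n",
              x$n_iter, x$seed, x$redrawn))
  ic <- (x$cost[, c("S1", "S2", "S3")] - x$cost[, "S4"]) /
    (x$qaly[, c("S1", "S2", "S3")] - x$qaly[, "S4"])
  print(round(t(apply(ic, 2, stats::quantile, c(0.5, 0.025, 0.975))), 1))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' From PSA output, for each willingness-to-pay value on the grid: (a) the
#' fraction of iterations in which each screening strategy has a higher net
#' monetary benefit than the no-screening reference, and (b) the fraction in
#' which each strategy (including no screening) maximises net monetary
#' benefit (ties broken toward the lower-cost strategy). The optimal-curve
#' probabilities partition the iterations at every grid point.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid WTP grid in USD/QALY (default \\$0-\\$100,000 by \\$1,000).
#' @return An object of class `ceac_curve`: data.frame with `wtp`,
#'   `strategy`, `p_ce_vs_ref`, `p_optimal`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"), psa$n_iter >= 1)
  strategies <- colnames(psa$cost)
  out <- list()
  for (w in wtp_grid) {
    nmb <- w * psa$qaly - psa$cost
    p_ce <- colMeans(nmb[, c("S1", "S2", "S3"), drop = FALSE] >
                       nmb[, "S4"])
    # argmax with ties toward lower cost
    best <- character(psa$n_iter)
    for (it in seq_len(psa$n_iter)) {
      cand <- which(nmb[it, ] == max(nmb[it, ]))
      best[it] <- strategies[cand[which.min(psa$cost[it, cand])]]
    }
    p_opt <- vapply(strategies, function(s) mean(best == s), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      wtp = w, strategy = strategies,
      p_ce_vs_ref = c(p_ce, NA_real_)[match(strategies,
                                            c("S1", "S2", "S3", "S4"))],
      p_optimal = p_opt, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("ceac_curve", "data.frame")
  tab
}
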