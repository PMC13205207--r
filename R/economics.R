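#' Discount factor for an annual cycle
#'
#' @param rate Annual discount rate (base case 3\%).
#' @param t Cycle index (non-negative integer).
#' @return `1 / (1 + rate)^t`.
#' @export
#' @examples
#' discount_factor(0.03, 1)  # 0.9709
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  1 / (1 + rate)^t
}

#' Discounted per-child QALYs along a trajectory
#'
#' Utilities accrue at the end of each cycle (cycles `1..horizon`; the cycle-0
#' state contributes none), each cycle's utility being the occupancy-weighted
#' stage utility discounted by [discount_factor()]. No half-cycle correction
#' is applied.
#'
#' @param trajectory A `(horizon + 1) x 5` occupancy matrix from
#'   [run_horizon()].
#' @param utilities Numeric utility vector over F0-F4.
#' @param rate Annual discount rate.
#' @return Discounted QALYs per child (scalar).
#' @export
accrue_qalys <- function(trajectory, utilities, rate) {
  h <- nrow(trajectory) - 1L
  if (h == 0L) return(0)
  disc <- discount_factor(rate, seq_len(h))
  sum((trajectory[-1L, , drop = FALSE] %*% utilities) * disc)
}

#' Discounted per-participant lifestyle-program cost
#'
#' Fixed plus variable annual program costs, charged per participant for each
#' of `duration` cycles (end-of-cycle, discounted like the utilities).
#'
#' @param params A `masld_params` parameter set.
#' @param rate Annual discount rate.
#' @param horizon Model horizon in years.
#' @param duration Program duration in years (capped at the horizon).
#' @return Discounted program cost per participant (USD).
#' @export
accrue_program_cost <- function(params, rate, horizon,
                                duration = params$program_duration_years %||% horizon) {
  duration <- min(duration, horizon)
  annual <- params$costs$program_fixed_annual + params$costs$program_variable_annual
  annual * sum(discount_factor(rate, seq_len(duration)))
}

#' Run one screening strategy through the full model
#'
#' Chains the decision-tree cascade, management assignment, Markov horizon
#' and discounted accrual for every (age, sex) stratum of the cohort, and
#' aggregates to cohort totals. Screening costs are one-off at cycle 0
#' (undiscounted); program costs and utilities accrue at the end of each
#' cycle, discounted. Disease-free children carry the disease-free utility,
#' which cancels from all incremental comparisons (disease status does not
#' differ across strategies).
#'
#' @param strategy A [strategy_spec()] or id string.
#' @param params A `masld_params` parameter set.
#' @param scenario A [scenario_config()].
#' @param cohort A stratified cohort from [generate_cohort()]; defaults to
#'   the parameter set's cohort size with uniform age weights and a 50/50
#'   sex split.
#' @return An object of class `econ_result` with fields `strategy`,
#'   `total_cost` (USD), `total_qaly`, and the run settings.
#' @export
#' @examples
#' run_strategy("S2", default_parameters())
run_strategy <- function(strategy, params, scenario = scenario_config(),
                         cohort = NULL) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                          ages = as.integer(names(params$prevalence_by_age)),
                                          prop_boys = params$prop_boys))
  }
  horizon <- scenario$horizon %||% params$horizon_years
  rate <- scenario$discount_rate %||% params$discount_rate
  rho <- scenario$response_rate %||% params$transitions$response_rate
  u <- utility_vector(params)
  disc_sum <- sum(discount_factor(rate, seq_len(horizon)))
  q_healthy <- params$utilities$disease_free * disc_sum
  c_program <- accrue_program_cost(
    params, rate, horizon,
    duration = scenario$program_duration %||%
      params$program_duration_years %||% horizon)

  # diseased per-child QALYs depend only on (sex, regime[, baseline age under
  # the adolescent flag]); memoise across strata
  qaly_cache <- new.env(parent = emptyenv())
  q_diseased <- function(sex, regime, age) {
    key <- if (scenario$adolescent_modifier) {
      paste(sex, regime, age)
    } else paste(sex, regime)
    if (is.null(qaly_cache[[key]])) {
      traj <- run_horizon(params$initial_stage_distribution, sex, regime,
                          params, horizon = horizon, baseline_age = age,
                          scenario = scenario)
      qaly_cache[[key]] <- accrue_qalys(traj, u, rate)
    }
    qaly_cache[[key]]
  }

  total_cost <- 0
  total_qaly <- 0
  for (i in seq_len(nrow(cohort))) {
    n_i <- cohort$count[i]
    if (n_i == 0) next
    casc <- run_cascade(strategy, params, cohort$age[i])
    slices <- assign_management(casc, params, response_rate = rho)
    total_cost <- total_cost + n_i * casc$one_off_cost_per_child
    for (j in seq_len(nrow(slices))) {
      f <- slices$fraction[j]
      if (f <= 0) next
      q <- if (slices$diseased[j]) {
        q_diseased(cohort$sex[i], slices$regime[j], cohort$age[i])
      } else q_healthy
      total_qaly <- total_qaly + n_i * f * q
      if (slices$program[j]) total_cost <- total_cost + n_i * f * c_program
    }
  }
  structure(list(strategy = strategy$id, label = strategy$label,
                 total_cost = total_cost, total_qaly = total_qaly,
                 cohort_size = sum(cohort$count), horizon = horizon,
                 discount_rate = rate, response_rate = rho),
            class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("%s (%s): cost $%.2f million, %.1f QALYs (cohort %s, %dy, %g%% discount)\n",
              x$strategy, x$label, x$total_cost / 1e6, x$total_qaly,
              format(x$cohort_size, big.mark = ","), x$horizon,
              100 * x$discount_rate))
  invisible(x)
}

#' Run all four strategies and tabulate incremental results
#'
#' Runs S1-S4 on the identical cohort and returns a base-case table with
#' absolute and incremental (versus the no-screening reference S4) costs and
#' QALYs, and the ICUR of each screening strategy against S4.
#'
#' @inheritParams run_strategy
#' @return An object of class `cea_results`: list with `results` (the four
#'   `econ_result`s), `table` (a data.frame in the shape of the published
#'   strategy table) and the `frontier` decisions at each configured WTP
#'   threshold.
#' @export
#' @examples
#' bc <- run_base_case(default_parameters())
#' bc$table
run_base_case <- function(params, scenario = scenario_config(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_spec(size = params$cohort_size,
                                          ages = as.integer(names(params$prevalence_by_age)),
                                          prop_boys = params$prop_boys))
  }
  results <- lapply(all_strategies(), run_strategy, params = params,
                    scenario = scenario, cohort = cohort)
  names(results) <- vapply(results, `[[`, "", "strategy")
  ref <- results$S4
  tab <- do.call(rbind, lapply(results, function(r) {
    ic <- r$total_cost - ref$total_cost
    iq <- r$total_qaly - ref$total_qaly
    data.frame(strategy = r$strategy,
               cost_million = round(ic / 1e6, 10),
               inc_qaly = iq,
               icur_vs_ref = if (r$strategy == "S4") NA_real_ else
                 icur_value(ic, iq),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  fr <- lapply(params$wtp_thresholds, function(w) frontier(results, w))
  structure(list(results = results, table = tab, frontier = fr,
                 wtp_thresholds = params$wtp_thresholds,
                 synthetic_prevalence = isTRUE(attr(params$prevalence_by_age,
                                                    "synthetic"))),
            class = "cea_results")
}

#' @export
print.cea_results <- function(x, ...) {
  cat("Cost-utility results (reference: S4, no screening)\n")
  if (x$synthetic_prevalence) {
    cat("  [age-specific prevalence: SYNTHETIC profile]\n")
  }
  print(transform(x$table, cost_million = round(cost_million, 2),
                  inc_qaly = round(inc_qaly, 1),
                  icur_vs_ref = round(icur_vs_ref, 1)))
  for (nm in names(x$frontier)) {
    f <- x$frontier[[nm]]
    cat(sprintf("  optimal at WTP $%s/QALY (%s): %s\n",
                format(x$wtp_thresholds[[nm]], big.mark = ","), nm, f$optimal))
  }
  invisible(x)
}

icur_value <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) return(NA_real_)
  delta_cost / delta_qaly
}

#' Incremental cost-utility ratio between two strategies
#'
#' `ICUR = (cost_a - cost_b) / (qaly_a - qaly_b)`. The ratio is symmetric
#' under exchanging the two strategies. When the QALY difference is zero the
#' ratio is undefined and flagged rather than raising a division error; the
#' dominance quadrant is reported so a misleading ratio (e.g. cheaper and
#' more effective) is never read as a price.
#'
#' @param a,b `econ_result`s (or lists with `total_cost`/`total_qaly`).
#' @return An object of class `icur_result`: `icur` (USD/QALY, `NA` when
#'   undefined), `delta_cost`, `delta_qaly`, `note` (`"ratio"`,
#'   `"a_dominant"`, `"a_dominated"` or `"undefined"`).
#' @export
#' @examples
#' icur(list(total_cost = 220000 + 10, total_qaly = 42.6),
#'      list(total_cost = 10, total_qaly = 0))
icur <- function(a, b) {
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qaly - b$total_qaly
  note <- if (dq == 0) {
    "undefined"
  } else if (dc <= 0 && dq > 0) {
    "a_dominant"
  } else if (dc >= 0 && dq < 0) {
    "a_dominated"
  } else "ratio"
  structure(list(icur = icur_value(dc, dq), delta_cost = dc, delta_qaly = dq,
                 a = a$strategy %||% "a", b = b$strategy %||% "b",
                 note = note),
            class = "icur_result")
}

#' @export
print.icur_result <- function(x, ...) {
  if (x$note == "undefined") {
    cat(sprintf("ICUR(%s vs %s): undefined (equal QALYs)\n", x$a, x$b))
  } else {
    cat(sprintf("ICUR(%s vs %s): $%.1f per QALY (dCost $%.0f, dQALY %.2f%s)\n",
                x$a, x$b, x$icur, x$delta_cost, x$delta_qaly,
                if (x$note == "ratio") "" else paste0("; ", x$note)))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' @param result An `econ_result`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return `wtp * total_qaly - total_cost`.
#' @export
nmb <- function(result, wtp) wtp * result$total_qaly - result$total_cost

#' Cost-effectiveness frontier and optimal strategy at a WTP threshold
#'
#' Sorts strategies by cost, removes strictly dominated options (costlier
#' with no more QALYs) and extendedly dominated options (a higher incremental
#' ratio than a more effective alternative), then walks up the frontier
#' accepting each step whose incremental ICUR is at most the threshold. The
#' same decision is recomputed as the net-monetary-benefit maximiser (ties
#' broken toward lower cost) and the two are asserted to agree.
#'
#' @param results List of `econ_result`s (>= 2).
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return An object of class `frontier_decision`: cost-ordered strategy
#'   ids, `dominated` (strict), `ext_dominated`, the frontier with step
#'   ICURs, and `optimal`.
#' @export
#' @examples
#' rs <- list(list(strategy = "A", total_cost = 0, total_qaly = 0),
#'            list(strategy = "B", total_cost = 10, total_qaly = 2),
#'            list(strategy = "C", total_cost = 30, total_qaly = 3))
#' frontier(rs, wtp = 5)$optimal   # "B"
frontier <- function(results, wtp) {
  stopifnot(length(results) >= 2)
  ids <- vapply(results, function(r) r$strategy %||% "?", "")
  cost <- vapply(results, `[[`, 0, "total_cost")
  qaly <- vapply(results, `[[`, 0, "total_qaly")
  ord <- order(cost, -qaly)
  ids <- ids[ord]; cost <- cost[ord]; qaly <- qaly[ord]

  # strict dominance: costlier (or equal-cost later in order) and no more QALYs
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j || !keep[j]) next
      if ((cost[j] < cost[i] && qaly[j] >= qaly[i]) ||
          (cost[j] <= cost[i] && qaly[j] > qaly[i]) ||
          (cost[j] == cost[i] && qaly[j] == qaly[i] && j < i)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  strict_dominated <- ids[!keep]

  # extended dominance: on the cost-ordered non-dominated set, drop options
  # whose incremental ratio exceeds that of the next step up
  fr_idx <- which(keep)
  repeat {
    if (length(fr_idx) < 3) break
    dropped <- FALSE
    for (m in seq(2, length(fr_idx) - 1)) {
      i0 <- fr_idx[m - 1]; i1 <- fr_idx[m]; i2 <- fr_idx[m + 1]
      r_low <- (cost[i1] - cost[i0]) / (qaly[i1] - qaly[i0])
      r_high <- (cost[i2] - cost[i1]) / (qaly[i2] - qaly[i1])
      if (r_low > r_high) {
        fr_idx <- fr_idx[-m]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  ext_dominated <- setdiff(ids[keep], ids[fr_idx])

  # walk the frontier: accept steps with incremental ICUR <= wtp
  step_icur <- c(NA_real_, diff(cost[fr_idx]) / diff(qaly[fr_idx]))
  opt_pos <- 1L
  if (length(fr_idx) > 1) {
    for (m in seq(2, length(fr_idx))) {
      if (step_icur[m] <= wtp) opt_pos <- m
    }
  }
  optimal <- ids[fr_idx[opt_pos]]

  # cross-check: NMB maximiser; an exact NMB tie means the frontier step ICUR
  # equals the threshold, where the <=-rule accepts the more effective option
  nmb_all <- wtp * qaly - cost
  best <- which(nmb_all == max(nmb_all))
  nmb_opt <- ids[best[which.max(qaly[best])]]
  stopifnot(identical(optimal, nmb_opt))

  structure(list(order = ids, cost = cost, qaly = qaly,
                 dominated = strict_dominated, ext_dominated = ext_dominated,
                 frontier = data.frame(strategy = ids[fr_idx],
                                       cost = cost[fr_idx], qaly = qaly[fr_idx],
                                       step_icur = step_icur,
                                       stringsAsFactors = FALSE),
                 wtp = wtp, optimal = optimal),
            class = "frontier_decision")
}

#' @export
print.frontier_decision <- function(x, ...) {
  cat(sprintf("Frontier at WTP $%s/QALY: optimal %s\n",
              format(x$wtp, big.mark = ","), x$optimal))
  if (length(x$dominated)) {
    cat("  strictly dominated:", paste(x$dominated, collapse = ", "), "\n")
  }
  if (length(x$ext_dominated)) {
    cat("  extendedly dominated:", paste(x$ext_dominated, collapse = ", "), "\n")
  }
  print(x$frontier, row.names = FALSE)
  invisible(x)
}
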