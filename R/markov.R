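#' Scenario flags and overrides for a model run
#'
#' Collects the switches exercised by the scenario analyses: discount-rate,
#' response-rate, horizon and program-duration overrides; the reduced
#' response multiplier for advanced fibrosis (F3/F4); and the adolescent
#' transition modifier (ages >= 15 progress faster and regress more slowly).
#'
#' @param discount_rate Override of the annual discount rate (`NULL` = base).
#' @param response_rate Override of the lifestyle-program response rate
#'   (declared range 0.30-1.00).
#' @param advanced_response Apply the advanced-fibrosis multiplier (base
#'   0.75) to the intervention regression probability in F3/F4?
#' @param adolescent_modifier Apply the adolescent transition modifiers when
#'   the attained age is >= 15?
#' @param horizon Override of the time horizon in years (1, 5 or 10).
#' @param program_duration Override of the lifestyle-program duration in
#'   years (`NULL` = full horizon).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(discount_rate = NULL, response_rate = NULL,
                            advanced_response = FALSE,
                            adolescent_modifier = FALSE,
                            horizon = NULL, program_duration = NULL) {
  if (!is.null(response_rate)) {
    if (response_rate < 0.30 || response_rate > 1.00) {
      stop("response_rate override must lie in [0.30, 1.00]", call. = FALSE)
    }
  }
  if (!is.null(discount_rate)) .assert_nonneg(discount_rate, "discount_rate")
  if (!is.null(horizon) && horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  structure(list(discount_rate = discount_rate, response_rate = response_rate,
                 advanced_response = isTRUE(advanced_response),
                 adolescent_modifier = isTRUE(adolescent_modifier),
                 horizon = horizon, program_duration = program_duration),
            class = "scenario_config")
}

#' Build the annual fibrosis transition matrix
#'
#' Constructs the tridiagonal 5-state (F0-F4) annual transition matrix. The
#' natural-history regime uses the sex-specific progression probabilities and
#' the fixed 6\% one-stage regression; the intervention regime replaces the
#' regression probability with 27.7\% in every non-F0 state, leaving
#' progression unchanged. Diagonals are filled by conservation. F0 has no
#' regression and F4 no progression. Scenario flags may scale the
#' intervention regression by the advanced-fibrosis multiplier in F3/F4, and
#' apply the adolescent modifiers (progression x1.25, regression x0.75 by
#' default) when `age >= 15`.
#'
#' @param sex `"boys"` or `"girls"`.
#' @param regime `"natural"` or `"intervention"`.
#' @param params A `masld_params` parameter set.
#' @param age Attained age at the cycle (only relevant with the adolescent
#'   flag); `NULL` means no age modifier.
#' @param scenario A [scenario_config()].
#' @return A 5x5 row-stochastic matrix with dimnames `F0..F4`.
#' @export
#' @examples
#' p <- default_parameters()
#' build_transition_matrix("boys", "natural", p)["F0", ]   # 0.996, 0.004, 0...
build_transition_matrix <- function(sex = c("boys", "girls"),
                                    regime = c("natural", "intervention"),
                                    params, age = NULL,
                                    scenario = scenario_config()) {
  sex <- match.arg(sex)
  regime <- match.arg(regime)
  tr <- params$transitions
  prog <- c(tr[[sex]]$F0_F1$mean, tr[[sex]]$F1_F2$mean,
            tr[[sex]]$F2_F3$mean, tr[[sex]]$F3_F4$mean, 0)
  reg <- if (regime == "intervention") {
    rep(tr$regression_tx, 5)
  } else {
    rep(tr$regression, 5)
  }
  reg[1] <- 0
  if (regime == "intervention" && scenario$advanced_response) {
    reg[4:5] <- reg[4:5] * tr$advanced_response_multiplier
  }
  if (scenario$adolescent_modifier && !is.null(age) && age >= 15) {
    prog <- pmin(prog * tr$adolescent_progression_factor, 1)
    reg <- reg * tr$adolescent_regression_factor
  }
  if (any(prog + reg > 1 + 1e-12)) {
    stop("invalid transition matrix: progression + regression > 1 in some state",
         call. = FALSE)
  }
  P <- matrix(0, 5, 5, dimnames = list(stage_names(), stage_names()))
  for (k in 1:5) {
    if (k > 1) P[k, k - 1] <- reg[k]
    if (k < 5) P[k, k + 1] <- prog[k]
    P[k, k] <- 1 - reg[k] - prog[k]
  }
  P
}

#' Advance a state vector one annual cycle
#'
#' @param state Occupancy over F0-F4 (non-negative, sums to 1).
#' @param matrix A 5x5 row-stochastic transition matrix.
#' @return The next state vector (`state \%*\% matrix`); mass is conserved.
#' @export
markov_step <- function(state, matrix) {
  stopifnot(length(state) == 5L, all(dim(matrix) == c(5L, 5L)))
  out <- as.vector(state %*% matrix)
  names(out) <- stage_names()
  out
}

#' Run a state vector over the full horizon
#'
#' Iterates [markov_step()] for `horizon` annual cycles, rebuilding the
#' transition matrix each cycle as the cohort slice ages (the matrix only
#' changes with age under the adolescent scenario flag).
#'
#' @param state0 Initial occupancy over F0-F4.
#' @param sex,regime,params,scenario Passed to [build_transition_matrix()].
#' @param horizon Number of annual cycles (defaults to the parameter set's).
#' @param baseline_age Age at cycle 0; attained age at cycle `t` is
#'   `baseline_age + t`.
#' @return A `(horizon + 1) x 5` matrix of occupancies, rows `0..horizon`.
#' @export
run_horizon <- function(state0, sex = "boys", regime = "natural", params,
                        horizon = params$horizon_years, baseline_age = 10,
                        scenario = scenario_config()) {
  stopifnot(length(state0) == 5L, all(state0 >= -1e-15),
            abs(sum(state0) - 1) < 1e-9)
  traj <- matrix(0, nrow = horizon + 1L, ncol = 5L,
                 dimnames = list(cycle = 0:horizon, stage = stage_names()))
  traj[1L, ] <- state0
  state <- state0
  for (t in seq_len(horizon)) {
    P <- build_transition_matrix(sex, regime, params,
                                 age = baseline_age + t - 1, scenario = scenario)
    state <- markov_step(state, P)
    traj[t + 1L, ] <- state
  }
  traj
}

# point-estimate utility vector over F0-F4
utility_vector <- function(params) {
  vapply(stage_names(), function(s) params$utilities[[s]]$mean, numeric(1))
}
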