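# shared test helpers: fixtures are built in code, no stored data

`%||%` <- function(x, y) if (is.null(x)) y else x

base_params <- function() default_parameters()

# replace every uncertain input by a point mass (degenerate PSA)
fix_parameters <- function(params) {
  walk <- function(x) {
    if (is_uncertain_value(x)) return(uncertain_value(x$mean))
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  out <- walk(unclass(params))
  class(out) <- "masld_params"
  out
}

is_uncertain_value <- function(x) inherits(x, "uncertain_value")

# parameter set with a flat prevalence profile (handy for hand arithmetic)
flat_prev_params <- function(prev = 0.08) {
  default_parameters(prevalence_by_age = stats::setNames(rep(prev, 9), 6:14))
}

# econ_result-shaped stub for frontier/icur unit tests
econ_stub <- function(id, cost, qaly) {
  list(strategy = id, total_cost = cost, total_qaly = qaly)
}

# occupancy comparison: binomial 3-SE band with a continuity correction for
# the 1/n resolution of an empirical fraction
expect_occupancy_agreement <- function(empirical, expected, n) {
  se <- sqrt(pmax(expected * (1 - expected), 0) / n)
  tol <- 3 * se + 0.5 / n
  expect_true(all(abs(empirical - expected) <= tol),
              label = sprintf("max |emp - exp| = %.4g within 3 binomial SE",
                              max(abs(empirical - expected))))
}
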