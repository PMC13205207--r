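#' An uncertain model input: point estimate with 95\% interval
#'
#' Model inputs are carried as a point estimate (the base-case value) plus a
#' 95\% confidence interval and a distribution kind. Probabilities and
#' utilities with intervals are `"beta"`-distributed in probabilistic
#' sensitivity analysis; inputs without an interval are `"fixed"`.
#'
#' @param mean Point estimate (probability or utility on `[0, 1]`).
#' @param ci_low,ci_high 95\% interval bounds; default to `mean` (fixed value).
#' @param dist `"beta"` or `"fixed"`; inferred when omitted (a zero-width
#'   interval is fixed).
#' @return An object of class `uncertain_value`.
#' @export
#' @examples
#' uncertain_value(0.72, 0.64, 0.79)   # FibroScan sensitivity
#' uncertain_value(0.06)               # fixed annual regression probability
uncertain_value <- function(mean, ci_low = mean, ci_high = mean, dist = NULL) {
  stopifnot(is.numeric(mean), length(mean) == 1L)
  if (is.null(dist)) dist <- if (ci_high > ci_low) "beta" else "fixed"
  dist <- match.arg(dist, c("beta", "fixed"))
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop("uncertain_value requires ci_low <= mean <= ci_high", call. = FALSE)
  }
  if (dist == "beta") .assert_prob(c(mean, ci_low, ci_high), "beta-kind value")
  if (dist == "fixed" && (ci_low != mean || ci_high != mean)) {
    stop("fixed-kind value must have ci_low = ci_high = mean", call. = FALSE)
  }
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high, dist = dist),
            class = "uncertain_value")
}

#' @export
print.uncertain_value <- function(x, ...) {
  if (x$dist == "fixed") {
    cat(sprintf("%.4g (fixed)\n", x$mean))
  } else {
    cat(sprintf("%.4g (%.4g, %.4g) ~ Beta\n", x$mean, x$ci_low, x$ci_high))
  }
  invisible(x)
}

is_uncertain_value <- function(x) inherits(x, "uncertain_value")

#' Fit a Beta distribution to a mean and 95\% interval
#'
#' Method-of-moments fit: the interval is converted to a normal-approximate
#' standard deviation, `sigma = (ci_high - ci_low) / (2 * 1.96)`, and the Beta
#' shape parameters solve the mean/variance equations
#' `alpha = m * (m * (1 - m) / sigma^2 - 1)`, `beta = (1 - m) * (...)`.
#' The fitted distribution has analytic mean exactly equal to the input mean;
#' asymmetric intervals are honoured only through `sigma`.
#'
#' @param mean Point estimate in `[0, 1]`.
#' @param ci_low,ci_high 95\% interval bounds, `ci_low <= mean <= ci_high`.
#' @return Named numeric vector `c(alpha, beta)`, both positive.
#'   A zero-width interval signals a classed error
#'   (`masldcea_fixed_value`): the input is a fixed value, not a
#'   distribution. An interval so wide that the implied variance reaches
#'   `mean * (1 - mean)` signals `masldcea_invalid_beta`.
#' @export
#' @examples
#' beta_from_ci(0.72, 0.64, 0.79)  # FibroScan sensitivity
beta_from_ci <- function(mean, ci_low, ci_high) {
  .assert_prob(c(mean, ci_low, ci_high), "beta_from_ci input")
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop("beta_from_ci requires ci_low <= mean <= ci_high", call. = FALSE)
  }
  if (ci_high == ci_low) {
    stop(structure(class = c("masldcea_fixed_value", "error", "condition"),
                   list(message = "zero-width interval: fixed value, not a distribution",
                        call = sys.call(-1))))
  }
  sigma <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  v <- sigma^2
  if (v >= mean * (1 - mean)) {
    stop(structure(class = c("masldcea_invalid_beta", "error", "condition"),
                   list(message = sprintf(
                     "implied variance %.4g >= mean*(1-mean) = %.4g: no valid Beta fit",
                     v, mean * (1 - mean)), call = sys.call(-1))))
  }
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Draw values from an uncertain input
#'
#' Fixed-kind inputs return their point estimate; beta-kind inputs draw from
#' the [beta_from_ci()] fit.
#'
#' @param uv An [uncertain_value()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_value <- function(uv, n = 1L) {
  stopifnot(is_uncertain_value(uv))
  if (uv$dist == "fixed") return(rep(uv$mean, n))
  ab <- beta_from_ci(uv$mean, uv$ci_low, uv$ci_high)
  stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
}

#' Base-case model parameters
#'
#' Returns the complete registry of model inputs at their base-case values:
#' WHtR positivity, second-stage test performance (ultrasound, FibroScan,
#' MRI-PDFF), the initial fibrosis-stage distribution, screening and
#' lifestyle-program costs (2019 USD), per-stage utilities, sex-specific
#' annual transition probabilities, the discount rate, horizon, cohort size
#' and willingness-to-pay thresholds. The age-specific MASLD prevalence is
#' not available as a published table; the default is the package's clearly
#' labelled synthetic profile from [synth_prevalence()].
#'
#' @param prevalence_by_age Named numeric vector mapping ages 6-14 to MASLD
#'   prevalence; defaults to the synthetic profile.
#' @return An object of class `masld_params` (a validated nested list).
#' @seealso [load_config()], [synth_prevalence()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$utilities$F4$mean      # 0.66
#' p$discount_rate          # 0.03
default_parameters <- function(prevalence_by_age = synth_prevalence()) {
  params <- structure(list(
    whtr_positivity = 0.226,
    whtr_stage1_sensitivity = 1.0,
    tests = list(
      ultrasound = list(se = uncertain_value(0.52, 0.41, 0.64),
                        sp = uncertain_value(0.96, 0.91, 0.99)),
      fibroscan  = list(se = uncertain_value(0.72, 0.64, 0.79),
                        sp = uncertain_value(0.98, 0.97, 0.98)),
      mri_pdff   = list(se = uncertain_value(0.95, 0.92, 0.97),
                        sp = uncertain_value(0.92, 0.77, 0.98))
    ),
    initial_stage_distribution = c(F0 = 0.885, F1 = 0.052, F2 = 0.035,
                                   F3 = 0.016, F4 = 0.012),
    prevalence_by_age = prevalence_by_age,
    costs = list(
      routine_exam = 2.9,
      ultrasound = 16.5,
      fibroscan = 13.0,
      mri_pdff = 87.0,
      blood_panel = 22.5,
      program_fixed_annual = 10.5,
      program_variable_annual = 21.7
    ),
    utilities = list(
      F0 = uncertain_value(0.95, 0.93, 1.00),
      F1 = uncertain_value(0.85, 0.79, 0.92),
      F2 = uncertain_value(0.85, 0.79, 0.92),
      F3 = uncertain_value(0.73, 0.64, 0.82),
      F4 = uncertain_value(0.66, 0.49, 0.83),
      disease_free = 1.0
    ),
    transitions = list(
      boys = list(
        F0_F1 = uncertain_value(0.004, 0.002, 0.006),
        F1_F2 = uncertain_value(0.033, 0.020, 0.051),
        F2_F3 = uncertain_value(0.033, 0.020, 0.051),
        F3_F4 = uncertain_value(0.034, 0.019, 0.064)
      ),
      girls = list(
        F0_F1 = uncertain_value(0.003, 0.002, 0.005),
        F1_F2 = uncertain_value(0.028, 0.016, 0.043),
        F2_F3 = uncertain_value(0.028, 0.016, 0.043),
        F3_F4 = uncertain_value(0.028, 0.016, 0.054)
      ),
      regression = 0.06,
      regression_tx = 0.277,
      response_rate = 0.40,
      advanced_response_multiplier = 0.75,
      adolescent_progression_factor = 1.25,
      adolescent_regression_factor = 0.75
    ),
    discount_rate = 0.03,
    horizon_years = 10L,
    program_duration_years = NULL,   # NULL = full horizon
    cohort_size = 100000L,
    prop_boys = 0.5,
    wtp_thresholds = c(national = 30584.0, beijing = 71415.5)
  ), class = "masld_params")
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities and utilities in
#' `[0, 1]`, non-negative costs, the initial stage distribution summing to 1,
#' the utility ordering `u(F0) >= u(F1) = u(F2) >= u(F3) >= u(F4)` at point
#' estimates, `progression + regression <= 1` in every state, and positive
#' horizon and cohort size. Errors name the offending key.
#'
#' @param params A `masld_params` object (or a list with the same shape).
#' @return `params`, invisibly classed as `masld_params`, if valid.
#' @export
validate_parameters <- function(params) {
  .assert_prob(params$whtr_positivity, "whtr_positivity")
  .assert_prob(params$whtr_stage1_sensitivity, "whtr_stage1_sensitivity")
  for (tn in names(params$tests)) {
    for (fld in c("se", "sp")) {
      uv <- params$tests[[tn]][[fld]]
      .assert_prob(c(uv$mean, uv$ci_low, uv$ci_high), paste0("tests.", tn, ".", fld))
    }
  }
  isd <- params$initial_stage_distribution
  if (length(isd) != 5L || any(isd < 0)) {
    stop("initial_stage_distribution must be 5 non-negative fractions", call. = FALSE)
  }
  if (abs(sum(isd) - 1) > 1e-12) {
    stop(sprintf("initial_stage_distribution must sum to 1 (got %.15g)", sum(isd)),
         call. = FALSE)
  }
  .assert_prob(params$prevalence_by_age, "prevalence_by_age")
  for (ck in setdiff(names(params$costs), character())) {
    .assert_nonneg(params$costs[[ck]], paste0("costs.", ck))
  }
  u <- params$utilities
  for (s in stage_names()) .assert_prob(u[[s]]$mean, paste0("utilities.", s))
  .assert_prob(u$disease_free, "utilities.disease_free")
  if (!(u$F0$mean >= u$F1$mean && u$F1$mean == u$F2$mean &&
        u$F2$mean >= u$F3$mean && u$F3$mean >= u$F4$mean)) {
    stop("utilities must satisfy u(F0) >= u(F1) = u(F2) >= u(F3) >= u(F4)",
         call. = FALSE)
  }
  tr <- params$transitions
  for (sex in c("boys", "girls")) {
    for (k in names(tr[[sex]])) {
      .assert_prob(tr[[sex]][[k]]$mean, paste0("transitions.", sex, ".", k))
    }
  }
  .assert_prob(tr$regression, "transitions.regression")
  .assert_prob(tr$regression_tx, "transitions.regression_tx")
  .assert_prob(tr$response_rate, "transitions.response_rate")
  .assert_prob(tr$advanced_response_multiplier,
               "transitions.advanced_response_multiplier")
  for (sex in c("boys", "girls")) {
    prog <- vapply(tr[[sex]], function(x) x$mean, numeric(1))
    if (any(prog[-1] + tr$regression > 1) || any(prog[-1] + tr$regression_tx > 1)) {
      stop(sprintf("transitions.%s: progression + regression exceeds 1", sex),
           call. = FALSE)
    }
  }
  .assert_nonneg(params$discount_rate, "discount_rate")
  if (params$horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (params$cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  if (!is.null(params$program_duration_years) &&
      params$program_duration_years < 1) {
    stop("program_duration_years must be >= 1 (or NULL for full horizon)",
         call. = FALSE)
  }
  .assert_prob(params$prop_boys, "prop_boys")
  .assert_nonneg(params$wtp_thresholds, "wtp_thresholds")
  class(params) <- "masld_params"
  invisible(params)
}

#' @export
print.masld_params <- function(x, ...) {
  cat("MASLD screening cost-utility parameter set\n")
  cat(sprintf("  WHtR positivity: %.1f%%; stage-1 sensitivity: %.2f\n",
              100 * x$whtr_positivity, x$whtr_stage1_sensitivity))
  cat(sprintf("  prevalence (ages %s-%s): %.3f-%.3f [synthetic profile unless user-supplied]\n",
              min(as.integer(names(x$prevalence_by_age))),
              max(as.integer(names(x$prevalence_by_age))),
              min(x$prevalence_by_age), max(x$prevalence_by_age)))
  cat(sprintf("  horizon: %d y; discount: %.0f%%; cohort: %s children\n",
              x$horizon_years, 100 * x$discount_rate,
              format(x$cohort_size, big.mark = ",")))
  cat(sprintf("  WTP thresholds: $%s and $%s per QALY\n",
              format(x$wtp_thresholds[[1]], big.mark = ","),
              format(x$wtp_thresholds[[2]], big.mark = ",")))
  invisible(x)
}

## ---- config serialization ----------------------------------------------

.uv_to_list <- function(uv) {
  list(mean = uv$mean, ci_low = uv$ci_low, ci_high = uv$ci_high, dist = uv$dist)
}

.uv_from_spec <- function(x, key) {
  if (is_uncertain_value(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(uncertain_value(x))
  if (is.list(x) && !is.null(x$mean)) {
    return(uncertain_value(x$mean, x$ci_low %||% x$mean, x$ci_high %||% x$mean,
                           x$dist))
  }
  stop(sprintf("cannot interpret '%s' as an uncertain value", key), call. = FALSE)
}

#' Convert a parameter set to a plain (YAML-ready) list
#' @param params A `masld_params` object.
#' @return A nested list of plain scalars/lists mirroring the parameter set.
#' @export
as_config_list <- function(params) {
  walk <- function(x) {
    if (is_uncertain_value(x)) return(.uv_to_list(x))
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  out <- walk(unclass(params))
  prev <- stats::setNames(as.numeric(params$prevalence_by_age),
                          names(params$prevalence_by_age))
  out$prevalence_by_age <- as.list(prev)
  out$initial_stage_distribution <- as.list(params$initial_stage_distribution)
  out$wtp_thresholds <- as.list(params$wtp_thresholds)
  out
}

#' Write a parameter set to a YAML config file
#' @param params A `masld_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(as_config_list(params), path, precision = 15)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML config whose sections mirror the parameter set. Any key
#' absent from the file falls back to [default_parameters()]; unknown keys
#' raise a warning and are ignored; every invariant is re-validated after the
#' merge (an out-of-range value is an error naming the key).
#'
#' @param path Path to a YAML config file.
#' @param base Parameter set supplying defaults.
#' @return A validated `masld_params` object.
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  merged <- .merge_config(unclass(base), cfg, prefix = "")
  merged$initial_stage_distribution <-
    unlist(merged$initial_stage_distribution)[stage_names()]
  prev <- unlist(merged$prevalence_by_age)
  merged$prevalence_by_age <- prev[order(as.integer(names(prev)))]
  merged$wtp_thresholds <- unlist(merged$wtp_thresholds)
  validate_parameters(structure(merged, class = "masld_params"))
}

# recursive merge of a config fragment over defaults; unknown keys warn
.merge_config <- function(base, cfg, prefix) {
  for (key in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      warning(sprintf("unknown config key '%s' ignored", full), call. = FALSE)
      next
    }
    bval <- base[[key]]
    cval <- cfg[[key]]
    if (is_uncertain_value(bval)) {
      base[[key]] <- .uv_from_spec(cval, full)
    } else if (is.list(bval) && is.list(cval) &&
               !key %in% c("prevalence_by_age", "initial_stage_distribution",
                           "wtp_thresholds")) {
      base[[key]] <- .merge_config(bval, cval, full)
    } else {
      base[key] <- list(cval)  # NULL-safe assignment
    }
  }
  base
}
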