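#' Screening strategy specification
#'
#' Four strategies are compared: S1 (WHtR followed by ultrasound), S2 (WHtR
#' followed by FibroScan), S3 (WHtR followed by MRI-PDFF) and S4 (no
#' screening). S4 has no second stage and accrues zero screening cost.
#'
#' @param id One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return An object of class `strategy_spec` with fields `id`,
#'   `second_stage` (test name or `NA`) and `label`.
#' @export
#' @examples
#' strategy_spec("S2")
strategy_spec <- function(id = c("S1", "S2", "S3", "S4")) {
  id <- match.arg(id)
  second <- switch(id, S1 = "ultrasound", S2 = "fibroscan",
                   S3 = "mri_pdff", S4 = NA_character_)
  label <- switch(id, S1 = "WHtR + ultrasound", S2 = "WHtR + FibroScan",
                  S3 = "WHtR + MRI-PDFF", S4 = "no screening")
  structure(list(id = id, second_stage = second, label = label),
            class = "strategy_spec")
}

all_strategies <- function() lapply(c("S1", "S2", "S3", "S4"), strategy_spec)

#' Classify a tested subgroup by a second-stage test
#'
#' Standard 2x2 decomposition of a tested population with disease prevalence
#' `prevalence` under a test with sensitivity `se` and specificity `sp`:
#' `tp = pi * se`, `fn = pi * (1 - se)`, `fp = (1 - pi) * (1 - sp)`,
#' `tn = (1 - pi) * sp`. The four fractions sum to 1.
#'
#' @param prevalence Disease prevalence among those tested.
#' @param se,sp Test sensitivity and specificity.
#' @return Named numeric vector `c(tp, fn, fp, tn)` (fractions of tested).
#' @export
#' @examples
#' classify_second_stage(0.3, 0.72, 0.98)
classify_second_stage <- function(prevalence, se, sp) {
  .assert_prob(c(prevalence, se, sp), "classify_second_stage input")
  c(tp = prevalence * se,
    fn = prevalence * (1 - se),
    fp = (1 - prevalence) * (1 - sp),
    tn = (1 - prevalence) * sp)
}

#' Run the decision-tree screening cascade for one age
#'
#' Partitions the cohort of a given age into six arms: the WHtR-positive
#' fraction (base 22.6\%) is tested with the strategy's second-stage modality
#' and split into TP/FP/TN/FN; WHtR-negatives split into diseased (missed by
#' stage 1) and healthy. The disease prevalence among WHtR-positives is
#' `prevalence(age) * stage1_sensitivity / whtr_positivity`; with the default
#' stage-1 sensitivity of 1 no diseased child is WHtR-negative. S4 (no
#' screening) leaves the whole cohort unscreened at zero cost. The one-off
#' screening cost per child is the routine physical examination (charged to
#' every screened child) plus, for each WHtR-positive, the second-stage image
#' and the blood biochemical panel.
#'
#' @param strategy A [strategy_spec()] (or its id string).
#' @param params A `masld_params` parameter set.
#' @param age Age in years (6-14).
#' @return An object of class `cascade_result`: arm fractions (`tp`, `fp`,
#'   `tn`, `fn`, `whtr_neg_diseased`, `whtr_neg_healthy`, summing to 1),
#'   `responder_fraction` (`tp * response_rate`), `one_off_cost_per_child`
#'   (USD), plus `strategy`, `age` and `prevalence`.
#' @export
#' @examples
#' run_cascade("S2", default_parameters(), age = 10)
run_cascade <- function(strategy, params, age) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  ages <- as.integer(names(params$prevalence_by_age))
  if (!age %in% ages) {
    stop(sprintf("age %s outside the modelled range %d-%d", age,
                 min(ages), max(ages)), call. = FALSE)
  }
  prev <- unname(params$prevalence_by_age[[as.character(age)]])
  rho <- params$transitions$response_rate
  if (strategy$id == "S4") {
    arms <- c(tp = 0, fp = 0, tn = 0, fn = 0,
              whtr_neg_diseased = prev, whtr_neg_healthy = 1 - prev)
    out <- list(strategy = strategy$id, age = age, prevalence = prev,
                arms = arms, responder_fraction = 0,
                one_off_cost_per_child = 0)
    class(out) <- "cascade_result"
    return(out)
  }
  pos <- params$whtr_positivity
  s1 <- params$whtr_stage1_sensitivity
  cond_prev <- prev * s1 / pos
  if (cond_prev > 1 + 1e-12) {
    stop(sprintf(paste0("stage-1 sensitivity %.2f incompatible with WHtR ",
                        "positivity %.3f at prevalence %.3f: implied conditional ",
                        "prevalence %.3f > 1"), s1, pos, prev, cond_prev),
         call. = FALSE)
  }
  cond_prev <- min(cond_prev, 1)
  test <- params$tests[[strategy$second_stage]]
  cls <- classify_second_stage(cond_prev, test$se$mean, test$sp$mean)
  neg_dis <- prev * (1 - s1)
  arms <- c(tp = unname(cls[["tp"]] * pos), fp = unname(cls[["fp"]] * pos),
            tn = unname(cls[["tn"]] * pos), fn = unname(cls[["fn"]] * pos),
            whtr_neg_diseased = neg_dis,
            whtr_neg_healthy = 1 - pos - neg_dis)
  if (any(arms < -1e-12)) {
    stop("negative arm fraction: prevalence inconsistent with WHtR positivity",
         call. = FALSE)
  }
  test_cost <- params$costs[[strategy$second_stage]]
  cost <- params$costs$routine_exam +
    pos * (test_cost + params$costs$blood_panel)
  out <- list(strategy = strategy$id, age = age, prevalence = prev,
              arms = arms, responder_fraction = unname(cls[["tp"]]) * pos * rho,
              one_off_cost_per_child = cost)
  class(out) <- "cascade_result"
  out
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("Screening cascade: %s, age %d (prevalence %.3f)\n",
              x$strategy, x$age, x$prevalence))
  print(round(x$arms, 5))
  cat(sprintf("responder fraction %.5f; one-off cost $%.2f per child\n",
              x$responder_fraction, x$one_off_cost_per_child))
  invisible(x)
}

#' Assign post-screening management to cohort slices
#'
#' Splits the cascade arms into homogeneous slices that enter the Markov
#' model: true positives divide into responders (fraction
#' `tp * response_rate`, intervention transitions) and non-responders
#' (natural history); false negatives and diseased WHtR-negatives follow
#' natural history untreated; false positives are disease-free but attend
#' the lifestyle program (costs, no transitions); true negatives and healthy
#' WHtR-negatives are disease-free with no further costs. Every diseased
#' slice starts from the initial fibrosis-stage distribution.
#'
#' @param cascade A [run_cascade()] result.
#' @param params A `masld_params` parameter set.
#' @param response_rate Override of the response rate (defaults to the
#'   parameter set's).
#' @return A data.frame of slices: `arm`, `fraction`, `diseased`, `regime`
#'   (`"natural"`, `"intervention"` or `NA` for disease-free), `program`
#'   (attends the lifestyle program).
#' @export
assign_management <- function(cascade, params,
                              response_rate = params$transitions$response_rate) {
  stopifnot(inherits(cascade, "cascade_result"))
  .assert_prob(response_rate, "response_rate")
  a <- cascade$arms
  slices <- data.frame(
    arm = c("tp_responder", "tp_nonresponder", "fn", "whtr_neg_diseased",
            "fp", "tn", "whtr_neg_healthy"),
    fraction = c(a[["tp"]] * response_rate, a[["tp"]] * (1 - response_rate),
                 a[["fn"]], a[["whtr_neg_diseased"]],
                 a[["fp"]], a[["tn"]], a[["whtr_neg_healthy"]]),
    diseased = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    regime = c("intervention", "natural", "natural", "natural",
               NA, NA, NA),
    program = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  stopifnot(abs(sum(slices$fraction) - 1) < 1e-9)
  slices
}
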