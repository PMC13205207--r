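utils::globalVariables(c("wtp", "prob", "strategy", "inc_qaly", "inc_cost",
                         "icur_low", "icur_high", "param"))

#' Plot cost-effectiveness acceptability curves
#'
#' Optimal-strategy probability against willingness-to-pay, one line per
#' strategy. Requires ggplot2.
#'
#' @param x A [ceac()] result.
#' @param which `"optimal"` (probability of maximising net monetary benefit)
#'   or `"vs_ref"` (probability of beating no screening).
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, which = c("optimal", "vs_ref")) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac requires ggplot2", call. = FALSE)
  }
  df <- as.data.frame(x)
  if (which == "vs_ref") df <- df[df$strategy != "S4", ]
  df$prob <- if (which == "optimal") df$p_optimal else df$p_ce_vs_ref
  ggplot2::ggplot(df, ggplot2::aes(x = wtp, y = prob, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = if (which == "optimal") "P(optimal strategy)" else
                    "P(cost-effective vs no screening)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane from PSA output
#'
#' Incremental costs and QALYs of each screening strategy versus no
#' screening, one point per iteration, with the WTP threshold line.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Threshold to draw (USD/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 30584) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ce_plane requires ggplot2", call. = FALSE)
  }
  df <- do.call(rbind, lapply(c("S1", "S2", "S3"), function(s) {
    data.frame(strategy = s,
               inc_qaly = psa$qaly[, s] - psa$qaly[, "S4"],
               inc_cost = psa$cost[, s] - psa$cost[, "S4"])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = inc_qaly, y = inc_cost,
                                   colour = strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs vs S4",
                  y = "Incremental cost vs S4 ($)", colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Tornado plot of one-way sensitivity results
#'
#' @param tab A [one_way()] table.
#' @param strategy Which comparison against no screening to show.
#' @param top Number of most influential parameters to display.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tab, strategy = "S2", top = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado requires ggplot2", call. = FALSE)
  }
  df <- as.data.frame(tab)
  df <- df[df$strategy == strategy & !is.na(df$swing), ]
  df <- utils::head(df[order(-df$swing), ], top)
  df$param <- factor(df$param, levels = rev(df$param))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = icur_low, xend = icur_high,
                                       y = param, yend = param),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = df$icur_base[1], linetype = "dashed") +
    ggplot2::labs(x = sprintf("ICUR %s vs S4 ($/QALY)", strategy), y = NULL) +
    ggplot2::theme_minimal()
}
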