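`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic components (probabilistic sensitivity analysis,
#' microsimulation, parameter-fit checks) draw their seed from a single
#' master seed through a named sub-stream, so each analysis is independently
#' reproducible from the run manifest.
#'
#' @param seed Master integer seed.
#' @param stream Character name of the sub-stream (e.g. `"psa"`, `"microsim"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "psa")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 1234567) %% 2147483647)
}

stage_names <- function() c("F0", "F1", "F2", "F3", "F4")

.assert_prob <- function(x, key) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("parameter '%s' must lie in [0, 1] (got %s)", key,
                 paste(signif(x, 4), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.assert_nonneg <- function(x, key) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("parameter '%s' must be non-negative", key), call. = FALSE)
  }
  invisible(x)
}
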