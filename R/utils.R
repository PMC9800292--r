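#' Geometric mean of positive values
#'
#' The collapse statistic used throughout the pipeline: probe counts are
#' collapsed to target values, and negative-probe background is summarized,
#' by `exp(mean(log(x)))`.
#'
#' @param x numeric vector, all values strictly positive.
#' @return The geometric mean as a single positive number.
#' @examples
#' geometric_mean(c(1, 100)) # 10
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) {
    stop("geometric_mean: empty input", call. = FALSE)
  }
  if (anyNA(x) || any(x <= 0)) {
    stop("geometric_mean: all values must be positive and non-missing",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

# sprintf-style stop/warning with call suppressed
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warningf <- function(...) warning(sprintf(...), call. = FALSE)

# Raw zeros are lifted to 1 before any log-space operation, so the
# "no pseudo count needed" log2 rule holds on simulated data too.
lift_counts <- function(x) pmax(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-wise geometric standard deviation on the natural-log scale;
# sample (n-1) standard deviation, so >= 2 values are required.
geometric_sd <- function(x) {
  if (length(x) < 2L) {
    stop("geometric_sd: at least two values required", call. = FALSE)
  }
  if (any(x <= 0)) stop("geometric_sd: values must be positive", call. = FALSE)
  exp(stats::sd(log(x)))
}

# Reserved target id for negative-control (spike-in) probes.
NEG_TARGET_SENTINEL <- "NegProbe"
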