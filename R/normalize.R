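#' @title Normalization methods
#' @description The five normalization strategies compared by the
#'   benchmarking stage: third-quartile (Q3) scaling, a modified
#'   counts-per-X scaling (CPM), median-of-ratios size factors (MOR),
#'   per-ROI gamma-fit distribution correction, and classic quantile
#'   normalization; plus the shared log2 transform rule (no pseudocount —
#'   collapsed values are never below 1).
#' @name normalization
NULL

new_normalization_result <- function(matrix, method, scale_factors = NULL,
                                     fit = NULL) {
  structure(list(matrix = matrix, method = method,
                 scale_factors = scale_factors, fit = fit),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization_result: method = %s, %d targets x %d ROIs, stage = %s\n",
              x$method, nrow(x$matrix), ncol(x$matrix), matrix_stage(x$matrix)))
  invisible(x)
}

.as_matrix <- function(matrix) {
  if (inherits(matrix, "normalization_result")) matrix$matrix else matrix
}

#' Third-quartile (Q3) normalization
#'
#' Each ROI is rescaled so that its 75th percentile of target values
#' (linear interpolation between order statistics, R quantile type 7)
#' aligns with the geometric mean of all ROIs' third quartiles. A pure
#' within-column rescaling: within-ROI ratios are preserved exactly.
#'
#' @param matrix collapsed-stage target matrix (positive values).
#' @param probs quartile probability (0.75; exposed for cross-checking).
#' @param type quantile estimator type (default 7, linear interpolation).
#' @return a `normalization_result` with per-ROI scale factors.
#' @export
q3_normalize <- function(matrix, probs = 0.75, type = 7) {
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), all(m > 0))
  q3 <- apply(m, 2, stats::quantile, probs = probs, type = type, names = FALSE)
  target <- geometric_mean(q3)
  sf <- q3 / target
  out <- sweep(m, 2, sf, "/")
  new_normalization_result(target_matrix(out, "normalized(q3)"), "q3",
                           scale_factors = stats::setNames(sf, colnames(m)))
}

#' Modified CPM normalization
#'
#' Each value is divided by the sum of all counts in its ROI and
#' multiplied by a scaling factor (default 10,000), so every column sums
#' to `scale`.
#'
#' @param matrix collapsed-stage target matrix.
#' @param scale scaling factor (default 10000).
#' @export
cpm_normalize <- function(matrix, scale = 10000) {
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), all(m > 0), scale > 0)
  cs <- colSums(m)
  out <- sweep(m, 2, cs / scale, "/")
  new_normalization_result(target_matrix(out, "normalized(cpm)"), "cpm",
                           scale_factors = stats::setNames(cs / scale, colnames(m)))
}

#' Median-of-ratios (size factor) normalization
#'
#' Values are rounded to integer counts; the reference for each target is
#' its geometric mean across ROIs, computed over targets with no zero
#' (after rounding); each ROI's size factor is the median of its
#' count-to-reference ratios, and the rounded counts are divided by it.
#' This substitutes for a variance-stabilizing transform: downstream the
#' matrix is log2 transformed like every other method, which is a
#' documented approximation.
#'
#' @param matrix collapsed-stage target matrix.
#' @export
mor_normalize <- function(matrix) {
  m <- round(.as_matrix(matrix))
  stopifnot(is.matrix(m))
  ref_ok <- rowSums(m <= 0) == 0
  if (!any(ref_ok)) stopf("mor_normalize: every target contains a zero; no reference set")
  geo <- exp(rowMeans(log(m[ref_ok, , drop = FALSE])))
  sf <- apply(m[ref_ok, , drop = FALSE] / geo, 2, stats::median)
  out <- sweep(m, 2, sf, "/")
  new_normalization_result(target_matrix(out, "normalized(mor)"), "mor",
                           scale_factors = stats::setNames(sf, colnames(m)))
}

# Gamma MLE by profile-likelihood Newton iteration on the shape:
# solve log(a) - digamma(a) = log(mean(x)) - mean(log(x)); rate = a / mean.
fit_gamma <- function(x, max_iter = 50L, tol = 1e-10) {
  stopifnot(all(x > 0), length(x) >= 2L)
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) stopf("fit_gamma: degenerate sample (zero log-spread)")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  if (!is.finite(a) || a <= 0) stopf("fit_gamma: MLE failed to converge")
  c(shape = a, rate = a / mean(x))
}

#' Gamma-fit distribution correction
#'
#' A two-parameter gamma is fitted to each ROI's values by maximum
#' likelihood; the reference distribution uses the arithmetic mean of the
#' fitted shapes and rates across ROIs (pooled-fit alternative behind
#' `reference = "pooled"`). Each value is mapped through
#' `Qref(F_roi(value))` — a strictly increasing, rank-preserving transform
#' that aligns the ROI distributions.
#'
#' @param matrix collapsed-stage target matrix (positive values).
#' @param reference `"mean_params"` (default) or `"pooled"`.
#' @return a `normalization_result`; fitted per-ROI and reference
#'   parameters in `$fit`.
#' @export
gamma_fit_normalize <- function(matrix, reference = c("mean_params", "pooled")) {
  reference <- match.arg(reference)
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), all(m > 0))
  fits <- vapply(seq_len(ncol(m)), function(j) {
    tryCatch(fit_gamma(m[, j]),
             error = function(e) stopf("gamma_fit_normalize: MLE failed for ROI %s: %s",
                                       colnames(m)[j], conditionMessage(e)))
  }, c(shape = 0, rate = 0))
  ref <- if (reference == "mean_params") {
    c(shape = mean(fits["shape", ]), rate = mean(fits["rate", ]))
  } else {
    fit_gamma(as.vector(m))
  }
  eps <- 1e-12
  out <- m
  for (j in seq_len(ncol(m))) {
    p <- stats::pgamma(m[, j], shape = fits["shape", j], rate = fits["rate", j])
    p <- pmin(pmax(p, eps), 1 - eps)
    out[, j] <- stats::qgamma(p, shape = ref["shape"], rate = ref["rate"])
  }
  new_normalization_result(
    target_matrix(out, "normalized(gamma)"), "gamma",
    fit = list(per_roi = t(fits), reference = ref))
}

#' Quantile normalization
#'
#' Classic quantile normalization: each column is sorted, values are
#' averaged across columns at each rank to form the reference
#' distribution, and each column's values are replaced by the reference
#' value at their rank. Ties within a column receive the mean of the
#' reference values over the tied rank positions. After normalization
#' every column holds the identical multiset of values.
#'
#' @param matrix collapsed-stage target matrix with >= 2 ROIs.
#' @export
quantile_normalize <- function(matrix) {
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    y <- numeric(length(x))
    y[order(x)] <- ref
    grp <- match(x, x) # tie groups share the mean reference value
    out[, j] <- stats::ave(y, grp, FUN = mean)
  }
  new_normalization_result(
    target_matrix(out, "normalized(quantile)"), "quantile",
    fit = list(reference = ref))
}

#' Log2 transform
#'
#' Elementwise log2. No pseudocount is added: collapsed GeoMx values are
#' never below 1, so values below 1 are a domain error unless
#' `allow_sub_one` floors them at 1 (with a recorded warning count).
#'
#' @param result a `normalization_result` or target matrix.
#' @param allow_sub_one floor values below 1 instead of erroring.
#' @return same type as the input, stage tag updated to `log2(method)`.
#' @export
apply_log2 <- function(result, allow_sub_one = FALSE) {
  m <- .as_matrix(result)
  stopifnot(is.matrix(m))
  n_sub <- sum(m < 1)
  if (n_sub > 0) {
    if (!allow_sub_one) {
      bad <- which(m < 1, arr.ind = TRUE)
      stopf("apply_log2: %d value(s) below 1 (first at target %s, ROI %s); set allow_sub_one to floor them",
            n_sub, rownames(m)[bad[1, 1]] %||% bad[1, 1],
            colnames(m)[bad[1, 2]] %||% bad[1, 2])
    }
    warningf("apply_log2: floored %d value(s) below 1", n_sub)
    m <- pmax(m, 1)
  }
  method <- if (inherits(result, "normalization_result")) result$method else "raw"
  out_m <- target_matrix(log2(m), sprintf("log2(%s)", method))
  if (inherits(result, "normalization_result")) {
    result$matrix <- out_m
    result
  } else {
    out_m
  }
}

#' Normalize by method name
#'
#' Dispatch helper used by the pipeline: applies one of the five methods
#' and (always) the log2 rule.
#'
#' @param matrix collapsed-stage target matrix.
#' @param method one of `"q3"`, `"cpm"`, `"mor"`, `"gamma"`, `"quantile"`.
#' @param log2 apply the log2 transform after normalizing (default TRUE).
#' @export
normalize_matrix <- function(matrix,
                             method = c("q3", "cpm", "mor", "gamma", "quantile"),
                             log2 = TRUE) {
  method <- match.arg(method)
  res <- switch(method,
                q3 = q3_normalize(matrix),
                cpm = cpm_normalize(matrix),
                mor = mor_normalize(matrix),
                gamma = gamma_fit_normalize(matrix),
                quantile = quantile_normalize(matrix))
  if (log2) res <- apply_log2(res, allow_sub_one = TRUE)
  res
}
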