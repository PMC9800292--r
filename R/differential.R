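#' @title Differential expression
#' @description Median-based log2 fold changes and per-target Wilcoxon
#'   rank-sum tests with Benjamini-Hochberg correction — the
#'   nonparametric procedure applied uniformly to every normalization
#'   method.
#' @name differential
NULL

.group_factor <- function(groups, roi_ids) {
  if (!is.null(names(groups))) groups <- groups[roi_ids]
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stopf("exactly two groups required, got %d", nlevels(groups))
  if (anyNA(groups)) stopf("group labels missing for some ROIs")
  groups
}

# De-log a log2-stage matrix so medians are taken on the natural scale.
.natural_scale <- function(matrix) {
  m <- .as_matrix(matrix)
  if (grepl("^log2", matrix_stage(m))) 2^m else m
}

#' Median-based log2 fold change
#'
#' `lfc(c) = log2(median_A(c) / median_B(c))` with medians taken on the
#' natural scale (log2-stage input is de-logged first). Group A is the
#' first factor level of `groups`.
#'
#' @param matrix target matrix (natural or log2 stage).
#' @param groups two-level group labels per ROI (named by roi_id or in
#'   column order).
#' @return named numeric vector of per-target log2 fold changes.
#' @export
median_lfc <- function(matrix, groups) {
  m <- .natural_scale(matrix)
  groups <- .group_factor(groups, colnames(m))
  med <- sapply(levels(groups), function(g) {
    apply(m[, groups == g, drop = FALSE], 1, stats::median)
  })
  if (any(med <= 0)) stopf("median_lfc: non-positive group median encountered")
  stats::setNames(log2(med[, 1] / med[, 2]), rownames(m))
}

# Two-sided rank-sum p-value for one target. Exact (via the Wilcoxon
# distribution) when both groups are small and tie-free; otherwise the
# normal approximation with tie and continuity corrections.
.ranksum_p <- function(x, ga, exact_max_n = 10L) {
  xa <- x[ga]
  xb <- x[!ga]
  na <- length(xa)
  nb <- length(xb)
  r <- rank(x)
  u <- sum(r[ga]) - na * (na + 1) / 2
  ties <- table(x)
  has_ties <- any(ties > 1)
  if (na <= exact_max_n && nb <= exact_max_n && !has_ties) {
    p <- if (u > na * nb / 2) {
      2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, na, nb)
    }
    return(c(stat = u, p = min(p, 1)))
  }
  n <- na + nb
  z <- u - na * nb / 2
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(c(stat = u, p = 1)) # fully tied
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  c(stat = u, p = min(2 * stats::pnorm(-abs(z)), 1))
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test per target between the two groups, exact when
#' both groups have at most `exact_max_n` ROIs and no ties, otherwise the
#' normal approximation with tie and continuity corrections; p-values are
#' Benjamini-Hochberg adjusted across all tested targets. The test is
#' rank-based, so log2 and natural-scale input give identical p-values;
#' fold changes are always computed from natural-scale medians.
#'
#' @param matrix target matrix.
#' @param groups two-level group labels per ROI.
#' @param alpha significance threshold applied to the adjusted p-values.
#' @param exact_max_n largest per-group size for the exact null
#'   distribution (default 10).
#' @return data.frame of class `dge_result`: target_id, group medians,
#'   lfc, statistic, p, padj, significant.
#' @export
wilcoxon_dge <- function(matrix, groups, alpha = 0.05, exact_max_n = 10L) {
  m <- .natural_scale(matrix)
  groups <- .group_factor(groups, colnames(m))
  if (min(table(groups)) < 2L) stopf("wilcoxon_dge: each group needs >= 2 ROIs")
  ga <- groups == levels(groups)[1]
  res <- t(apply(m, 1, .ranksum_p, ga = ga, exact_max_n = exact_max_n))
  med_a <- apply(m[, ga, drop = FALSE], 1, stats::median)
  med_b <- apply(m[, !ga, drop = FALSE], 1, stats::median)
  padj <- stats::p.adjust(res[, "p"], method = "BH")
  out <- data.frame(target_id = rownames(m),
                    median_a = med_a, median_b = med_b,
                    lfc = log2(med_a / med_b),
                    stat = res[, "stat"], p = res[, "p"], padj = padj,
                    significant = padj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- levels(groups)
  attr(out, "alpha") <- alpha
  class(out) <- c("dge_result", "data.frame")
  out
}
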