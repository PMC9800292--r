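#' @title Normalization benchmarking
#' @description The benchmarking framework that scores each normalization
#'   method on three technical criteria — (i) similarity of ROI data
#'   distributions (pairwise two-sample Kolmogorov-Smirnov tests),
#'   (ii) deviation of the MA plot from the y = 0 line (OLS fit of M on
#'   A), (iii) noise interference (Spearman association between per-target
#'   summed group-median signal-to-noise and log2 fold change) — plus a
#'   biological criterion (agreement of marker-gene correlation structure
#'   with a reference matrix) and a PCA-based signal-to-noise diagnostic.
#' @name benchmark
NULL

#' Pairwise Kolmogorov-Smirnov summary over ROI columns
#'
#' All pairwise two-sample KS statistics D and asymptotic p-values across
#' ROI columns, summarized as the mean D and the fraction of pairs with
#' p < 0.05.
#'
#' @param matrix target matrix with >= 2 ROIs.
#' @param groups optional group labels; when given, a per-group summary
#'   (between-group pairs only) is added.
#' @return list with `D` (symmetric matrix), `p`, `mean_d`,
#'   `frac_significant`, and optionally `between_group`.
#' @export
ks_matrix <- function(matrix, groups = NULL) {
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  n <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  P <- matrix(1, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      kt <- suppressWarnings(stats::ks.test(m[, i], m[, j]))
      D[i, j] <- D[j, i] <- unname(kt$statistic)
      P[i, j] <- P[j, i] <- kt$p.value
    }
  }
  ut <- upper.tri(D)
  out <- list(D = D, p = P, mean_d = mean(D[ut]),
              frac_significant = mean(P[ut] < 0.05))
  if (!is.null(groups)) {
    g <- .group_factor(groups, colnames(m))
    between <- outer(g, g, "!=") & ut
    out$between_group <- list(mean_d = mean(D[between]),
                              frac_significant = mean(P[between] < 0.05))
  }
  out
}

#' MA-plot deviation from y = 0
#'
#' Per target, `M` is the median-based log2 fold change between the two
#' groups and `A` is log2 of the mean natural-scale expression over all
#' ROIs (both groups pooled). An ordinary least-squares fit `M = a + b*A`
#' quantifies systematic deviation from the unbiased `M = 0` line.
#'
#' @param matrix log2-stage (or natural) target matrix.
#' @param groups two-level group labels per ROI.
#' @return list with `slope`, `intercept`, `r_squared`, `p_slope`, and the
#'   per-target `M` and `A` vectors.
#' @export
ma_deviation <- function(matrix, groups) {
  m <- .natural_scale(matrix)
  if (nrow(m) < 3L) stopf("ma_deviation: at least 3 targets required")
  M <- median_lfc(matrix, groups)
  A <- log2(rowMeans(m))
  fit <- stats::lm(M ~ A)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = unname(sm$coefficients[2, 4]),
       M = M, A = A)
}

#' Association of signal-to-noise with fold change
#'
#' Spearman correlation (average ranks for ties) between the per-target
#' sum of group-median signal-to-noise ratios and the per-target log2
#' fold change. On unbiased data this should vanish; a strong association
#' is the signature of S/N-driven differential expression.
#'
#' @param lfc per-target log2 fold changes.
#' @param snr_sum per-target summed group-median S/N (same order/names).
#' @return list with `rho`, `p`, and `degenerate` (TRUE when either
#'   vector is constant, in which case rho is reported as 0).
#' @export
sn_lfc_association <- function(lfc, snr_sum) {
  stopifnot(length(lfc) == length(snr_sum))
  if (!is.null(names(lfc)) && !is.null(names(snr_sum))) {
    snr_sum <- snr_sum[names(lfc)]
  }
  if (stats::sd(lfc) == 0 || stats::sd(snr_sum) == 0) {
    return(list(rho = 0, p = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(snr_sum, lfc, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Marker-gene correlation agreement with a reference matrix
#'
#' Spearman gene-gene correlation matrices are computed over the shared
#' marker genes in the test and reference matrices; the strict upper
#' triangles (deduplicated pairs) are vectorized in matching gene order
#' and compared by Spearman correlation. High agreement means the
#' normalization preserves the reference's co-expression structure.
#'
#' @param matrix test target matrix (normalized, log2 stage).
#' @param reference reference expression matrix (e.g. bulk RNA-seq),
#'   genes in rows.
#' @param markers a marker gene set list (or character vector of genes).
#' @return list with `rho`, `p`, `n_genes`, `dropped_genes`, and the
#'   paired upper-triangle vectors `pairs`.
#' @export
marker_correlation_agreement <- function(matrix, reference, markers) {
  m <- .as_matrix(matrix)
  genes <- unique(unlist(markers, use.names = FALSE))
  shared <- intersect(intersect(genes, rownames(m)), rownames(reference))
  dropped <- setdiff(genes, shared)
  if (length(shared) < 3L) stopf("marker_correlation_agreement: fewer than 3 shared marker genes")
  c_test <- stats::cor(t(m[shared, , drop = FALSE]), method = "spearman")
  c_ref <- stats::cor(t(reference[shared, , drop = FALSE]), method = "spearman")
  ut <- upper.tri(c_test)
  ct <- suppressWarnings(stats::cor.test(c_test[ut], c_ref[ut], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       n_genes = length(shared), dropped_genes = dropped,
       pairs = data.frame(test = c_test[ut], reference = c_ref[ut]))
}

#' PCA signal-to-noise diagnostic
#'
#' Principal component analysis of the ROIs (targets centered); reports
#' the absolute Pearson correlation of the first two PC scores with the
#' per-ROI median signal-to-noise ratio. A large value means S/N, not
#' biology, drives the leading structure.
#'
#' @param matrix log2-stage target matrix.
#' @param stats `roi_noise_stats` carrying `median_snr` per ROI, or a
#'   named numeric vector of per-ROI median S/N.
#' @param scale. pass-through to [stats::prcomp()] (default FALSE).
#' @return list with `r_pc1`, `r_pc2`, `scores`, `sdev`.
#' @export
pca_snr_diagnostic <- function(matrix, stats, scale. = FALSE) {
  m <- .as_matrix(matrix)
  if (ncol(m) < 3L) stopf("pca_snr_diagnostic: at least 3 ROIs required")
  snr <- if (is.data.frame(stats)) {
    stats::setNames(stats$median_snr, stats$roi_id)[colnames(m)]
  } else {
    stats[colnames(m)]
  }
  if (anyNA(snr)) stopf("pca_snr_diagnostic: median S/N missing for some ROIs")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  list(r_pc1 = abs(stats::cor(pc$x[, 1], snr)),
       r_pc2 = abs(stats::cor(pc$x[, 2], snr)),
       scores = pc$x[, 1:2, drop = FALSE],
       sdev = pc$sdev)
}

#' Benchmark one or more normalization methods
#'
#' Runs the three technical criteria (and, when a reference matrix and
#' marker sets are supplied, the biological agreement criterion) for each
#' requested method on a collapsed-stage matrix, and ranks the methods by
#' mean criterion rank (smaller |rho|, smaller MA R-squared, smaller mean
#' KS D, larger biological agreement are better).
#'
#' @param matrix collapsed-stage target matrix (post-QC).
#' @param groups two-level group labels per ROI.
#' @param stats `roi_noise_stats` from the QC stage.
#' @param methods methods to benchmark (default all five).
#' @param markers optional marker gene sets.
#' @param reference optional reference expression matrix.
#' @return list of class `benchmark_report` with one entry per method and
#'   a `ranking` data.frame.
#' @export
run_benchmark <- function(matrix, groups, stats,
                          methods = c("q3", "cpm", "mor", "gamma", "quantile"),
                          markers = NULL, reference = NULL) {
  m <- .as_matrix(matrix)
  groups <- .group_factor(groups, colnames(m))
  snr <- compute_snr(m, stats, groups)
  reports <- lapply(methods, function(method) {
    norm <- suppressWarnings(normalize_matrix(m, method, log2 = TRUE))
    ks <- ks_matrix(norm$matrix, groups)
    ma <- ma_deviation(norm$matrix, groups)
    sn <- sn_lfc_association(ma$M, snr$snr_sum)
    bio <- if (!is.null(markers) && !is.null(reference)) {
      marker_correlation_agreement(norm$matrix, reference, markers)
    } else NULL
    pca <- pca_snr_diagnostic(norm$matrix,
                              stats::setNames(snr$per_roi_median, colnames(m)))
    list(method = method,
         ks_summary = ks[c("mean_d", "frac_significant", "between_group")],
         ma_fit = ma[c("slope", "intercept", "r_squared", "p_slope")],
         sn_lfc = sn,
         bio_agreement = if (is.null(bio)) NULL else bio[c("rho", "p", "n_genes")],
         pca_snr = pca[c("r_pc1", "r_pc2")])
  })
  names(reports) <- methods
  crit <- data.frame(
    method = methods,
    ks_mean_d = vapply(reports, function(r) r$ks_summary$mean_d, 0),
    ma_r_squared = vapply(reports, function(r) r$ma_fit$r_squared, 0),
    sn_lfc_abs_rho = vapply(reports, function(r) abs(r$sn_lfc$rho), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  ranks <- cbind(rank(crit$ks_mean_d), rank(crit$ma_r_squared),
                 rank(crit$sn_lfc_abs_rho))
  if (!is.null(markers) && !is.null(reference)) {
    crit$bio_rho <- vapply(reports, function(r) r$bio_agreement$rho, 0)
    ranks <- cbind(ranks, rank(-crit$bio_rho))
  }
  crit$mean_rank <- rowMeans(ranks)
  crit <- crit[order(crit$mean_rank), ]
  structure(list(reports = reports, ranking = crit),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Normalization benchmark (best first):\n")
  print(x$ranking, row.names = FALSE, digits = 3)
  invisible(x)
}
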