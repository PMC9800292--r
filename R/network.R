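#' @title Signed weighted co-expression network analysis
#' @description A lightweight re-implementation of the signed WGCNA
#'   workflow: soft-threshold selection by the scale-free topology
#'   criterion, signed adjacency, topological overlap, average-linkage
#'   hierarchical clustering with a simplified tree cut and eigengene
#'   merging, module eigengenes, module membership, module-trait
#'   correlation with Student-t p-values, and per-module signal-to-noise
#'   summaries. Not a drop-in for the WGCNA package: the hybrid dynamic
#'   tree cut is replaced by a documented quantile cut.
#' @name network
NULL

# WGCNA-style color labels assigned by decreasing module size.
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Network parameters
#'
#' @param candidate_powers soft-threshold powers to scan (default 1..20).
#' @param power_override fixed power; skips selection when given (the
#'   reference analyses used 16 on quantile- and 24 on Q3-normalized
#'   data).
#' @param scale_free_r2_threshold minimum signed scale-free fit R-squared
#'   (default 0.8).
#' @param min_module_size clusters below this size become grey
#'   (default 30).
#' @param deep_split integer 0..4 controlling cut height (default 3);
#'   maps to fractions 0.95, 0.85, 0.75, 0.65, 0.55 of the dendrogram's
#'   merge-height range (deeper split cuts lower, producing more, finer
#'   modules).
#' @param merge_eigengene_cor modules whose eigengenes correlate above
#'   this are merged (default 0.75).
#' @return list of class `network_params`.
#' @export
network_params <- function(candidate_powers = 1:20,
                           power_override = NULL,
                           scale_free_r2_threshold = 0.8,
                           min_module_size = 30L,
                           deep_split = 3L,
                           merge_eigengene_cor = 0.75) {
  p <- list(candidate_powers = as.integer(candidate_powers),
            power_override = if (is.null(power_override)) NULL else as.integer(power_override),
            scale_free_r2_threshold = scale_free_r2_threshold,
            min_module_size = as.integer(min_module_size),
            deep_split = as.integer(deep_split),
            merge_eigengene_cor = merge_eigengene_cor)
  if (any(p$candidate_powers < 1L)) stopf("network_params: powers must be >= 1")
  if (p$scale_free_r2_threshold <= 0 || p$scale_free_r2_threshold >= 1 ||
      p$merge_eigengene_cor <= 0 || p$merge_eigengene_cor >= 1) {
    stopf("network_params: thresholds must be in (0,1)")
  }
  if (!p$deep_split %in% 0:4) stopf("network_params: deep_split must be in 0..4")
  class(p) <- "network_params"
  p
}

DEEP_SPLIT_QUANTILES <- c(`0` = 0.95, `1` = 0.85, `2` = 0.75,
                          `3` = 0.65, `4` = 0.55)

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power` with Pearson correlation across
#' ROIs; entries in [0,1], unit diagonal. Negative correlation maps
#' toward 0, so only positive co-expression forms edges.
#'
#' @param matrix log2-stage target matrix (genes in rows).
#' @param power soft-threshold power.
#' @return symmetric adjacency matrix.
#' @export
signed_adjacency <- function(matrix, power) {
  m <- .as_matrix(matrix)
  stopifnot(is.matrix(m), ncol(m) >= 3L, power >= 1)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stopf("signed_adjacency: zero-variance gene(s): %s",
          paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  }
  a <- ((1 + stats::cor(t(m))) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free topology soft-threshold selection
#'
#' For each candidate power the signed adjacency is built, connectivity
#' `k_i = sum_j a_ij - 1` computed, `k` binned (10 bins), and
#' `log10(freq)` regressed on `log10(mean k)`; the fit R-squared is
#' negated when the slope is positive. The chosen power is the smallest
#' with signed R-squared at or above the threshold, or the argmax (with a
#' warning flag) when none reaches it. `power_override` short-circuits
#' the choice but the fit table is still returned.
#'
#' @param matrix log2-stage target matrix.
#' @param params [network_params()].
#' @param n_bins histogram bins for the connectivity distribution.
#' @return list with `power`, `fit_table` (power, signed_r2, slope,
#'   mean_k) and `reached_threshold`.
#' @export
pick_soft_threshold <- function(matrix, params = network_params(), n_bins = 10L) {
  m <- .as_matrix(matrix)
  cor_half <- (1 + stats::cor(t(m))) / 2
  diag(cor_half) <- NA
  rows <- lapply(params$candidate_powers, function(beta) {
    a <- cor_half^beta
    k <- rowSums(a, na.rm = TRUE)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- as.vector(table(bin))
    kmid <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(kmid) & kmid > 0
    if (sum(ok) < 3L) {
      return(data.frame(power = beta, signed_r2 = NA_real_,
                        slope = NA_real_, mean_k = mean(k)))
    }
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
    r2 <- summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2])
    data.frame(power = beta, signed_r2 = ifelse(slope > 0, -r2, r2),
               slope = slope, mean_k = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  if (!is.null(params$power_override)) {
    return(list(power = params$power_override, fit_table = fit_table,
                reached_threshold = NA))
  }
  ok <- which(!is.na(fit_table$signed_r2) &
                fit_table$signed_r2 >= params$scale_free_r2_threshold)
  if (length(ok) > 0L) {
    list(power = fit_table$power[ok[1L]], fit_table = fit_table,
         reached_threshold = TRUE)
  } else {
    best <- which.max(fit_table$signed_r2)
    warningf("pick_soft_threshold: no power reached R2 >= %.2f; using argmax (power %d)",
             params$scale_free_r2_threshold, fit_table$power[best])
    list(power = fit_table$power[best], fit_table = fit_table,
         reached_threshold = FALSE)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' with `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' diagonal 1. The dissimilarity used for clustering is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency with unit diagonal.
#' @return TOM matrix.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  stopifnot(is.matrix(a))
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stopf("topological_overlap: adjacency must be symmetric")
  }
  ad <- a
  diag(ad) <- 0
  L <- ad %*% ad
  k <- rowSums(ad)
  kmin <- outer(k, k, pmin)
  tom <- (L + ad) / (kmin + 1 - ad)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module detection by hierarchical clustering with a simplified tree cut
#'
#' Average-linkage clustering of the TOM dissimilarity; the tree is cut
#' at the `deep_split`-mapped quantile of its merge heights; clusters
#' below `min_module_size` are sent to grey; when the expression matrix
#' is supplied, modules whose eigengenes correlate above
#' `merge_eigengene_cor` are merged iteratively. Color labels are
#' assigned by decreasing module size (turquoise first); unassigned
#' genes are grey.
#'
#' @param diss_tom dissimilarity matrix (1 - TOM), values in [0,1].
#' @param params [network_params()].
#' @param matrix optional log2-stage expression matrix (needed for
#'   eigengene merging; skipped when absent).
#' @return named character vector of module colors per gene, with the
#'   `hclust` tree in attribute `"tree"`.
#' @export
detect_modules <- function(diss_tom, params = network_params(), matrix = NULL) {
  stopifnot(is.matrix(diss_tom), nrow(diss_tom) > 0L)
  if (any(diss_tom < -1e-8) || any(diss_tom > 1 + 1e-8)) {
    stopf("detect_modules: dissimilarity must lie in [0,1]")
  }
  tree <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  q <- DEEP_SPLIT_QUANTILES[as.character(params$deep_split)]
  # cut at a fraction of the merge-height range: quantiles of the raw merge
  # heights are dominated by the many near-zero within-module joins and
  # would shatter clean modules
  h <- tree$height
  cut_height <- min(h) + q * (max(h) - min(h))
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < params$min_module_size])] <- 0L
  if (!is.null(matrix) && length(unique(cl[cl != 0L])) > 1L) {
    cl <- .merge_by_eigengene(cl, .as_matrix(matrix), params$merge_eigengene_cor)
  }
  colors <- .label_modules(cl)
  names(colors) <- rownames(diss_tom)
  attr(colors, "tree") <- tree
  attr(colors, "cut_height") <- cut_height
  colors
}

.merge_by_eigengene <- function(cl, m, cor_threshold) {
  repeat {
    mods <- sort(unique(cl[cl != 0L]))
    if (length(mods) < 2L) return(cl)
    eg <- sapply(mods, function(k) .eigengene(m[cl == k, , drop = FALSE]))
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= cor_threshold) return(cl)
    cl[cl == mods[best[2]]] <- mods[best[1]]
  }
}

.label_modules <- function(cl) {
  mods <- sort(unique(cl[cl != 0L]))
  sizes <- vapply(mods, function(k) sum(cl == k), integer(1))
  ord <- mods[order(-sizes)]
  labels <- rep(MODULE_COLORS, length.out = length(ord))
  out <- rep("grey", length(cl))
  for (i in seq_along(ord)) out[cl == ord[i]] <- labels[i]
  out
}

# First principal direction of a module across ROIs: genes standardized,
# first right-singular vector, unit norm, oriented so it correlates
# positively with the module's average standardized profile.
.eigengene <- function(sub) {
  z <- t(scale(t(sub)))
  if (nrow(sub) == 1L) {
    v <- z[1, ]
    return(v / sqrt(sum(v^2)))
  }
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (stats::cor(v, colMeans(z)) < 0) v <- -v
  v
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression across ROIs (unit norm, sign-oriented so it
#' correlates positively with the module's mean standardized profile).
#' A single-gene module's eigengene is its standardized profile. The
#' grey module gets no eigengene.
#'
#' @param matrix log2-stage target matrix.
#' @param assignment named module colors per gene (from
#'   [detect_modules()]).
#' @return list with `eigengenes` (ROIs x modules matrix),
#'   `var_explained` per module, and `membership` (gene x module Pearson
#'   correlation of expression with each eigengene).
#' @export
module_eigengenes <- function(matrix, assignment) {
  m <- .as_matrix(matrix)
  assignment <- assignment[rownames(m)]
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0L) stopf("module_eigengenes: no non-grey modules")
  mods <- mods[order(-vapply(mods, function(k) sum(assignment == k), integer(1)))]
  eg <- sapply(mods, function(k) .eigengene(m[assignment == k, , drop = FALSE]))
  rownames(eg) <- colnames(m)
  var_explained <- vapply(mods, function(k) {
    z <- t(scale(t(m[assignment == k, , drop = FALSE])))
    if (nrow(z) == 1L) return(1)
    d2 <- svd(z, nu = 0, nv = 0)$d^2
    d2[1] / sum(d2)
  }, 0)
  membership <- suppressWarnings(stats::cor(t(m), eg)) # NA for constant genes
  list(eigengenes = eg, var_explained = var_explained,
       membership = membership)
}

#' Pearson correlation p-value via the Student-t transform
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p from Student's t
#' with `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation(s).
#' @param n sample size.
#' @export
cor_pvalue_student <- function(r, n) {
  stopifnot(n >= 3)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and each ROI trait,
#' with two-sided Student-t p-values; optionally the same per-gene
#' association between expression and trait (for membership-vs-
#' significance scatter plots).
#'
#' @param eigengenes ROIs x modules eigengene matrix.
#' @param traits data.frame or matrix of numeric traits (rows = ROIs,
#'   aligned with the eigengene rows) or a single named vector.
#' @param matrix optional log2-stage expression matrix for the per-gene
#'   trait association.
#' @return list with `cor`, `p` (modules x traits), `degenerate` flags
#'   for constant traits, and optionally `gene_trait` (cor and p per
#'   gene x trait).
#' @export
module_trait_correlation <- function(eigengenes, traits, matrix = NULL) {
  eg <- as.matrix(eigengenes)
  n <- nrow(eg)
  if (n < 3L) stopf("module_trait_correlation: need >= 3 ROIs")
  if (is.null(dim(traits))) {
    tn <- deparse(substitute(traits))
    traits <- matrix(traits, ncol = 1,
                     dimnames = list(names(traits), tn))
  }
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) && !is.null(rownames(eg))) {
    traits <- traits[rownames(eg), , drop = FALSE]
  }
  degenerate <- apply(traits, 2, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(eg, traits))
  p <- cor_pvalue_student(cc, n)
  out <- list(cor = cc, p = p, degenerate = degenerate)
  if (!is.null(matrix)) {
    m <- .as_matrix(matrix)
    gc <- suppressWarnings(stats::cor(t(m), traits))
    out$gene_trait <- list(cor = gc, p = cor_pvalue_student(gc, n))
  }
  out
}

#' Per-module signal-to-noise summary
#'
#' Distribution of per-gene median S/N within each module (grey
#' included) with summary statistics. On well-normalized data the grey
#' (unassigned) module is expected to sit lowest.
#'
#' @param assignment named module colors per gene.
#' @param snr per-gene median S/N vector, or an S/N matrix (genes x ROIs,
#'   medians taken per gene).
#' @return data.frame: module, n_genes, median, mean, q25, q75 of the
#'   per-gene median S/N; per-gene values in attribute
#'   `"per_gene"`.
#' @export
module_snr_summary <- function(assignment, snr) {
  if (is.matrix(snr)) snr <- apply(snr, 1, stats::median)
  shared <- intersect(names(assignment), names(snr))
  assignment <- assignment[shared]
  snr <- snr[shared]
  mods <- unique(assignment)
  df <- do.call(rbind, lapply(mods, function(k) {
    v <- snr[assignment == k]
    data.frame(module = k, n_genes = length(v),
               median = stats::median(v), mean = mean(v),
               q25 = stats::quantile(v, 0.25, names = FALSE),
               q75 = stats::quantile(v, 0.75, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  attr(df, "per_gene") <- split(snr, assignment)
  df
}

#' Hypergeometric gene-set overlap test for modules
#'
#' Plain one-sided hypergeometric enrichment of each marker set within
#' each module, against the universe of assigned genes. A lightweight
#' substitute for curated pathway analysis tools.
#'
#' @param assignment named module colors per gene.
#' @param markers marker gene sets (list of character vectors).
#' @return data.frame: module, set, overlap, module_size, set_size, p.
#' @export
module_geneset_enrichment <- function(assignment, markers) {
  universe <- names(assignment)
  rows <- list()
  for (mod in unique(assignment)) {
    in_mod <- universe[assignment == mod]
    for (set_name in names(markers)) {
      set_genes <- intersect(markers[[set_name]], universe)
      ov <- length(intersect(in_mod, set_genes))
      p <- stats::phyper(ov - 1L, length(set_genes),
                         length(universe) - length(set_genes),
                         length(in_mod), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(module = mod, set = set_name, overlap = ov,
                   module_size = length(in_mod),
                   set_size = length(set_genes), p = p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full network stage
#'
#' @param matrix log2-stage target matrix.
#' @param traits numeric trait data (rows = ROIs) or named vector.
#' @param params [network_params()].
#' @param snr optional per-gene median S/N for the module summary.
#' @return list of class `network_result`: power, fit table, adjacency
#'   power used, module assignment, eigengenes, membership, trait
#'   correlations, and per-module S/N summary when `snr` given.
#' @export
run_network <- function(matrix, traits = NULL, params = network_params(),
                        snr = NULL) {
  m <- .as_matrix(matrix)
  v <- apply(m, 1, stats::var)
  dropped <- rownames(m)[v == 0]
  if (length(dropped) > 0L) {
    # constant profiles (e.g. heavily floored low counts) carry no
    # correlation information; excluded from the network
    m <- m[v > 0, , drop = FALSE]
  }
  sel <- pick_soft_threshold(m, params)
  adj <- signed_adjacency(m, sel$power)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(1 - tom, params, matrix = m)
  if (all(assignment == "grey")) {
    # weakly modular data: nothing rose above min_module_size
    eg <- list(eigengenes = NULL, var_explained = NULL, membership = NULL)
    trait_cor <- NULL
  } else {
    eg <- module_eigengenes(m, assignment)
    trait_cor <- if (!is.null(traits)) {
      module_trait_correlation(eg$eigengenes, traits, matrix = m)
    } else NULL
  }
  snr_summary <- if (!is.null(snr)) module_snr_summary(assignment, snr) else NULL
  structure(list(power = sel$power, fit_table = sel$fit_table,
                 assignment = assignment, eigengenes = eg$eigengenes,
                 var_explained = eg$var_explained,
                 membership = eg$membership,
                 trait_correlation = trait_cor,
                 snr_summary = snr_summary, params = params,
                 dropped_genes = dropped),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  n_mod <- if (is.null(x$eigengenes)) 0L else ncol(x$eigengenes)
  cat(sprintf("network_result: power %d, %d modules (+ grey: %d genes)\n",
              x$power, n_mod, sum(x$assignment == "grey")))
  print(sort(table(x$assignment), decreasing = TRUE))
  invisible(x)
}
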