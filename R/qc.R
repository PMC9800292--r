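#' @title Probe, ROI and target quality control
#' @description The fixed filter cascade applied to raw probe counts:
#'   low-count probe filter, global outlier probe filter, Grubbs outlier
#'   probe filter, ROI spike-in filter, geometric-mean target collapse,
#'   per-ROI limit of quantification (LOQ) and the LOQ-based target
#'   filter; plus the signal-to-noise statistics that diagnose the
#'   platform's group-differential bias.
#' @name qc
NULL

#' Quality-control parameters
#'
#' @param low_count_threshold counts at or below this are "low" (default 5).
#' @param low_count_max_rois a probe is excluded when it is low in strictly
#'   more than this many ROIs (default 2).
#' @param global_outlier_ratio minimum allowed ratio of a probe's
#'   geometric mean to its target's overall geometric mean (default 0.1,
#'   strict "below" excludes).
#' @param grubbs_alpha two-sided significance level of the per-(target,
#'   ROI) Grubbs test (default 0.05).
#' @param grubbs_roi_fraction a probe is excluded when flagged as the
#'   Grubbs outlier in strictly more than this fraction of ROIs
#'   (default 0.2).
#' @param roi_spikein_min_geomean ROIs whose negative-probe geometric mean
#'   is strictly below this are excluded (default 10).
#' @param loq_sd_multiplier number of (geometric) standard deviations above
#'   the negative-probe geometric mean defining the LOQ (default 2).
#' @param low_count_rule `"literal"` (default) excludes a probe low in more
#'   than `low_count_max_rois` ROIs; `"inverted"` keeps a probe only when
#'   it exceeds the threshold in more than `low_count_max_rois` ROIs (the
#'   alternative reading of the manufacturer rule).
#' @param exempt_negative_probes negative probes are exempt from the
#'   low-count filter by default (removing low background probes would
#'   bias the LOQ upward).
#' @param loq_mode `"geometric"` (default): LOQ = geomean * GSD^multiplier;
#'   `"arithmetic"`: LOQ = geomean + multiplier * sd of the raw counts.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(low_count_threshold = 5,
                      low_count_max_rois = 2,
                      global_outlier_ratio = 0.1,
                      grubbs_alpha = 0.05,
                      grubbs_roi_fraction = 0.2,
                      roi_spikein_min_geomean = 10,
                      loq_sd_multiplier = 2,
                      low_count_rule = c("literal", "inverted"),
                      exempt_negative_probes = TRUE,
                      loq_mode = c("geometric", "arithmetic")) {
  p <- list(low_count_threshold = low_count_threshold,
            low_count_max_rois = low_count_max_rois,
            global_outlier_ratio = global_outlier_ratio,
            grubbs_alpha = grubbs_alpha,
            grubbs_roi_fraction = grubbs_roi_fraction,
            roi_spikein_min_geomean = roi_spikein_min_geomean,
            loq_sd_multiplier = loq_sd_multiplier,
            low_count_rule = match.arg(low_count_rule),
            exempt_negative_probes = isTRUE(exempt_negative_probes),
            loq_mode = match.arg(loq_mode))
  if (p$low_count_threshold <= 0 || p$global_outlier_ratio <= 0 ||
      p$roi_spikein_min_geomean <= 0 || p$loq_sd_multiplier <= 0) {
    stopf("qc_params: thresholds must be positive")
  }
  if (p$grubbs_alpha <= 0 || p$grubbs_alpha >= 1 ||
      p$grubbs_roi_fraction <= 0 || p$grubbs_roi_fraction >= 1) {
    stopf("qc_params: grubbs_alpha and grubbs_roi_fraction must be in (0,1)")
  }
  class(p) <- "qc_params"
  p
}

.subset_probes <- function(table, keep) {
  probe_counts(table$counts[keep, , drop = FALSE],
               table$probes$target_id[keep],
               table$probes$probe_class[keep])
}

.exclusion_df <- function(ids, reason, what = "probe_id") {
  df <- data.frame(id = as.character(ids), reason = rep(reason, length(ids)),
                   stringsAsFactors = FALSE)
  names(df)[1] <- what
  df
}

#' Low-count probe filter
#'
#' Under the literal rule a target probe is excluded when its count fails
#' to exceed `low_count_threshold` in strictly more than
#' `low_count_max_rois` ROIs. Negative probes are exempt unless
#' `exempt_negative_probes` is disabled.
#'
#' @param table a [probe_counts] object.
#' @param params a [qc_params()] list.
#' @return list with the filtered `table` and an `excluded` data.frame
#'   (`probe_id`, `reason`).
#' @export
filter_low_count_probes <- function(table, params = qc_params()) {
  stopifnot(inherits(table, "probe_counts"))
  low <- table$counts <= params$low_count_threshold
  n_low <- rowSums(low)
  if (params$low_count_rule == "literal") {
    drop <- n_low > params$low_count_max_rois
  } else {
    n_high <- ncol(table$counts) - n_low
    drop <- !(n_high > params$low_count_max_rois)
  }
  if (params$exempt_negative_probes) {
    drop <- drop & table$probes$probe_class == "target"
  }
  list(table = .subset_probes(table, !drop),
       excluded = .exclusion_df(table$probes$probe_id[drop], "low_count"))
}

#' Global outlier probe filter
#'
#' A target probe is excluded when the ratio of its geometric mean over
#' all ROIs to the geometric mean of all counts of its target (over all
#' probes and ROIs) falls strictly below `global_outlier_ratio`. Zero
#' counts are lifted to 1 before log-space operations.
#'
#' @inheritParams filter_low_count_probes
#' @export
global_outlier_filter <- function(table, params = qc_params()) {
  stopifnot(inherits(table, "probe_counts"))
  counts <- lift_counts(table$counts)
  logc <- log(counts)
  probe_geo <- exp(rowMeans(logc))
  is_target <- table$probes$probe_class == "target"
  target_geo <- exp(tapply(rowMeans(logc), table$probes$target_id, mean))
  # target geomean over all probes x ROIs: probes may differ only via equal
  # ROI count, so mean of per-probe log-means is the grand log-mean
  ratio <- probe_geo / as.numeric(target_geo[table$probes$target_id])
  drop <- is_target & ratio < params$global_outlier_ratio
  list(table = .subset_probes(table, !drop),
       excluded = .exclusion_df(table$probes$probe_id[drop], "global_outlier"))
}

#' Two-sided Grubbs critical value
#'
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the
#' upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees of
#' freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Grubbs outlier probe filter
#'
#' Within each (target, ROI) cell with at least 3 probes, the most extreme
#' probe count is tested with the two-sided Grubbs statistic
#' `G = max|x - mean| / sd`; the extreme probe is flagged when `G` exceeds
#' the critical value at `grubbs_alpha`. A probe is excluded when it is
#' flagged in strictly more than `grubbs_roi_fraction` of ROIs. Cells with
#' zero spread flag nothing; one pass only (no iterative removal).
#'
#' @inheritParams filter_low_count_probes
#' @export
grubbs_outlier_filter <- function(table, params = qc_params()) {
  stopifnot(inherits(table, "probe_counts"))
  is_target <- table$probes$probe_class == "target"
  n_rois <- ncol(table$counts)
  flags <- integer(nrow(table$counts))
  idx_by_target <- split(which(is_target), table$probes$target_id[is_target])
  for (idx in idx_by_target) {
    n <- length(idx)
    if (n < 3L) next
    x <- table$counts[idx, , drop = FALSE]
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    dev <- abs(sweep(x, 2, mu))
    gmax <- apply(dev, 2, max) / sdv
    crit <- grubbs_critical(n, params$grubbs_alpha)
    hit <- which(sdv > 0 & gmax > crit)
    if (length(hit) > 0L) {
      extreme <- apply(dev[, hit, drop = FALSE], 2, which.max)
      tab <- tabulate(extreme, nbins = n)
      flags[idx] <- flags[idx] + tab
    }
  }
  drop <- flags / n_rois > params$grubbs_roi_fraction
  list(table = .subset_probes(table, !drop),
       excluded = .exclusion_df(table$probes$probe_id[drop], "grubbs"),
       flag_counts = stats::setNames(flags, table$probes$probe_id))
}

#' ROI spike-in filter
#'
#' An ROI is excluded when the geometric mean of its negative-probe counts
#' falls strictly below `roi_spikein_min_geomean`.
#'
#' @inheritParams filter_low_count_probes
#' @return list with the ROI-filtered `table` and `excluded` data.frame
#'   (`roi_id`, `reason`).
#' @export
filter_rois_by_spikein <- function(table, params = qc_params()) {
  stopifnot(inherits(table, "probe_counts"))
  neg <- table$probes$probe_class == "negative"
  if (!any(neg)) stopf("filter_rois_by_spikein: table has no negative probes")
  neg_counts <- lift_counts(table$counts[neg, , drop = FALSE])
  geo <- exp(colMeans(log(neg_counts)))
  drop <- geo < params$roi_spikein_min_geomean
  out <- table
  out$counts <- table$counts[, !drop, drop = FALSE]
  list(table = out,
       excluded = .exclusion_df(colnames(table$counts)[drop],
                                "low_spikein_geomean", "roi_id"))
}

#' Collapse probes to target values
#'
#' The value of a target in an ROI is the geometric mean of its surviving
#' probes' counts in that ROI (zeros lifted to 1). Targets with zero
#' surviving probes are dropped and reported.
#'
#' @param table a filtered [probe_counts] object.
#' @return list with `matrix` (collapsed-stage target matrix) and
#'   `dropped_targets`.
#' @export
collapse_targets <- function(table) {
  stopifnot(inherits(table, "probe_counts"))
  is_target <- table$probes$probe_class == "target"
  logc <- log(lift_counts(table$counts[is_target, , drop = FALSE]))
  tid <- table$probes$target_id[is_target]
  m <- exp(rowsum(logc, tid) / as.vector(table(tid)[sort(unique(tid))]))
  m <- m[order(rownames(m)), , drop = FALSE]
  list(matrix = target_matrix(m, "collapsed"),
       dropped_targets = character(0))
}

#' Per-ROI limit of quantification
#'
#' For each ROI: the geometric mean and geometric standard deviation
#' (`exp(sd(log counts))`, sample sd) of the negative-probe counts, and
#' the LOQ. Geometric mode (default): `LOQ = geomean * GSD^multiplier`;
#' arithmetic mode: `LOQ = geomean + multiplier * sd(counts)`.
#'
#' @inheritParams filter_low_count_probes
#' @return data.frame of class `roi_noise_stats` with columns `roi_id`,
#'   `neg_geomean`, `neg_gsd`, `loq`.
#' @export
compute_loq <- function(table, params = qc_params()) {
  stopifnot(inherits(table, "probe_counts"))
  neg <- table$probes$probe_class == "negative"
  if (sum(neg) < 2L) {
    stopf("compute_loq: at least 2 negative probes required per ROI")
  }
  neg_counts <- lift_counts(table$counts[neg, , drop = FALSE])
  logc <- log(neg_counts)
  geo <- exp(colMeans(logc))
  gsd <- exp(apply(logc, 2, stats::sd))
  loq <- if (params$loq_mode == "geometric") {
    geo * gsd^params$loq_sd_multiplier
  } else {
    geo + params$loq_sd_multiplier * apply(neg_counts, 2, stats::sd)
  }
  structure(data.frame(roi_id = colnames(table$counts),
                       neg_geomean = geo, neg_gsd = gsd, loq = loq,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("roi_noise_stats", "data.frame"))
}

#' LOQ-based target filter
#'
#' A target is kept iff its collapsed value exceeds the ROI's LOQ in at
#' least one ROI.
#'
#' @param matrix collapsed-stage target matrix.
#' @param stats a `roi_noise_stats` data.frame from [compute_loq()].
#' @return list with the filtered `matrix` and `excluded` data.frame.
#' @export
filter_targets_by_loq <- function(matrix, stats) {
  stopifnot(is.matrix(matrix), inherits(stats, "roi_noise_stats"))
  loq <- stats$loq[match(colnames(matrix), stats$roi_id)]
  if (anyNA(loq)) stopf("filter_targets_by_loq: ROI sets do not match")
  keep <- rowSums(sweep(matrix, 2, loq, ">")) > 0
  list(matrix = target_matrix(matrix[keep, , drop = FALSE],
                              matrix_stage(matrix)),
       excluded = .exclusion_df(rownames(matrix)[!keep], "below_loq",
                                "target_id"))
}

#' Signal-to-noise statistics
#'
#' `snr(g, r) = value(g, r) / LOQ(r)` on the collapsed-stage matrix. Also
#' returns the per-ROI median over targets, and (when groups are given)
#' the per-target median within each group plus their sum — the x-axis of
#' the bias diagnostic relating S/N to fold change.
#'
#' @param matrix collapsed-stage target matrix.
#' @param stats `roi_noise_stats` from [compute_loq()].
#' @param groups optional factor/character of group labels per ROI
#'   (two levels).
#' @return list with `snr` (matrix), `per_roi_median`, and when groups are
#'   supplied `group_medians` (targets x 2) and `snr_sum`.
#' @export
compute_snr <- function(matrix, stats, groups = NULL) {
  stopifnot(is.matrix(matrix), inherits(stats, "roi_noise_stats"))
  loq <- stats$loq[match(colnames(matrix), stats$roi_id)]
  if (anyNA(loq)) stopf("compute_snr: ROI sets do not match")
  snr <- sweep(matrix, 2, loq, "/")
  out <- list(snr = snr,
              per_roi_median = apply(snr, 2, stats::median))
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stopf("compute_snr: groups must have two levels")
    gm <- sapply(levels(groups), function(g) {
      apply(snr[, groups == g, drop = FALSE], 1, stats::median)
    })
    out$group_medians <- gm
    out$snr_sum <- rowSums(gm)
  }
  out
}

#' Run the full QC cascade
#'
#' Fixed order: low-count filter, global outlier filter, Grubbs filter,
#' ROI spike-in filter, target collapse, LOQ computation, LOQ target
#' filter. The report records every exclusion with its reason and the
#' survivor counts after each stage.
#'
#' @param table raw [probe_counts].
#' @param params [qc_params()].
#' @param groups optional per-ROI group labels (named by roi_id or in
#'   column order) passed through to [compute_snr()].
#' @param filter_rois apply the ROI spike-in filter (default TRUE).
#'   Disable when background levels are deliberately near the filter
#'   boundary and the downstream contrast needs both groups intact.
#' @return list of class `qc_result` with `matrix` (collapsed, LOQ
#'   filtered), `noise_stats`, `snr`, `report` and the filtered probe
#'   `table`.
#' @export
run_qc <- function(table, params = qc_params(), groups = NULL,
                   filter_rois = TRUE) {
  stopifnot(inherits(table, "probe_counts"))
  survivors <- c(input_probes = nrow(table$counts),
                 input_rois = ncol(table$counts))
  s1 <- filter_low_count_probes(table, params)
  s2 <- global_outlier_filter(s1$table, params)
  s3 <- grubbs_outlier_filter(s2$table, params)
  s4 <- if (filter_rois) {
    filter_rois_by_spikein(s3$table, params)
  } else {
    list(table = s3$table,
         excluded = .exclusion_df(character(0), character(0), "roi_id"))
  }
  collapsed <- collapse_targets(s4$table)
  noise <- compute_loq(s4$table, params)
  s5 <- filter_targets_by_loq(collapsed$matrix, noise)
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      groups <- groups[colnames(s5$matrix)]
    } else {
      groups <- groups[match(colnames(s5$matrix), colnames(table$counts))]
    }
  }
  snr <- compute_snr(s5$matrix, noise, groups)
  noise$median_snr <- snr$per_roi_median[noise$roi_id]
  report <- list(
    excluded_probes = rbind(s1$excluded, s2$excluded, s3$excluded),
    excluded_rois = s4$excluded,
    excluded_targets = s5$excluded,
    survivors = c(survivors,
                  after_low_count = nrow(s1$table$counts),
                  after_global_outlier = nrow(s2$table$counts),
                  after_grubbs = nrow(s3$table$counts),
                  rois_after_spikein = ncol(s4$table$counts),
                  targets_collapsed = nrow(collapsed$matrix),
                  targets_after_loq = nrow(s5$matrix)))
  structure(list(matrix = s5$matrix, noise_stats = noise, snr = snr,
                 report = report, table = s4$table, params = params),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  s <- x$report$survivors
  cat("GeoMx QC cascade\n")
  cat(sprintf("  probes: %d -> %d (low count) -> %d (global outlier) -> %d (Grubbs)\n",
              s["input_probes"], s["after_low_count"],
              s["after_global_outlier"], s["after_grubbs"]))
  cat(sprintf("  ROIs: %d -> %d (spike-in geomean)\n",
              s["input_rois"], s["rois_after_spikein"]))
  cat(sprintf("  targets: %d collapsed -> %d above LOQ\n",
              s["targets_collapsed"], s["targets_after_loq"]))
  invisible(x)
}
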