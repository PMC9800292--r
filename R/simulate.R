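#' @title Probe-count simulator with group-differential signal-to-noise
#' @description Generates GeoMx-like probe-level datasets with known ground
#'   truth. The central emulated artifact is a systematic signal-to-noise
#'   difference between the two sample groups: one group receives both a
#'   higher per-ROI background level and a lower capture efficiency, which
#'   biases third-quartile normalized differential expression and is
#'   removed by rank-based normalization.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate a cancer-transcriptome-atlas-scale run: ~1800 targets
#' measured by 3-5 probes each plus 88 ERCC-derived negative-control
#' probes, two groups of ROIs, and an ROI trait (T-cell count) driving a
#' planted co-expression module.
#'
#' @param n_targets number of target genes.
#' @param probes_per_target_range integer pair; probes per target are drawn
#'   uniformly from this range (must lie within 1..10).
#' @param n_negative_probes number of negative-control probes.
#' @param n_rois_per_group ROIs per group.
#' @param group_labels two condition names.
#' @param baseline_log_expr_mean,baseline_log_expr_sd natural-log mean and
#'   sd of per-target baseline expression (log-normal across targets).
#' @param background_mean_by_group expected per-ROI background count, one
#'   positive value per group. Unequal values create the group-differential
#'   signal-to-noise structure.
#' @param efficiency_log_sd log-sd of the per-ROI capture efficiency.
#' @param probe_efficiency_log_sd log-sd of per-probe efficiency.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); shared across probes.
#' @param n_de_targets number of planted differentially expressed targets.
#' @param de_log2fc planted absolute log2 fold change (signs alternate).
#' @param n_module_targets number of targets in the planted
#'   trait-correlated module.
#' @param module_trait_name name of the ROI trait column.
#' @param trait_poisson_mean Poisson mean of the per-ROI trait counts.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_targets = 1800L,
                              probes_per_target_range = c(3L, 5L),
                              n_negative_probes = 88L,
                              n_rois_per_group = 20L,
                              group_labels = c("primary", "recurrent"),
                              baseline_log_expr_mean = log(50),
                              baseline_log_expr_sd = 1.2,
                              background_mean_by_group = c(30, 10),
                              efficiency_log_sd = 0.3,
                              probe_efficiency_log_sd = 0.25,
                              nb_dispersion = 0.15,
                              n_de_targets = 50L,
                              de_log2fc = 1,
                              n_module_targets = 50L,
                              module_trait_name = "t_cell_count",
                              trait_poisson_mean = 15,
                              seed = 1L) {
  cfg <- list(n_targets = as.integer(n_targets),
              probes_per_target_range = as.integer(probes_per_target_range),
              n_negative_probes = as.integer(n_negative_probes),
              n_rois_per_group = as.integer(n_rois_per_group),
              group_labels = as.character(group_labels),
              baseline_log_expr_mean = baseline_log_expr_mean,
              baseline_log_expr_sd = baseline_log_expr_sd,
              background_mean_by_group = as.numeric(background_mean_by_group),
              efficiency_log_sd = efficiency_log_sd,
              probe_efficiency_log_sd = probe_efficiency_log_sd,
              nb_dispersion = nb_dispersion,
              n_de_targets = as.integer(n_de_targets),
              de_log2fc = de_log2fc,
              n_module_targets = as.integer(n_module_targets),
              module_trait_name = as.character(module_trait_name),
              trait_poisson_mean = trait_poisson_mean,
              seed = as.integer(seed))
  .check_field <- function(ok, field, msg) {
    if (!ok) stopf("invalid simulation config field '%s': %s", field, msg)
  }
  .check_field(cfg$n_targets >= 1L, "n_targets", "must be >= 1")
  .check_field(length(cfg$probes_per_target_range) == 2L &&
                 all(cfg$probes_per_target_range >= 1L) &&
                 all(cfg$probes_per_target_range <= 10L) &&
                 cfg$probes_per_target_range[1] <= cfg$probes_per_target_range[2],
               "probes_per_target_range", "must be an ordered pair within [1, 10]")
  .check_field(cfg$n_negative_probes >= 2L, "n_negative_probes",
               "must be >= 2 (LOQ needs a spread)")
  .check_field(cfg$n_rois_per_group >= 1L, "n_rois_per_group", "must be >= 1")
  .check_field(length(cfg$group_labels) == 2L &&
                 !anyDuplicated(cfg$group_labels), "group_labels",
               "must be two distinct condition names")
  .check_field(length(cfg$background_mean_by_group) == 2L &&
                 all(cfg$background_mean_by_group > 0),
               "background_mean_by_group", "must be two positive values")
  .check_field(cfg$baseline_log_expr_sd >= 0, "baseline_log_expr_sd", "must be >= 0")
  .check_field(cfg$efficiency_log_sd >= 0, "efficiency_log_sd", "must be >= 0")
  .check_field(cfg$probe_efficiency_log_sd >= 0, "probe_efficiency_log_sd",
               "must be >= 0")
  .check_field(cfg$nb_dispersion > 0, "nb_dispersion", "must be > 0")
  .check_field(cfg$n_de_targets >= 0L, "n_de_targets", "must be >= 0")
  .check_field(cfg$n_module_targets >= 0L, "n_module_targets", "must be >= 0")
  .check_field(cfg$n_de_targets + cfg$n_module_targets <= cfg$n_targets,
               "n_de_targets", "n_de_targets + n_module_targets must be <= n_targets")
  .check_field(cfg$trait_poisson_mean > 0, "trait_poisson_mean", "must be > 0")
  .check_field(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed",
               "must be a single integer")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a probe-level GeoMx-like dataset
#'
#' Count model: for probe p of target g in ROI r,
#' `count ~ NegBin(mean = s_r * e_p * mu_g * 2^(delta_g * group_r) + b_r,
#' dispersion)`, where `s_r` is ROI capture efficiency, `e_p` probe
#' efficiency, `mu_g` baseline expression, `delta_g` the planted log2 fold
#' change and `b_r` the ROI background level. Negative probes draw from
#' `NegBin(mean = b_r, dispersion)`. Module targets have `mu_g` scaled by
#' `(1 + trait_r / trait_poisson_mean)` per ROI. Counts are floored at 1 so
#' log2 transformation never needs a pseudocount.
#'
#' The group-differential signal-to-noise structure enters jointly through
#' `background_mean_by_group` and capture efficiency: the higher-background
#' group also receives proportionally lower mean efficiency
#' (`s_r` centered at `sqrt(b_other / b_own)` on the ratio scale), so its
#' control probes run high while its target probes run low.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `counts` (a [probe_counts] table),
#'   `annotations` (an ROI annotation data.frame with group and trait) and
#'   `truth` (planted log2 fold changes, module target ids, trait values
#'   and the latent per-ROI background `b_r`, efficiency `s_r` and
#'   per-probe efficiency `e_p`).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  cfg <- config
  set.seed(cfg$seed)

  n_rois <- 2L * cfg$n_rois_per_group
  group <- rep(cfg$group_labels, each = cfg$n_rois_per_group)
  group01 <- rep(c(0, 1), each = cfg$n_rois_per_group)
  roi_id <- sprintf("ROI_%03d", seq_len(n_rois))
  # ~6 ROIs per sample, samples nested in group (replicate-free)
  sample_idx <- ceiling(seq_len(cfg$n_rois_per_group) / 6)
  sample_id <- paste0(group, "_S", rep(sample_idx, 2L))
  patient_id <- sub("^.*_S", "P", sample_id)

  # per-ROI latent state
  bg_mean <- cfg$background_mean_by_group[group01 + 1L]
  b_r <- stats::rlnorm(n_rois, meanlog = log(bg_mean) - 0.2^2 / 2, sdlog = 0.2)
  # efficiency centered so groups are symmetric when backgrounds are equal
  eff_center <- -0.5 * (log(bg_mean) - mean(log(cfg$background_mean_by_group)))
  s_r <- stats::rlnorm(n_rois,
                       meanlog = eff_center - cfg$efficiency_log_sd^2 / 2,
                       sdlog = cfg$efficiency_log_sd)
  trait_r <- stats::rpois(n_rois, cfg$trait_poisson_mean)

  # per-target latent state
  target_id <- sprintf("GENE%04d", seq_len(cfg$n_targets))
  mu_g <- stats::rlnorm(cfg$n_targets, cfg$baseline_log_expr_mean,
                        cfg$baseline_log_expr_sd)
  delta_g <- numeric(cfg$n_targets)
  de_idx <- seq_len(cfg$n_de_targets)
  if (cfg$n_de_targets > 0L) {
    delta_g[de_idx] <- cfg$de_log2fc * rep_len(c(1, -1), cfg$n_de_targets)
  }
  module_idx <- if (cfg$n_module_targets > 0L) {
    cfg$n_de_targets + seq_len(cfg$n_module_targets)
  } else integer(0)

  # probes
  rng <- cfg$probes_per_target_range
  probes_per_target <- if (rng[1] == rng[2]) {
    rep(rng[1], cfg$n_targets)
  } else {
    sample(seq(rng[1], rng[2]), cfg$n_targets, replace = TRUE)
  }
  probe_target_idx <- rep(seq_len(cfg$n_targets), probes_per_target)
  n_target_probes <- length(probe_target_idx)
  probe_id <- paste0(target_id[probe_target_idx], "_P",
                     unlist(lapply(probes_per_target, seq_len)))
  e_p <- stats::rlnorm(n_target_probes,
                       -cfg$probe_efficiency_log_sd^2 / 2,
                       cfg$probe_efficiency_log_sd)

  # mean matrix for target probes: probes x ROIs
  mu_target_roi <- (mu_g %o% rep(1, n_rois)) * 2^(delta_g %o% group01)
  if (length(module_idx) > 0L) {
    mod_scale <- 1 + trait_r / cfg$trait_poisson_mean
    mu_target_roi[module_idx, ] <-
      mu_target_roi[module_idx, , drop = FALSE] *
      rep(mod_scale, each = length(module_idx))
  }
  mean_mat <- (e_p * mu_target_roi[probe_target_idx, , drop = FALSE]) %*%
    diag(s_r, n_rois) + rep(b_r, each = n_target_probes)

  size <- 1 / cfg$nb_dispersion
  counts_target <- matrix(
    stats::rnbinom(length(mean_mat), mu = as.vector(mean_mat), size = size),
    nrow = n_target_probes, ncol = n_rois)
  counts_neg <- matrix(
    stats::rnbinom(cfg$n_negative_probes * n_rois,
                   mu = rep(b_r, each = cfg$n_negative_probes), size = size),
    nrow = cfg$n_negative_probes, ncol = n_rois)

  counts <- rbind(pmax(counts_target, 1), pmax(counts_neg, 1))
  neg_ids <- sprintf("NegProbe_%03d", seq_len(cfg$n_negative_probes))
  rownames(counts) <- c(probe_id, neg_ids)
  colnames(counts) <- roi_id

  tbl <- probe_counts(
    counts,
    target_id = c(target_id[probe_target_idx],
                  rep(NEG_TARGET_SENTINEL, cfg$n_negative_probes)),
    probe_class = c(rep("target", n_target_probes),
                    rep("negative", cfg$n_negative_probes)))

  ann <- data.frame(roi_id = roi_id, sample_id = sample_id,
                    patient_id = patient_id, group = group,
                    stringsAsFactors = FALSE)
  ann[[cfg$module_trait_name]] <- trait_r
  class(ann) <- c("roi_annotations", "data.frame")

  truth <- list(
    de_targets = data.frame(target_id = target_id[de_idx],
                            log2fc = delta_g[de_idx],
                            stringsAsFactors = FALSE),
    module_targets = target_id[module_idx],
    trait = stats::setNames(trait_r, roi_id),
    background = stats::setNames(b_r, roi_id),
    roi_efficiency = stats::setNames(s_r, roi_id),
    probe_efficiency = stats::setNames(e_p, probe_id),
    seed = cfg$seed)

  list(counts = tbl, annotations = ann, truth = truth, config = cfg)
}

#' Simulate a modular expression matrix with planted co-expression blocks
#'
#' Companion generator for the network stage: log2-scale expression for
#' `n_modules` blocks of correlated genes driven by shared latent ROI
#' factors, plus independent noise genes. Module genes are given higher
#' baseline expression than noise genes, so when signal-to-noise is
#' computed against a common limit of quantification, unassigned noise
#' genes sit lowest — the pattern expected of a catch-all grey module.
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module genes per module.
#' @param n_noise_genes number of unstructured genes.
#' @param n_rois number of ROIs.
#' @param module_cor within-module correlation strength in (0,1); the
#'   shared-factor loading is `sqrt(module_cor)`.
#' @param module_log2_baseline,noise_log2_baseline mean log2 expression of
#'   module and noise genes.
#' @param seed integer seed.
#' @return list with `matrix` (genes x ROIs, log2 stage), `assignment`
#'   (true module index per gene, 0 = noise) and `snr` (per-gene median
#'   signal-to-noise against a unit LOQ reference).
#' @export
simulate_module_matrix <- function(n_modules = 3L, genes_per_module = 50L,
                                   n_noise_genes = 150L, n_rois = 40L,
                                   module_cor = 0.7,
                                   module_log2_baseline = 7,
                                   noise_log2_baseline = 3,
                                   seed = 1L) {
  stopifnot(n_modules >= 1L, genes_per_module >= 2L, n_rois >= 4L,
            module_cor > 0, module_cor < 1)
  set.seed(seed)
  n_genes <- n_modules * genes_per_module + n_noise_genes
  load <- sqrt(module_cor)
  factors <- matrix(stats::rnorm(n_modules * n_rois), n_modules, n_rois)
  rows <- vector("list", n_genes)
  assignment <- integer(n_genes)
  g <- 0L
  for (m in seq_len(n_modules)) {
    for (k in seq_len(genes_per_module)) {
      g <- g + 1L
      assignment[g] <- m
      rows[[g]] <- module_log2_baseline +
        load * factors[m, ] + sqrt(1 - module_cor) * stats::rnorm(n_rois)
    }
  }
  for (k in seq_len(n_noise_genes)) {
    g <- g + 1L
    assignment[g] <- 0L
    rows[[g]] <- noise_log2_baseline + stats::rnorm(n_rois)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- sprintf("GENE%04d", seq_len(n_genes))
  colnames(mat) <- sprintf("ROI_%03d", seq_len(n_rois))
  snr_mat <- 2^mat # against unit LOQ
  list(matrix = target_matrix(mat, "log2(simulated)"),
       assignment = stats::setNames(assignment, rownames(mat)),
       snr = apply(snr_mat, 1, stats::median))
}
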