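#' @title End-to-end pipeline orchestration
#' @description One-config runs of the full workflow — simulate (or read)
#'   probe counts, QC cascade, the five normalizations, benchmarking,
#'   differential expression, network analysis — with every stage's
#'   outputs written to disk and a manifest recording parameters, seed
#'   and file hashes for reproducibility.
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' @param counts_path,annotations_path paths to input tables; leave NULL
#'   to simulate instead.
#' @param simulation a [simulation_config()] (or list of its arguments);
#'   used when no input paths are given.
#' @param qc a [qc_params()] list.
#' @param methods normalization methods to run.
#' @param group_column annotation column holding the two-group labels.
#' @param trait_columns annotation columns treated as numeric traits for
#'   the network stage.
#' @param dge_method,network_method which normalized matrix feeds the
#'   differential-expression and network stages (default quantile).
#' @param network a [network_params()] list, or NULL to skip the stage.
#' @param markers_path optional GMT file for benchmarking/enrichment.
#' @param reference_path optional reference expression matrix (TSV/CSV)
#'   for the biological benchmark criterion.
#' @param filter_rois apply the ROI spike-in filter in the QC stage
#'   (default TRUE; see [run_qc()]).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, annotations_path = NULL,
                            simulation = simulation_config(),
                            qc = qc_params(),
                            methods = c("q3", "cpm", "mor", "gamma", "quantile"),
                            group_column = "group",
                            trait_columns = "t_cell_count",
                            dge_method = "quantile",
                            network_method = "quantile",
                            network = network_params(),
                            markers_path = NULL,
                            reference_path = NULL,
                            filter_rois = TRUE,
                            seed = 1L) {
  if (length(methods) < 1L) stopf("pipeline_config: at least one method required")
  if (!dge_method %in% methods) stopf("pipeline_config: dge_method must be among methods")
  cfg <- list(counts_path = counts_path, annotations_path = annotations_path,
              simulation = simulation, qc = qc, methods = methods,
              group_column = group_column, trait_columns = trait_columns,
              dge_method = dge_method, network_method = network_method,
              network = network, markers_path = markers_path,
              reference_path = reference_path,
              filter_rois = isTRUE(filter_rois), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation`, `qc` and `network` keys take the corresponding
#' constructor arguments as nested maps.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulation)) raw$simulation <- do.call(simulation_config, raw$simulation)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_params, raw$qc)
  if (!is.null(raw$network)) raw$network <- do.call(network_params, raw$network)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Stage order: input (simulate or read), QC cascade, normalization per
#' method (+ log2), benchmark, differential expression, network. Each
#' stage writes its outputs under `out_dir` before the next starts; a
#' failing stage aborts with its name while earlier outputs are kept.
#' Identical config and seed reproduce identical file hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the run manifest (also written as `manifest.json`), listing
#'   per-stage outputs with md5 hashes, the seed and package version.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "geomxnorm",
                   version = as.character(utils::packageVersion("geomxnorm")),
                   seed = config$seed, stages = list())
  outputs <- character(0)
  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (outputs so far kept in %s)",
            name, conditionMessage(e), out_dir)
    })
  }

  # --- input ---
  if (!is.null(config$counts_path)) {
    tbl <- .stage("input", read_probe_counts(config$counts_path))
    ann <- .stage("input", read_annotations(config$annotations_path))
  } else {
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    sim <- .stage("simulate", simulate_dataset(sim_cfg))
    tbl <- sim$counts
    ann <- sim$annotations
    write_probe_counts(tbl, file.path(out_dir, "simulated_counts.tsv"))
    write_annotations(ann, file.path(out_dir, "simulated_annotations.tsv"))
    outputs <- c(outputs, "simulated_counts.tsv", "simulated_annotations.tsv")
  }
  groups <- stats::setNames(ann[[config$group_column]], ann$roi_id)
  if (is.null(groups)) stopf("annotation column '%s' not found", config$group_column)

  # --- qc ---
  qc_res <- .stage("qc", run_qc(tbl, config$qc, groups,
                                filter_rois = config$filter_rois))
  write_target_matrix(qc_res$matrix, file.path(out_dir, "collapsed.csv"))
  utils::write.csv(qc_res$noise_stats, file.path(out_dir, "roi_noise_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(qc_res$report$excluded_probes,
                   file.path(out_dir, "qc_excluded_probes.csv"), row.names = FALSE)
  outputs <- c(outputs, "collapsed.csv", "roi_noise_stats.csv",
               "qc_excluded_probes.csv")

  # --- normalization ---
  norm <- list()
  for (method in config$methods) {
    norm[[method]] <- .stage(paste0("normalize:", method),
                             suppressWarnings(normalize_matrix(qc_res$matrix, method)))
    f <- sprintf("normalized_%s.csv", method)
    write_target_matrix(norm[[method]]$matrix, file.path(out_dir, f))
    outputs <- c(outputs, f)
  }

  # --- benchmark ---
  markers <- if (!is.null(config$markers_path)) read_gmt(config$markers_path) else NULL
  reference <- if (!is.null(config$reference_path)) {
    read_target_matrix(config$reference_path, stage = "reference")
  } else NULL
  bench <- .stage("benchmark",
                  run_benchmark(qc_res$matrix, groups, qc_res$noise_stats,
                                methods = config$methods,
                                markers = markers, reference = reference))
  utils::write.csv(bench$ranking, file.path(out_dir, "benchmark_ranking.csv"),
                   row.names = FALSE)
  outputs <- c(outputs, "benchmark_ranking.csv")

  # --- differential expression ---
  dge <- .stage("dge", wilcoxon_dge(norm[[config$dge_method]]$matrix, groups))
  utils::write.csv(dge, file.path(out_dir, "dge.csv"), row.names = FALSE)
  outputs <- c(outputs, "dge.csv")

  # --- network ---
  net <- NULL
  if (!is.null(config$network) && config$network_method %in% names(norm)) {
    trait_cols <- intersect(config$trait_columns, names(ann))
    traits <- if (length(trait_cols) > 0L) {
      tm <- as.matrix(ann[trait_cols])
      rownames(tm) <- ann$roi_id
      tm[colnames(qc_res$matrix), , drop = FALSE]
    } else NULL
    snr_gene <- apply(qc_res$snr$snr, 1, stats::median)
    net <- .stage("network",
                  run_network(norm[[config$network_method]]$matrix,
                              traits = traits, params = config$network,
                              snr = snr_gene))
    utils::write.csv(data.frame(target_id = names(net$assignment),
                                module = as.vector(net$assignment)),
                     file.path(out_dir, "modules.csv"), row.names = FALSE)
    outputs <- c(outputs, "modules.csv")
    if (!is.null(net$eigengenes)) {
      utils::write.csv(data.frame(roi_id = rownames(net$eigengenes),
                                  net$eigengenes, check.names = FALSE),
                       file.path(out_dir, "eigengenes.csv"), row.names = FALSE)
      outputs <- c(outputs, "eigengenes.csv")
    }
    if (!is.null(net$trait_correlation)) {
      utils::write.csv(data.frame(module = rownames(net$trait_correlation$cor),
                                  cor = net$trait_correlation$cor,
                                  p = net$trait_correlation$p,
                                  check.names = FALSE),
                       file.path(out_dir, "module_trait_correlation.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, "module_trait_correlation.csv")
    }
  }

  hashes <- tools::md5sum(file.path(out_dir, outputs))
  manifest$stages <- list(files = stats::setNames(as.vector(hashes), outputs))
  manifest$benchmark_ranking <- bench$ranking
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(list(manifest = manifest, qc = qc_res,
                           normalized = norm, benchmark = bench,
                           dge = dge, network = net),
                      class = "pipeline_result"))
}
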