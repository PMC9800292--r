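# Shared fixture builders for the test suite. All fixtures are built in
# code; nothing is read from disk except round-trip temp files.

# Minimal probe table: counts matrix plus per-probe target/class vectors.
make_probe_table <- function(counts, target_id, probe_class = NULL) {
  if (is.null(probe_class)) {
    probe_class <- ifelse(target_id == "NegProbe", "negative", "target")
  }
  probe_counts(counts, target_id, probe_class)
}

# 6 probes (2 targets x 2 probes + 2 negatives) x 3 ROIs, all positive.
small_table <- function() {
  counts <- matrix(c(10, 20, 30,
                     12, 22, 32,
                     100, 200, 300,
                     110, 210, 310,
                     5, 6, 7,
                     4, 5, 8),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(c("A_P1", "A_P2", "B_P1", "B_P2",
                                     "NEG1", "NEG2"),
                                   c("R1", "R2", "R3")))
  make_probe_table(counts, c("A", "A", "B", "B", "NegProbe", "NegProbe"),
                   c("target", "target", "target", "target",
                     "negative", "negative"))
}

# Fast simulator config for unit tests; any field can be overridden.
tiny_sim <- function(..., seed = 1L) {
  defaults <- list(n_targets = 120L, probes_per_target_range = c(3L, 4L),
                   n_negative_probes = 20L, n_rois_per_group = 8L,
                   n_de_targets = 10L, n_module_targets = 10L, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# The acceptance bias world: probe cascade + collapse + LOQ, ROI spike-in
# filter off (background mean 10 sits below the filter boundary by
# construction; both groups must stay intact for the contrast).
acceptance_world <- function(seed, n_de_targets = 50L, de_log2fc = 1,
                             background = c(30, 10), n_targets = 1500L) {
  cfg <- simulation_config(n_targets = n_targets,
                           probes_per_target_range = c(4L, 4L),
                           n_negative_probes = 88L,
                           n_rois_per_group = 20L,
                           background_mean_by_group = background,
                           n_de_targets = n_de_targets,
                           de_log2fc = de_log2fc,
                           n_module_targets = 0L,
                           seed = seed)
  sim <- simulate_dataset(cfg)
  groups <- stats::setNames(sim$annotations$group, sim$annotations$roi_id)
  qc <- run_qc(sim$counts, groups = groups, filter_rois = FALSE)
  list(sim = sim, qc = qc, groups = groups)
}

# Adjusted Rand index between two partitions (independent helper used as
# the module-recovery score).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
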