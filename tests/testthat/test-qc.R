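test_that("geometric mean matches the closed form and rejects bad input", {
  expect_equal(geometric_mean(c(4, 4, 4)), 4)
  expect_equal(geometric_mean(c(1, 100)), 10)
  set.seed(1)
  x <- rlnorm(200, 3, 1)
  expect_equal(geometric_mean(x), exp(mean(log(x))), tolerance = 1e-12)
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(1, 0, 2)), "positive")
})

test_that("low-count probe filter applies the strict 'more than' boundary", {
  counts <- rbind(P_high = rep(100, 5),
                  P_edge = c(5, 5, 100, 100, 100),   # low in exactly 2 ROIs
                  P_low  = c(5, 5, 5, 100, 100),     # low in 3 ROIs
                  NEG1   = rep(2, 5),
                  NEG2   = rep(3, 5))
  colnames(counts) <- paste0("R", 1:5)
  tbl <- make_probe_table(counts, c("A", "B", "C", "NegProbe", "NegProbe"))
  res <- filter_low_count_probes(tbl)
  expect_equal(res$excluded$probe_id, "P_low")
  expect_true(all(c("P_high", "P_edge", "NEG1", "NEG2") %in%
                    res$table$probes$probe_id))
  # negatives are low everywhere but exempt by default; not with the flag off
  res2 <- filter_low_count_probes(tbl, qc_params(exempt_negative_probes = FALSE))
  expect_true(all(c("NEG1", "NEG2") %in% res2$excluded$probe_id))
  # inverted reading keeps only probes above threshold in > 2 ROIs
  res3 <- filter_low_count_probes(tbl, qc_params(low_count_rule = "inverted"))
  expect_equal(res3$excluded$probe_id, "P_low")
})

test_that("global outlier filter excludes probes below 0.1x target geomean", {
  # 3-probe target, one probe at 0.01x the others; 4 ROIs
  base <- c(100, 200, 400, 800)
  counts <- rbind(T_P1 = base, T_P2 = base, T_P3 = 0.01 * base,
                  NEG1 = rep(5, 4), NEG2 = rep(5, 4))
  colnames(counts) <- paste0("R", 1:4)
  tbl <- make_probe_table(counts, c("T", "T", "T", "NegProbe", "NegProbe"))
  res <- global_outlier_filter(tbl)
  # hand computation: probe geomeans (g, g, 0.01g); target geomean =
  # (g*g*0.01g)^(1/3) = g*0.01^(1/3) ~ 0.215g; ratio = 0.01/0.215 = 0.046
  expect_equal(res$excluded$probe_id, "T_P3")

  # identical probes: all ratios 1, nothing excluded
  same <- rbind(A_P1 = base, A_P2 = base, NEG1 = rep(5, 4))
  colnames(same) <- paste0("R", 1:4)
  res2 <- global_outlier_filter(make_probe_table(same, c("A", "A", "NegProbe")))
  expect_equal(nrow(res2$excluded), 0L)

  # ratio exactly at the threshold is kept ("below" is strict): a 2-probe
  # target with probes g and r*g has ratios sqrt(r) and 1/sqrt(r); choose
  # r = 0.01 so the low probe's ratio is exactly 0.1
  two <- rbind(B_P1 = base, B_P2 = 0.01 * base, NEG1 = rep(5, 4))
  colnames(two) <- paste0("R", 1:4)
  res3 <- global_outlier_filter(make_probe_table(two, c("B", "B", "NegProbe")))
  expect_equal(nrow(res3$excluded), 0L)
})

test_that("Grubbs flagging matches the critical-value formula", {
  # independent oracle: critical value computed inline from Student's t
  n <- 4
  alpha <- 0.05
  t_up <- qt(1 - alpha / (2 * n), df = n - 2)
  g_crit <- ((n - 1) / sqrt(n)) * sqrt(t_up^2 / (n - 2 + t_up^2))
  expect_equal(grubbs_critical(n, alpha), g_crit, tolerance = 1e-12)

  x <- c(10, 11, 12, 100)
  g_obs <- max(abs(x - mean(x))) / sd(x)
  expect_gt(g_obs, g_crit) # the 100 probe is an outlier at alpha = 0.05

  # one ROI with the outlier: flagged there, but 1/3 ROIs > 0.2 -> excluded
  counts <- cbind(R1 = c(10, 11, 12, 100), R2 = c(10, 11, 12, 13),
                  R3 = c(9, 10, 11, 12))
  rownames(counts) <- paste0("T_P", 1:4)
  tbl <- make_probe_table(rbind(counts, NEG1 = c(5, 5, 5), NEG2 = c(6, 6, 6)),
                          c(rep("T", 4), "NegProbe", "NegProbe"))
  res <- grubbs_outlier_filter(tbl)
  expect_equal(unname(res$flag_counts["T_P4"]), 1L)
  expect_equal(res$excluded$probe_id, "T_P4")

  # identical probe counts in every ROI: sd = 0, nothing flagged
  same <- matrix(7, 3, 4, dimnames = list(paste0("S_P", 1:3), paste0("R", 1:4)))
  res2 <- grubbs_outlier_filter(
    make_probe_table(rbind(same, NEG1 = rep(5, 4)), c(rep("S", 3), "NegProbe")))
  expect_equal(nrow(res2$excluded), 0L)
})

test_that("Grubbs exclusion needs flags in strictly more than 20% of ROIs", {
  # 10 ROIs; outlier present in exactly 2 (0.2, kept) then 3 (0.3, excluded)
  mk <- function(n_out) {
    base <- matrix(rep(c(10, 11, 12, 13), 10), 4, 10)
    base[4, seq_len(n_out)] <- 100
    rownames(base) <- paste0("T_P", 1:4)
    colnames(base) <- paste0("R", 1:10)
    make_probe_table(rbind(base, NEG1 = rep(5, 10)),
                     c(rep("T", 4), "NegProbe"))
  }
  expect_equal(nrow(grubbs_outlier_filter(mk(2))$excluded), 0L)
  expect_equal(grubbs_outlier_filter(mk(3))$excluded$probe_id, "T_P4")
})

test_that("ROI spike-in filter uses a strict 'below 10' geomean rule", {
  counts <- rbind(A_P1 = c(50, 60, 70),
                  NEG1 = c(10, 1, 20), NEG2 = c(10, 2, 20), NEG3 = c(10, 4, 20))
  colnames(counts) <- c("R_edge", "R_low", "R_high")
  tbl <- make_probe_table(counts, c("A", rep("NegProbe", 3)))
  res <- filter_rois_by_spikein(tbl)
  # R_edge geomean exactly 10 -> kept; R_low geomean = (1*2*4)^(1/3) = 2 -> out
  expect_equal(res$excluded$roi_id, "R_low")
  expect_equal(colnames(res$table$counts), c("R_edge", "R_high"))
  no_neg <- make_probe_table(counts[1, , drop = FALSE], "A")
  expect_error(filter_rois_by_spikein(no_neg), "no negative probes")
})

test_that("target collapse is the per-cell geometric mean of probes", {
  tbl <- small_table()
  m <- collapse_targets(tbl)$matrix
  expect_equal(m["A", ], sqrt(tbl$counts["A_P1", ] * tbl$counts["A_P2", ]))
  expect_equal(m["B", ], sqrt(tbl$counts["B_P1", ] * tbl$counts["B_P2", ]))
  expect_equal(attr(m, "stage"), "collapsed")

  # single-probe target is the identity; [2, 8] collapses to 4
  counts <- rbind(S_P1 = c(3, 9), D_P1 = c(2, 2), D_P2 = c(8, 8),
                  NEG1 = c(5, 5))
  colnames(counts) <- c("R1", "R2")
  m2 <- collapse_targets(make_probe_table(counts,
                                          c("S", "D", "D", "NegProbe")))$matrix
  expect_equal(unname(m2["S", ]), c(3, 9))
  expect_equal(unname(m2["D", ]), c(4, 4))

  # random table against the exp(mean(log)) formula oracle
  set.seed(2)
  rnd <- matrix(rpois(60, 50) + 1, 6, 10,
                dimnames = list(paste0("G_P", 1:6), paste0("R", 1:10)))
  tid <- rep(c("G1", "G2"), each = 3)
  m3 <- collapse_targets(make_probe_table(rnd, tid))$matrix
  for (g in c("G1", "G2")) {
    expect_equal(m3[g, ], exp(colMeans(log(rnd[tid == g, ]))),
                 tolerance = 1e-12)
  }
})

test_that("LOQ follows the geometric geomean * GSD^2 rule", {
  mk <- function(neg) {
    counts <- rbind(A_P1 = rep(50, ncol(neg)), neg)
    make_probe_table(counts, c("A", rep("NegProbe", nrow(neg))))
  }
  # zero spread: gsd = 1, loq = geomean
  neg <- matrix(7, 3, 2, dimnames = list(paste0("NEG", 1:3), c("R1", "R2")))
  s <- compute_loq(mk(neg))
  expect_equal(s$neg_gsd, c(1, 1))
  expect_equal(s$loq, c(7, 7))

  # [1, 10, 100]: geomean 10, gsd = exp(sd(log)) = 10, loq = 10 * 10^2
  neg2 <- matrix(c(1, 10, 100), 3, 1, dimnames = list(paste0("NEG", 1:3), "R1"))
  s2 <- compute_loq(mk(neg2))
  expect_equal(s2$neg_geomean, 10)
  expect_equal(s2$neg_gsd, exp(sd(log(c(1, 10, 100)))))
  expect_equal(s2$loq, 1000)

  # raising any single negative count above the geomean raises the LOQ
  base <- c(5, 10, 20, 40)
  loq_of <- function(v) {
    neg <- matrix(v, length(v), 1, dimnames = list(paste0("NEG", seq_along(v)), "R1"))
    compute_loq(mk(neg))$loq
  }
  l0 <- loq_of(base)
  for (bump in c(2, 5, 10)) {
    v <- base
    v[4] <- v[4] + bump
    expect_gt(loq_of(v), l0)
  }

  # arithmetic variant and the single-negative-probe error
  s3 <- compute_loq(mk(neg2), qc_params(loq_mode = "arithmetic"))
  expect_equal(s3$loq, 10 + 2 * sd(c(1, 10, 100)))
  one <- rbind(A_P1 = c(50, 50), NEG1 = c(5, 5))
  colnames(one) <- c("R1", "R2")
  expect_error(compute_loq(make_probe_table(one, c("A", "NegProbe"))),
               "at least 2 negative probes")
})

test_that("LOQ target filter keeps a target iff it exceeds LOQ somewhere", {
  m <- geomxnorm:::target_matrix(
    rbind(below = c(5, 5, 5), edge = c(5, 5, 11), high = c(100, 100, 100)),
    "collapsed")
  colnames(m) <- paste0("R", 1:3)
  stats <- structure(data.frame(roi_id = paste0("R", 1:3),
                                neg_geomean = 5, neg_gsd = sqrt(2),
                                loq = c(10, 10, 10)),
                     class = c("roi_noise_stats", "data.frame"))
  res <- filter_targets_by_loq(m, stats)
  expect_setequal(rownames(res$matrix), c("edge", "high"))
  expect_equal(res$excluded$target_id, "below")
})

test_that("signal-to-noise is elementwise value / LOQ", {
  set.seed(3)
  m <- geomxnorm:::target_matrix(
    matrix(rlnorm(50, 4), 10, 5,
           dimnames = list(paste0("G", 1:10), paste0("R", 1:5))), "collapsed")
  loq <- c(2, 4, 8, 16, 32)
  stats <- structure(data.frame(roi_id = paste0("R", 1:5), neg_geomean = 1,
                                neg_gsd = 2, loq = loq),
                     class = c("roi_noise_stats", "data.frame"))
  snr <- compute_snr(m, stats, groups = rep(c("a", "b"), c(2, 3)))
  expect_equal(snr$snr, sweep(m, 2, loq, "/"), ignore_attr = TRUE)
  expect_equal(snr$per_roi_median, apply(sweep(m, 2, loq, "/"), 2, median))
  # value equal to LOQ gives snr exactly 1
  m2 <- m
  m2[1, ] <- loq
  expect_equal(unname(compute_snr(m2, stats)$snr[1, ]), rep(1, 5))
  # doubling one ROI's counts doubles that ROI's snr column
  m3 <- m
  m3[, 2] <- 2 * m[, 2]
  expect_equal(compute_snr(m3, stats)$snr[, 2], 2 * snr$snr[, 2])
  # group medians and their sum
  gm <- snr$group_medians
  expect_equal(gm[, "a"], apply(snr$snr[, 1:2], 1, median))
  expect_equal(snr$snr_sum, gm[, "a"] + gm[, "b"])
})

test_that("filters are idempotent and invariant to probe row order", {
  sim <- simulate_dataset(tiny_sim(seed = 9L))
  tbl <- sim$counts
  params <- qc_params()
  for (f in list(filter_low_count_probes, global_outlier_filter,
                 grubbs_outlier_filter)) {
    once <- f(tbl, params)
    twice <- f(once$table, params)
    expect_equal(nrow(twice$excluded), 0L)
    expect_equal(twice$table$counts, once$table$counts)
  }
  # permuting probe rows never changes the excluded sets
  set.seed(42)
  perm <- sample(nrow(tbl$counts))
  shuffled <- probe_counts(tbl$counts[perm, ], tbl$probes$target_id[perm],
                           tbl$probes$probe_class[perm])
  for (f in list(filter_low_count_probes, global_outlier_filter,
                 grubbs_outlier_filter)) {
    expect_setequal(f(tbl, params)$excluded$probe_id,
                    f(shuffled, params)$excluded$probe_id)
  }
  expect_setequal(filter_rois_by_spikein(tbl, params)$excluded$roi_id,
                  filter_rois_by_spikein(shuffled, params)$excluded$roi_id)
})

test_that("the QC cascade reproduces the simulated group S/N gap", {
  cfg <- simulation_config(n_targets = 400L, probes_per_target_range = c(3L, 4L),
                           n_negative_probes = 40L, n_rois_per_group = 20L,
                           background_mean_by_group = c(30, 10),
                           n_de_targets = 0L, n_module_targets = 0L, seed = 13L)
  sim <- simulate_dataset(cfg)
  groups <- setNames(sim$annotations$group, sim$annotations$roi_id)
  qc <- run_qc(sim$counts, groups = groups, filter_rois = FALSE)
  g <- groups[colnames(qc$matrix)]
  w <- wilcox.test(qc$snr$per_roi_median[g == "primary"],
                   qc$snr$per_roi_median[g == "recurrent"],
                   alternative = "less")
  expect_lt(w$p.value, 0.05)
})
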