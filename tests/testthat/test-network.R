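log2m <- function(m) geomxnorm:::target_matrix(m, "log2(test)")

test_that("signed adjacency matches its closed form", {
  # endpoints via constructed profiles: cor 1 -> 1, cor -1 -> 0
  x <- seq_len(10)
  m <- rbind(g1 = x, g2 = 2 * x + 3, g3 = -x, g4 = rnorm(10))
  colnames(m) <- paste0("R", 1:10)
  a <- signed_adjacency(log2m(m), power = 6)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  expect_equal(diag(a), setNames(rep(1, 4), rownames(m)))

  # uncorrelated pair maps to 0.5^beta; random matrix vs formula oracle
  set.seed(1)
  rnd <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(sprintf("G%02d", 1:20), paste0("R", 1:15)))
  for (beta in c(1, 6, 12)) {
    expect_equal(signed_adjacency(log2m(rnd), beta),
                 ((1 + cor(t(rnd))) / 2)^beta,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  flat <- rbind(rnd, zero_var = rep(2, 15))
  expect_error(signed_adjacency(log2m(flat), 6), "zero-variance.*zero_var")
})

test_that("topological overlap matches the triple-loop oracle", {
  n <- 6
  ones <- matrix(1, n, n)
  expect_equal(topological_overlap(ones), ones)
  eye <- diag(n)
  tom_eye <- topological_overlap(eye)
  expect_equal(tom_eye[upper.tri(tom_eye)], rep(0, n * (n - 1) / 2))

  set.seed(2)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  tom <- topological_overlap(a)
  # brute-force oracle
  oracle <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_lt(max(abs(tom - oracle)), 1e-10)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_error(topological_overlap(matrix(runif(36), 6, 6)), "symmetric")
})

test_that("soft threshold selection honors overrides and computes connectivity", {
  sim <- simulate_module_matrix(n_modules = 2L, genes_per_module = 30L,
                                n_noise_genes = 40L, n_rois = 30L, seed = 3L)
  params <- network_params(candidate_powers = c(2L, 4L, 6L),
                           power_override = 16L)
  sel <- pick_soft_threshold(sim$matrix, params)
  expect_equal(sel$power, 16L)
  expect_equal(sel$fit_table$power, c(2L, 4L, 6L))

  # connectivity = adjacency row sums minus the diagonal (brute force)
  a <- signed_adjacency(sim$matrix, 6)
  k <- rowSums(a) - 1
  k_brute <- vapply(seq_len(nrow(a)),
                    function(i) sum(a[i, -i]), 0)
  expect_equal(k, k_brute, ignore_attr = TRUE, tolerance = 1e-12)

  sel2 <- suppressWarnings(
    pick_soft_threshold(sim$matrix,
                        network_params(candidate_powers = c(2L, 4L, 6L, 8L))))
  expect_true(sel2$power %in% c(2L, 4L, 6L, 8L))
  expect_true(is.data.frame(sel2$fit_table))
})

test_that("module detection separates clean blocks and respects min size", {
  # two perfectly correlated 40-gene blocks, zero cross-correlation
  set.seed(4)
  f1 <- rnorm(30); f2 <- rnorm(30)
  m <- rbind(matrix(rep(f1, each = 40), 40, 30) + rnorm(1200, 0, 0.01),
             matrix(rep(f2, each = 40), 40, 30) + rnorm(1200, 0, 0.01))
  dimnames(m) <- list(sprintf("G%02d", 1:80), paste0("R", 1:30))
  adj <- signed_adjacency(log2m(m), 6)
  diss <- 1 - topological_overlap(adj)
  mods <- detect_modules(diss, network_params(min_module_size = 30L),
                         matrix = log2m(m))
  expect_equal(sum(mods == "grey"), 0L)
  expect_length(unique(mods), 2L)
  expect_equal(unname(table(mods)[unique(mods)]),
               c(40L, 40L), ignore_attr = TRUE)

  all_grey <- detect_modules(diss, network_params(min_module_size = 100L))
  expect_true(all(all_grey == "grey"))
})

test_that("planted modules are recovered with noise genes sent to grey", {
  sim <- simulate_module_matrix(n_modules = 3L, genes_per_module = 50L,
                                n_noise_genes = 150L, n_rois = 40L, seed = 5L)
  adj <- signed_adjacency(sim$matrix, 6)
  mods <- detect_modules(1 - topological_overlap(adj), network_params(),
                         matrix = sim$matrix)
  truth <- sim$assignment
  ari <- adjusted_rand_index(mods, truth)
  expect_gte(ari, 0.9)
  expect_gte(mean(mods[truth == 0] == "grey"), 0.8)
})

test_that("eigengenes are unit-norm first principal directions", {
  set.seed(6)
  profile <- rnorm(20)
  m_same <- matrix(rep(profile, each = 5), 5, 20) * runif(5, 0.5, 2)
  dimnames(m_same) <- list(paste0("G", 1:5), paste0("R", 1:20))
  assign_same <- setNames(rep("turquoise", 5), rownames(m_same))
  eg <- module_eigengenes(log2m(m_same), assign_same)
  e <- eg$eigengenes[, "turquoise"]
  expect_equal(sum(e^2), 1, tolerance = 1e-10)
  expect_equal(abs(cor(e, profile)), 1, tolerance = 1e-8)
  expect_gt(cor(e, colMeans(t(scale(t(m_same))))), 0) # positive orientation
  expect_lt(abs(mean(e)), 1e-10)

  # variance explained equals the top eigenvalue fraction (eigen oracle)
  m_mix <- rbind(m_same, matrix(rnorm(3 * 20), 3, 20))
  dimnames(m_mix) <- list(paste0("G", 1:8), paste0("R", 1:20))
  assign_mix <- setNames(rep("turquoise", 8), rownames(m_mix))
  eg2 <- module_eigengenes(log2m(m_mix), assign_mix)
  z <- t(scale(t(m_mix)))
  lam <- eigen(t(z) %*% z, symmetric = TRUE)$values
  expect_equal(unname(eg2$var_explained["turquoise"]), lam[1] / sum(lam),
               tolerance = 1e-10)
  # membership is the gene-eigengene Pearson correlation
  expect_equal(eg2$membership[, "turquoise"],
               apply(m_mix, 1, cor, eg2$eigengenes[, "turquoise"]),
               tolerance = 1e-12)
})

test_that("module-trait correlation uses the Student-t transform", {
  set.seed(7)
  eg <- matrix(rnorm(30), 10, 3,
               dimnames = list(paste0("R", 1:10), c("turquoise", "blue", "brown")))
  # trait equal to an eigengene: r = 1 and p ~ 0
  res <- module_trait_correlation(eg, setNames(eg[, 1], rownames(eg)))
  expect_equal(res$cor["turquoise", 1], 1)
  expect_lt(res$p["turquoise", 1], 1e-12)

  # orthogonal constructed vectors: r = 0 exactly, p = 1
  v <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  w <- c(1, 1, -1, -1, 1, 1, -1, -1, 1, 1)
  eg0 <- matrix(v, 10, 1, dimnames = list(paste0("R", 1:10), "turquoise"))
  res0 <- module_trait_correlation(eg0, setNames(w, rownames(eg0)))
  expect_equal(unname(res0$cor[1, 1]), 0)
  expect_equal(unname(res0$p[1, 1]), 1)

  # grid of (r, n): p matches the cor.test oracle
  for (n in c(5, 12, 40)) {
    for (s in 1:3) {
      set.seed(100 * n + s)
      x <- rnorm(n); y <- rnorm(n)
      r <- cor(x, y)
      expect_equal(cor_pvalue_student(r, n), cor.test(x, y)$p.value,
                   tolerance = 1e-10)
    }
  }
  const <- module_trait_correlation(eg, setNames(rep(2, 10), rownames(eg)))
  expect_true(const$degenerate[1])
})

test_that("per-module S/N summaries recompute correctly, grey sits lowest", {
  sim <- simulate_module_matrix(seed = 8L)
  adj <- signed_adjacency(sim$matrix, 6)
  mods <- detect_modules(1 - topological_overlap(adj), network_params(),
                         matrix = sim$matrix)
  summ <- module_snr_summary(mods, sim$snr)
  # direct recomputation oracle
  for (k in summ$module) {
    expect_equal(summ$median[summ$module == k],
                 median(sim$snr[names(mods)[mods == k]]))
  }
  # noise genes were planted at low expression hence low S/N: grey is minimum
  expect_equal(summ$module[which.min(summ$median)], "grey")

  one <- setNames(rep("turquoise", length(sim$snr)), names(sim$snr))
  expect_equal(module_snr_summary(one, sim$snr)$median, median(sim$snr))
})

test_that("gene-set enrichment flags a planted overlap", {
  assignment <- setNames(c(rep("turquoise", 50), rep("grey", 150)),
                         sprintf("G%03d", 1:200))
  markers <- list(t_cells = sprintf("G%03d", 1:30),    # all in turquoise
                  unrelated = sprintf("G%03d", 171:200))
  enr <- module_geneset_enrichment(assignment, markers)
  hit <- enr[enr$module == "turquoise" & enr$set == "t_cells", ]
  expect_equal(hit$overlap, 30)
  # oracle: one-sided Fisher test on the 2x2 table
  fisher_p <- fisher.test(matrix(c(30, 20, 0, 150), 2, 2),
                          alternative = "greater")$p.value
  expect_equal(hit$p, fisher_p, tolerance = 1e-12)
  miss <- enr[enr$module == "turquoise" & enr$set == "unrelated", ]
  expect_equal(miss$overlap, 0)
})
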