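test_that("gene trend fits match the least-squares oracle and classify slopes", {
  set.seed(81)
  inst <- make_ordering_instance(2, 10, 4, noise = 0.2, seed = 81)
  ord <- sample(20)
  for (g in rownames(inst$values)) {
    fit <- fit_gene_mse(ord, inst, g, degree = 3)
    expect_equal(fit$mse, mse_oracle(inst$values[g, ord], 3), tolerance = 1e-9)
  }
  # exact polynomial -> MSE 0; strictly increasing values -> positive slope
  x <- seq(0, 1, length.out = 15)
  v <- rbind(2 * x^2 - x + 1, x)
  m <- rescale_genes(make_matrix(v, time = rep("0h", 15)), log_transform = FALSE)
  expect_lt(fit_gene_mse(1:15, m, "g1", 2)$mse, 1e-18)
  expect_identical(fit_gene_mse(1:15, m, "g2", 2)$slope_sign, "+")
  expect_identical(fit_gene_mse(15:1, m, "g2", 2)$slope_sign, "-")
  expect_error(fit_gene_mse(1:3, m, "g1", 3), "degree \\+ 2")
  expect_error(fit_gene_mse(1:15, m, "missing", 3), "not in data")
})

test_that("permutation p-values obey the counting formula and its edge cases", {
  # a candidate lying exactly on the polynomial beats every permutation: p = 0
  set.seed(82)
  x <- seq(0, 1, length.out = 24)
  v <- rbind(x, matrix(rnorm(10 * 24), 10))
  m <- rescale_genes(make_matrix(v - min(v), time = rep("0h", 24)),
                     log_transform = FALSE)
  res <- permutation_pvalues(1:24, m, candidates = "g1", degree = 1,
                             n_perm = 300, seed = 1)
  expect_identical(res$p_literal, 0)
  expect_equal(res$p_corrected, 1 / 301)
  # p-values are exact multiples of 1/n_perm; the two variants differ by <= 1/n_perm
  res2 <- permutation_pvalues(1:24, m, candidates = rownames(m$values),
                              degree = 1, n_perm = 250, seed = 2)
  expect_true(all(abs(res2$p_literal * 250 - round(res2$p_literal * 250)) < 1e-9))
  expect_true(all(abs(res2$p_literal - res2$p_corrected) <= 1 / 250 + 1e-12))
  # identical seed reproduces everything; different seed moves the null pool
  res3 <- permutation_pvalues(1:24, m, candidates = rownames(m$values),
                              degree = 1, n_perm = 250, seed = 2)
  expect_identical(res2, res3)
  expect_error(permutation_pvalues(1:24, m, "g1", n_perm = 50), "force")
  expect_error(permutation_pvalues(1:24, m, "absent"), "absent")
  # per-candidate null mode runs and stays in [0, 1]
  res4 <- permutation_pvalues(1:24, m, candidates = c("g1", "g2"), degree = 1,
                              n_perm = 120, seed = 3, shared_null = FALSE)
  expect_true(all(res4$p_literal >= 0 & res4$p_literal <= 1))
})

test_that("a flat-profile (worst-fit) candidate is not called significant", {
  set.seed(83)
  n <- 30
  v <- matrix(rnorm(20 * n), 20, n)
  v[1, ] <- rep(c(-3, 3), length.out = n)  # oscillating: terrible smooth fit
  m <- rescale_genes(make_matrix(v - min(v), time = rep("0h", n)),
                     log_transform = FALSE)
  res <- permutation_pvalues(1:n, m, candidates = "g1", degree = 2,
                             n_perm = 400, seed = 4)
  expect_gt(res$p_literal, 0.5)
})

test_that("ranking splits by slope direction and orders by MSE", {
  res <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    mse = c(0.2, 0.1, 0.3, 0.1),
    p_literal = c(0.01, 0.01, 0.02, 0.005),
    p_corrected = c(0.02, 0.02, 0.03, 0.01),
    slope = c(1, 2, -1, -2),
    slope_sign = c("+", "+", "-", "-"),
    direction = c("up", "up", "down", "down"),
    zero_slope = FALSE)
  rk <- rank_candidates(res, top_k = 25)
  expect_identical(rk$up$gene_id, c("b", "a"))
  expect_identical(rk$up$rank, 1:2)
  expect_identical(rk$down$gene_id, c("d", "c"))
  expect_identical(rank_candidates(res, top_k = 1)$up$gene_id, "b")
})

test_that("null-gene p-values are approximately uniform (calibration)", {
  cfg <- sim_config(n_timepoints = 3, cells_per_time = 15, n_genes = 200,
                    n_up = 0, n_down = 0, n_peak = 0)
  m <- simulate_null_genes(cfg, seed = 84)
  rc <- rescale_genes(median_by_ratio_normalize(m, min_frac = 0.5)$matrix)
  ord <- cell_order(seq_len(ncol(rc$values)), rc$time)
  res <- permutation_pvalues(ord, rc, candidates = rownames(rc$values),
                             degree = 3, n_perm = 600, seed = 85)
  ks <- suppressWarnings(ks.test(res$p_corrected, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
  # observed type-I rate near nominal
  expect_lte(mean(res$p_corrected <= 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("planted trend genes rank above nulls (power)", {
  cfg <- sim_config(n_timepoints = 3, cells_per_time = 20, n_genes = 150,
                    n_up = 5, n_down = 5, n_peak = 0)
  sim <- simulate_time_course(cfg, seed = 86)
  rc <- rescale_genes(median_by_ratio_normalize(sim$matrix,
                                                min_frac = 0.5)$matrix)
  # order by the true latent pseudotime (block-respecting by construction)
  ord <- cell_order(order(as.integer(rc$time), sim$truth$pseudotime), rc$time)
  res <- permutation_pvalues(ord, rc, candidates = rownames(rc$values),
                             degree = 3, n_perm = 500, seed = 87)
  rk <- rank_candidates(res, top_k = 10)
  planted_up <- sim$truth$genes$gene_id[sim$truth$genes$class == "up"]
  planted_down <- sim$truth$genes$gene_id[sim$truth$genes$class == "down"]
  expect_gte(length(intersect(rk$up$gene_id, planted_up)), 4)
  expect_gte(length(intersect(rk$down$gene_id, planted_down)), 4)
})
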