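test_that("cell_order enforces the time-block constraint", {
  time <- factor(c("0h", "0h", "12h", "12h"), levels = c("0h", "12h"),
                 ordered = TRUE)
  o <- cell_order(c(2L, 1L, 4L, 3L), time)
  expect_s3_class(o, "cw_order")
  expect_equal(o$blocks$start, c(1L, 3L))
  expect_error(cell_order(c(3L, 1L, 2L, 4L), time), "mixed")
  expect_error(cell_order(c(1L, 1L, 2L, 3L), time), "permutation")
})

test_that("aggregated MSE matches the normal-equations oracle and sums over genes", {
  set.seed(71)
  inst <- make_ordering_instance(3, 10, 5, noise = 0.3, seed = 71)
  ord <- sample(30)
  for (degree in c(1, 2, 3)) {
    per_gene <- vapply(rownames(inst$values),
                       function(g) mse_oracle(inst$values[g, ord], degree),
                       numeric(1))
    expect_equal(aggregated_mse(ord, inst, rownames(inst$values), degree),
                 sum(per_gene), tolerance = 1e-9)
  }
  # two genes: aggregate equals the sum of the individual aggregates
  g <- rownames(inst$values)[1:2]
  expect_equal(aggregated_mse(ord, inst, g, 3),
               aggregated_mse(ord, inst, g[1], 3) +
                 aggregated_mse(ord, inst, g[2], 3), tolerance = 1e-12)
  # values exactly on a cubic give zero MSE
  x <- seq(0, 1, length.out = 12)
  v <- rbind(5 + x - 2 * x^2 + 3 * x^3, 1 - x^3)
  cub <- rescale_genes(make_matrix(v, time = rep("0h", 12)),
                       log_transform = FALSE)
  expect_lt(aggregated_mse(seq_len(12), cub, c("g1", "g2"), 3), 1e-18)
  expect_error(aggregated_mse(1:4, inst, g, 3), "degree \\+ 2")
  expect_error(aggregated_mse(ord, inst, "nope", 3), "absent")
})

test_that("exhaustive oracle enumerates the admissible orders", {
  inst <- make_ordering_instance(2, 2, 2, noise = 0.5, seed = 72)
  res <- exhaustive_oracle(inst, rownames(inst$values), degree = 1)
  expect_equal(res$n_orders, 4L)  # 2! * 2!
  expect_s3_class(res$order, "cw_order")
  # a noiseless monotone instance is fit exactly at sufficient degree
  clean <- make_ordering_instance(2, 3, 2, noise = 0, seed = 73)
  expect_lt(exhaustive_oracle(clean, rownames(clean$values), degree = 3)$mse,
            1e-12)
})

test_that("ENI respects blocks, is seed-deterministic, and finds monotone structure", {
  inst <- make_ordering_instance(2, 3, 1, noise = 0, seed = 74)
  genes <- rownames(inst$values)
  o1 <- eni_order(inst, genes, degree = 2, seed = 5)
  o2 <- eni_order(inst, genes, degree = 2, seed = 5)
  expect_identical(o1$perm, o2$perm)
  # block constraint holds as a hard assertion
  expect_false(is.unsorted(as.integer(inst$time)[o1$perm]))
  # recovered order attains the exhaustive global minimum on this instance
  oracle <- exhaustive_oracle(inst, genes, degree = 2)
  refined <- two_opt_refine(o1, inst, genes, degree = 2, n_iter = 2000, seed = 6)
  expect_equal(attr(refined, "mse"), oracle$mse, tolerance = 1e-9)
  # degenerate input: all cells identical; any order ties, output still valid
  flat <- inst
  flat$values[] <- 0
  od <- eni_order(flat, genes, degree = 2, seed = 7)
  expect_false(is.unsorted(as.integer(flat$time)[od$perm]))
  od2 <- eni_order(flat, genes, degree = 2, seed = 7)
  expect_identical(od$perm, od2$perm)
})

test_that("2-opt never increases the objective and fixes scrambled blocks", {
  inst <- make_ordering_instance(2, 6, 3, noise = 0.05, seed = 75)
  genes <- rownames(inst$values)
  # deliberately scrambled within-block order
  set.seed(76)
  scram <- c(sample(1:6), sample(7:12))
  o <- cell_order(scram, inst$time, colnames(inst$values))
  before <- aggregated_mse(o, inst, genes, 2)
  refined <- two_opt_refine(o, inst, genes, degree = 2, n_iter = 5000, seed = 8)
  expect_lt(attr(refined, "mse"), before)
  expect_equal(aggregated_mse(refined, inst, genes, 2), attr(refined, "mse"),
               tolerance = 1e-12)
  # zero iterations returns the input untouched
  same <- two_opt_refine(o, inst, genes, degree = 2, n_iter = 0, seed = 8)
  expect_identical(same$perm, o$perm)
  # already-optimal input stays put
  oracle <- exhaustive_oracle(make_ordering_instance(2, 3, 2, noise = 0.1, seed = 77),
                              paste0("m", 1:2), degree = 2)
  inst2 <- make_ordering_instance(2, 3, 2, noise = 0.1, seed = 77)
  stay <- two_opt_refine(oracle$order, inst2, paste0("m", 1:2), degree = 2,
                         n_iter = 3000, seed = 9)
  expect_equal(attr(stay, "mse"), oracle$mse, tolerance = 1e-12)
  # swap move mode also preserves blocks and monotone objective
  sw <- two_opt_refine(o, inst, genes, degree = 2, n_iter = 1000,
                       move = "swap", seed = 10)
  expect_false(is.unsorted(as.integer(inst$time)[sw$perm]))
  expect_lte(attr(sw, "mse"), before)
})

test_that("restarted ENI + 2-opt matches the exhaustive optimum on most small random instances", {
  hits <- 0L
  n_inst <- 20L
  for (i in seq_len(n_inst)) {
    inst <- make_ordering_instance(2, 4, 3, noise = 0.4, seed = 100 + i)
    genes <- rownames(inst$values)
    oracle <- exhaustive_oracle(inst, genes, degree = 2)
    o <- wavecrest_order(inst, genes, degree = 2, n_iter = 4000,
                         n_starts = 5, seed = 200 + i)
    expect_gte(attr(o, "mse"), oracle$mse - 1e-9)  # oracle is a lower bound
    if (attr(o, "mse") <= oracle$mse + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_inst, 0.9)
  # restarts are deterministic given the seed
  o2 <- wavecrest_order(make_ordering_instance(2, 4, 3, noise = 0.4, seed = 101),
                        paste0("m", 1:3), degree = 2, n_iter = 4000,
                        n_starts = 5, seed = 201)
  o3 <- wavecrest_order(make_ordering_instance(2, 4, 3, noise = 0.4, seed = 101),
                        paste0("m", 1:3), degree = 2, n_iter = 4000,
                        n_starts = 5, seed = 201)
  expect_identical(o2$perm, o3$perm)
})

test_that("order concordance reports per-block |Kendall tau|", {
  inst <- make_ordering_instance(2, 5, 2, noise = 0, seed = 78)
  o <- cell_order(1:10, inst$time, colnames(inst$values))
  cc <- order_concordance(o, seq(0, 1, length.out = 10))
  expect_equal(cc$tau, c(1, 1))
  expect_equal(attr(cc, "weighted_tau"), 1)
  # a reversed block still scores 1 in absolute value
  o2 <- cell_order(c(5:1, 6:10), inst$time, colnames(inst$values))
  expect_equal(order_concordance(o2, seq(0, 1, length.out = 10))$tau, c(1, 1))
})
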