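# Shared fixture builders and independent oracles, all generated in code.

# Small expression matrix with labelled genes/cells and a time course.
make_matrix <- function(values, n_genes = nrow(values), n_cells = ncol(values),
                        time = rep("0h", n_cells), unit = "counts",
                        time_levels = unique(time)) {
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("c", seq_len(ncol(values))))
  expression_matrix(values, time, time_levels = time_levels, unit = unit)
}

# Rescaled matrix with a planted latent order: each marker is a smooth
# monotone function of the latent position plus Gaussian noise.
make_ordering_instance <- function(n_blocks, block_size, n_genes, noise = 0,
                                   seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n <- n_blocks * block_size
    latent <- seq(0, 1, length.out = n)
    v <- t(vapply(seq_len(n_genes), function(g) {
      sign <- if (g %% 2 == 0) -1 else 1
      sign * latent + rnorm(n, 0, noise)
    }, numeric(n)))
    dimnames(v) <- list(paste0("m", seq_len(n_genes)), paste0("c", seq_len(n)))
    time <- rep(paste0("t", seq_len(n_blocks)), each = block_size)
    m <- expression_matrix(v - min(v), time, unit = "counts")
    rescale_genes(m, log_transform = FALSE)
  })
}

# Literal least-squares oracle: degree-d polynomial MSE via normal equations.
mse_oracle <- function(y, degree) {
  n <- length(y)
  x <- seq(0, 1, length.out = n)
  X <- outer(x, 0:degree, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  mean((y - X %*% beta)^2)
}

# Literal median-of-ratios oracle (double loop over genes/cells).
size_factor_oracle <- function(v) {
  ref <- which(apply(v, 1, function(r) all(r > 0)))
  geo <- vapply(ref, function(g) exp(mean(log(v[g, ]))), numeric(1))
  vapply(seq_len(ncol(v)), function(j) {
    median(vapply(seq_along(ref), function(i) v[ref[i], j] / geo[i], numeric(1)))
  }, numeric(1))
}
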