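#' Configuration for the time-course simulator
#'
#' Describes a synthetic differentiation time course: cells are collected at
#' `n_timepoints` discrete clock times but progress asynchronously, so each
#' cell's latent pseudotime is drawn from its collection time's window on
#' \[0, 1\]; consecutive windows overlap by a configurable fraction.  Each
#' gene follows a smooth profile class on the log2 scale — monotone up,
#' monotone down, peaked, or flat (null) — and counts are drawn with
#' negative-binomial overdispersion plus a dropout mask whose probability
#' decays with the mean, the standard phenomenology of single-cell RNA-seq
#' counts.
#'
#' Default noise levels describe strong differentiation markers profiled
#' with a full-length, deep-coverage single-cell protocol: a trend amplitude
#' of 5 log2 units (~32-fold, modest next to the orders-of-magnitude
#' induction of canonical lineage markers), dispersion 0.15 (count CV around
#' 40% at high expression), and dropout that is near-certain for means close
#' to zero but negligible above ~100 counts.
#'
#' @param n_timepoints Number of collection times (default 4).
#' @param cells_per_time Cells per collection time (default 40).
#' @param n_genes Total genes (default 600).
#' @param n_up,n_down,n_peak Planted trend genes per class (defaults 20
#'   each); the remainder are flat nulls.
#' @param effect Trend amplitude in log2 units (default 5).
#' @param base_range Range of per-gene baseline log2 mean (default c(3, 8)).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives deterministic means (default 0.15).
#' @param dropout Dropout probability scale in \[0, 1\]: a zero-mean gene
#'   drops out with this probability (default 1).
#' @param dropout_decay Decay rate of dropout with the count mean; the
#'   dropout probability is `dropout * exp(-dropout_decay * mean)`
#'   (default 0.05).
#' @param overlap Fractional overlap of consecutive pseudotime windows
#'   (default 0.25, emulating cell-state asynchrony at each clock time).
#' @param time_labels Labels for the collection times (default
#'   `"t1" ... "tK"`).
#' @return A list of class `cw_simconfig`.
#' @export
sim_config <- function(n_timepoints = 4, cells_per_time = 40, n_genes = 600,
                       n_up = 20, n_down = 20, n_peak = 20,
                       effect = 5, base_range = c(3, 8),
                       dispersion = 0.15, dropout = 1, dropout_decay = 0.05,
                       overlap = 0.25,
                       time_labels = paste0("t", seq_len(n_timepoints))) {
  stopifnot(n_timepoints >= 2, cells_per_time >= 1,
            n_genes >= n_up + n_down + n_peak,
            effect >= 0, dispersion >= 0,
            dropout >= 0, dropout <= 1, dropout_decay >= 0,
            overlap >= 0, overlap < 1,
            length(time_labels) == n_timepoints)
  structure(as.list(environment()), class = "cw_simconfig")
}

# Pseudotime window [lo, hi] for time point i of T: equal-width slices of
# [0, 1] widened symmetrically so consecutive windows overlap by `overlap`.
time_windows <- function(cfg) {
  T <- cfg$n_timepoints
  half <- (1 + cfg$overlap) / (2 * T)
  centers <- (seq_len(T) - 0.5) / T
  cbind(lo = pmax(0, centers - half), hi = pmin(1, centers + half))
}

# Profile value f(t) in [0, 1] per class.
profile_value <- function(class, t, peak_center) {
  switch(class,
         up = t,
         down = 1 - t,
         peak = exp(-(t - peak_center)^2 / (2 * 0.15^2)),
         null = rep(0, length(t)))
}

gene_catalogue <- function(cfg) {
  n_null <- cfg$n_genes - cfg$n_up - cfg$n_down - cfg$n_peak
  cls <- c(rep("up", cfg$n_up), rep("down", cfg$n_down),
           rep("peak", cfg$n_peak), rep("null", n_null))
  data.frame(
    gene_id = sprintf("gene%04d_%s", seq_len(cfg$n_genes), cls),
    class = cls,
    base = stats::runif(cfg$n_genes, cfg$base_range[1], cfg$base_range[2]),
    effect = ifelse(cls == "null", 0, cfg$effect),
    peak_center = ifelse(cls == "peak", stats::runif(cfg$n_genes, 0.3, 0.7), NA))
}

sample_counts <- function(cfg, genes, pseudotime) {
  n_cells <- length(pseudotime)
  v <- matrix(0, nrow(genes), n_cells)
  for (i in seq_len(nrow(genes))) {
    f <- profile_value(genes$class[i], pseudotime, genes$peak_center[i])
    mu <- 2^(genes$base[i] + genes$effect[i] * f)
    x <- if (cfg$dispersion > 0)
      stats::rnbinom(n_cells, mu = mu, size = 1 / cfg$dispersion)
    else mu
    p_drop <- cfg$dropout * exp(-cfg$dropout_decay * mu)
    x[stats::runif(n_cells) < p_drop] <- 0
    v[i, ] <- x
  }
  rownames(v) <- genes$gene_id
  v
}

#' Simulate a time-course single-cell expression matrix with ground truth
#'
#' Draws each cell's latent pseudotime from its collection-time window, each
#' gene's mean from its smooth profile on the log2 scale, and counts from an
#' overdispersed count model with mean-dependent dropout (see
#' [sim_config()]).  Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `matrix` (a counts [expression_matrix()]) and `truth`
#'   (list: `pseudotime`, named per cell, and `genes`, the per-gene
#'   catalogue data.frame with class and parameters).
#' @export
simulate_time_course <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cw_simconfig"))
  with_seed(seed, {
    win <- time_windows(cfg)
    T <- cfg$n_timepoints
    n_cells <- T * cfg$cells_per_time
    block <- rep(seq_len(T), each = cfg$cells_per_time)
    pt <- stats::runif(n_cells, win[block, "lo"], win[block, "hi"])
    genes <- gene_catalogue(cfg)
    v <- sample_counts(cfg, genes, pt)
    colnames(v) <- sprintf("cell%04d_%s", seq_len(n_cells),
                           cfg$time_labels[block])
    names(pt) <- colnames(v)
    m <- expression_matrix(v, cfg$time_labels[block],
                           time_levels = cfg$time_labels, unit = "counts")
    list(matrix = m, truth = list(pseudotime = pt, genes = genes))
  })
}

#' Simulate a matrix of flat (null) genes
#'
#' All genes have constant profiles: expression is independent of both
#' collection time and latent pseudotime.  Used for type-I-error and
#' p-value-calibration checks of the trend and path tests.
#'
#' @param cfg A [sim_config()]; its trend-gene counts are ignored.
#' @param n_genes Number of null genes.
#' @param seed Integer seed.
#' @return A counts [expression_matrix()].
#' @export
simulate_null_genes <- function(cfg, n_genes = cfg$n_genes, seed = NULL) {
  stopifnot(inherits(cfg, "cw_simconfig"))
  cfg$n_genes <- n_genes
  cfg$n_up <- cfg$n_down <- cfg$n_peak <- 0L
  simulate_time_course(cfg, seed = seed)$matrix
}

#' Simulate a paired bulk + single-cell fixture
#'
#' Shares one gene catalogue between a single-cell time-course matrix and a
#' bulk matrix whose samples are within-time-point means of independently
#' simulated cells, multiplied by mild log-normal sample noise — mirroring a
#' design where bulk RNA was collected alongside each single-cell batch.
#'
#' @param cfg A [sim_config()].
#' @param n_bulk_per_time Bulk replicates per collection time (default 3).
#' @param bulk_noise_sd Log-normal sd of bulk sample noise (default 0.05).
#' @param seed Integer seed.
#' @return List with `bulk` (counts [expression_matrix()], samples labelled
#'   by time), `cells` (single-cell counts matrix), and `truth`.
#' @export
make_paired_fixture <- function(cfg, n_bulk_per_time = 3, bulk_noise_sd = 0.05,
                                seed = NULL) {
  stopifnot(inherits(cfg, "cw_simconfig"))
  with_seed(seed, {
    sc <- simulate_time_course(cfg, seed = NULL)
    genes <- sc$truth$genes
    win <- time_windows(cfg)
    T <- cfg$n_timepoints
    bulk_cols <- list()
    labels <- character(0)
    for (t in seq_len(T)) for (r in seq_len(n_bulk_per_time)) {
      pt <- stats::runif(cfg$cells_per_time, win[t, "lo"], win[t, "hi"])
      pool <- sample_counts(cfg, genes, pt)
      noise <- exp(stats::rnorm(nrow(genes), 0, bulk_noise_sd))
      bulk_cols[[length(bulk_cols) + 1L]] <- rowMeans(pool) * noise
      labels <- c(labels, cfg$time_labels[t])
    }
    bv <- do.call(cbind, bulk_cols)
    rownames(bv) <- genes$gene_id
    colnames(bv) <- sprintf("bulk%02d_%s", seq_along(labels), labels)
    bulk <- expression_matrix(bv, labels, time_levels = cfg$time_labels,
                              unit = "counts")
    list(bulk = bulk, cells = sc$matrix, truth = sc$truth)
  })
}
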