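#' Directional two-sample Kolmogorov-Smirnov statistic
#'
#' Compares expression at two adjacent ordered conditions.  The magnitude of
#' the statistic is the two-sample KS distance `D = max(D+, D-)`; its sign is
#' that of the dominant one-sided statistic, with positive meaning `y` is
#' stochastically larger than `x` (an increase over time, "Up").  The
#' p-value is the asymptotic two-sided KS p-value for `D`.
#'
#' @param x,y Numeric vectors of expression values at conditions `t` and
#'   `t + 1`; each needs at least 3 values.
#' @return List with `stat` (signed, in \[-1, 1\]), `p`, and the one-sided
#'   components `d_plus`, `d_minus`.
#' @examples
#' signed_ks(rnorm(50), rnorm(50) + 2)$stat  # close to +1: strong increase
#' @export
signed_ks <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    cw_stop("each condition needs at least 3 cells (got %d and %d)",
            length(x), length(y))
  z <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(z)
  fy <- stats::ecdf(y)(z)
  d_plus <- max(fx - fy)    # x's CDF above y's: y stochastically larger (Up)
  d_minus <- max(fy - fx)
  d <- max(d_plus, d_minus, 0)
  stat <- if (d_plus >= d_minus) d else -d
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- ks_asymp_p(sqrt(n_eff) * d)
  list(stat = stat, p = p, d_plus = d_plus, d_minus = d_minus)
}

# Asymptotic two-sided Kolmogorov distribution tail: P(sqrt(n) D > t).
ks_asymp_p <- function(t) {
  if (t < 1e-10) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Call per-gene expression paths across ordered conditions
#'
#' For every gene and every pair of adjacent collection times, runs the
#' directional KS test ([signed_ks()]) between the two groups of cells and
#' calls the transition `Up` or `Down` when the (optionally BH-adjusted
#' across genes, within each transition) p-value is at or below `alpha`,
#' with the direction given by the statistic's sign; otherwise `EE` (equal
#' expression).  The per-transition calls compose into an expression path
#' such as `EE-Up-Up`, and a gene is differentially expressed if any
#' transition is not `EE`.  This is a thresholded KS path composer, not a
#' posterior-probability path model.
#'
#' @param m A [expression_matrix()] (typically normalized) with at least two
#'   time points and at least 3 cells per time point.
#' @param alpha Per-transition call threshold (default 0.05).
#' @param fdr Benjamini-Hochberg adjust p-values across genes within each
#'   transition before thresholding (default `TRUE`).
#' @param drop_zeros Exclude zero values from each sample before testing
#'   (default `FALSE`: dropouts stay in the empirical distributions).
#' @return A data.frame of class `cw_paths`, sorted by gene ID: `gene_id`,
#'   then per transition `stat_<a>_<b>`, `p_<a>_<b>`, `padj_<a>_<b>`,
#'   `call_<a>_<b>`, then `path` (calls joined by `-`) and `overall_de`.
#' @export
classify_paths <- function(m, alpha = 0.05, fdr = TRUE, drop_zeros = FALSE) {
  stopifnot(inherits(m, "cw_matrix"))
  lv <- levels(droplevels(m$time))
  if (length(lv) < 2) cw_stop("need at least 2 time points")
  counts <- table(m$time)[lv]
  if (any(counts < 3))
    cw_stop("every time point needs at least 3 cells (%s)",
            paste(sprintf("%s: %d", lv, counts), collapse = ", "))
  v <- m$values
  genes <- rownames(v)
  groups <- lapply(lv, function(t) which(m$time == t))
  out <- data.frame(gene_id = genes)
  calls <- matrix("EE", length(genes), length(lv) - 1L)
  for (i in seq_len(length(lv) - 1L)) {
    res <- lapply(genes, function(g) {
      x <- v[g, groups[[i]]]
      y <- v[g, groups[[i + 1L]]]
      if (drop_zeros) { x <- x[x > 0]; y <- y[y > 0] }
      if (length(x) < 3 || length(y) < 3) return(list(stat = 0, p = 1))
      signed_ks(x, y)
    })
    stat <- vapply(res, `[[`, numeric(1), "stat")
    p <- vapply(res, `[[`, numeric(1), "p")
    padj <- if (fdr) stats::p.adjust(p, "BH") else p
    call_i <- ifelse(padj <= alpha & stat != 0,
                     ifelse(stat > 0, "Up", "Down"), "EE")
    calls[, i] <- call_i
    tag <- sprintf("%s_%s", lv[i], lv[i + 1L])
    out[[paste0("stat_", tag)]] <- stat
    out[[paste0("p_", tag)]] <- p
    out[[paste0("padj_", tag)]] <- padj
    out[[paste0("call_", tag)]] <- call_i
  }
  out$path <- apply(calls, 1L, paste, collapse = "-")
  out$overall_de <- apply(calls != "EE", 1L, any)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cw_paths", "data.frame")
  out
}
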