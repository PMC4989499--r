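#' Polynomial trend fit for one gene along an order
#'
#' Reorders the gene's standardized expression along the recovered order (or
#' a contiguous slice of it, e.g. the cells of one collection time), fits a
#' polynomial of the given degree against rank position in \[0, 1\], and
#' records the mean squared error.  The trend direction is taken from a
#' separate degree-1 (linear) fit on the same points: positive slope = up.
#'
#' @param order A [cell_order()] or an integer vector of cell indices (a
#'   slice of an order, in order).
#' @param data A `cw_rescaled` matrix.
#' @param gene Gene ID.
#' @param degree Polynomial degree for the MSE fit.
#' @return A list of class `cw_trendfit`: `gene`, `degree`, `coefficients`
#'   (intercept first, raw polynomial basis), `mse`, `slope` (linear
#'   coefficient), `slope_sign` (`"+"`, `"-"`, or `"0"`).
#' @export
fit_gene_mse <- function(order, data, gene, degree = 3) {
  stopifnot(inherits(data, "cw_rescaled"), length(gene) == 1L)
  if (!gene %in% rownames(data$values)) cw_stop("gene not in data: %s", gene)
  ord <- if (inherits(order, "cw_order")) order$perm else as.integer(order)
  n <- length(ord)
  if (n < degree + 2) cw_stop("slice length %d is below degree + 2 = %d",
                              n, degree + 2)
  y <- data$values[gene, ord]
  x <- seq(0, 1, length.out = n)
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  slope <- stats::lm.fit(cbind(1, x), y)$coefficients[[2L]]
  structure(
    list(gene = gene, degree = degree,
         coefficients = unname(fit$coefficients),
         mse = sum(fit$residuals^2) / n,
         slope = slope,
         slope_sign = if (slope > 0) "+" else if (slope < 0) "-" else "0"),
    class = "cw_trendfit")
}

resolve_slice <- function(order, data, slice) {
  ord <- if (inherits(order, "cw_order")) order$perm else as.integer(order)
  if (!is.null(slice)) {
    if (!inherits(order, "cw_order"))
      cw_stop("slicing by time label needs a cw_order")
    b <- order$blocks[order$blocks$time == slice, ]
    if (!nrow(b)) cw_stop("no time block labelled %s", slice)
    ord <- ord[b$start:b$end]
  }
  ord
}

#' Permutation test for smooth expression trends ("fishing")
#'
#' Scores each candidate gene by the MSE of its polynomial fit along the
#' recovered order and assigns significance by permutation: each null draw
#' picks a gene uniformly from the universe, permutes its cell order
#' uniformly, refits the polynomial, and records the MSE.  The permutation
#' p-value is the fraction of null MSEs at or below the observed MSE
#' (`p_literal`, which can be exactly 0); the standard `(k + 1) / (n + 1)`
#' corrected value is reported alongside.  By default one null pool is
#' shared across all candidates; `shared_null = FALSE` draws a separate pool
#' per candidate (permuting that candidate itself).
#'
#' @param order A [cell_order()] or integer index vector.
#' @param data A `cw_rescaled` matrix.
#' @param candidates Candidate gene IDs (must be present in `data`).
#' @param universe Gene IDs to draw null genes from; default all genes in
#'   `data`.
#' @param degree Polynomial degree.
#' @param n_perm Number of permutations (>= 100 unless `force = TRUE`).
#' @param seed Integer seed; identical seeds give identical null pools and
#'   p-values.
#' @param slice Optional time label: restrict to that block of the order.
#' @param shared_null Share one null pool across candidates (default) or
#'   permute each candidate against itself.
#' @param force Allow `n_perm < 100`.
#' @return A data.frame of class `cw_fishing`, one row per candidate:
#'   `gene_id`, `mse`, `p_literal`, `p_corrected`, `slope`, `slope_sign`,
#'   `direction` (`"up"`/`"down"`; zero slopes fall to `"up"` and are
#'   flagged in `zero_slope`).
#' @export
permutation_pvalues <- function(order, data, candidates,
                                universe = rownames(data$values),
                                degree = 3, n_perm = 10000, seed = NULL,
                                slice = NULL, shared_null = TRUE,
                                force = FALSE) {
  stopifnot(inherits(data, "cw_rescaled"))
  miss <- setdiff(candidates, rownames(data$values))
  if (length(miss)) cw_stop("candidates absent from data: %s",
                            paste(miss, collapse = ", "))
  universe <- intersect(universe, rownames(data$values))
  if (!length(universe)) cw_stop("permutation universe is empty")
  if (n_perm < 100 && !force)
    cw_stop("n_perm = %d gives a very coarse p-value grid; use n_perm >= 100 or force = TRUE",
            n_perm)
  ord <- resolve_slice(order, data, slice)
  n <- length(ord)
  if (n < degree + 2) cw_stop("slice length %d is below degree + 2 = %d",
                              n, degree + 2)
  qt <- poly_qt(n, degree)
  Y <- t(data$values[, ord, drop = FALSE])   # n x G, already along the order
  seq_ord <- seq_len(n)

  obs <- vapply(candidates, function(g) {
    y <- Y[, g]
    (sum(y^2) - sum((qt %*% y)^2)) / n
  }, numeric(1))
  slopes <- vapply(candidates, function(g)
    stats::lm.fit(cbind(1, seq(0, 1, length.out = n)), Y[, g])$coefficients[[2L]],
    numeric(1))

  null_pool <- function(gene_draw) {
    # gene_draw: character vector length n_perm of universe genes
    mse <- numeric(n_perm)
    chunk <- 5000L
    for (lo in seq(1L, n_perm, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_perm)
      idx <- lo:hi
      M <- vapply(idx, function(k) Y[sample(seq_ord), gene_draw[k]], numeric(n))
      mse[idx] <- (colSums(M * M) - colSums((qt %*% M)^2)) / n
    }
    mse
  }

  with_seed(seed, {
    if (shared_null) {
      pool <- null_pool(sample(universe, n_perm, replace = TRUE))
      k <- vapply(obs, function(o) sum(pool <= o), numeric(1))
    } else {
      k <- vapply(seq_along(candidates), function(i) {
        pool <- null_pool(rep(candidates[i], n_perm))
        sum(pool <= obs[i])
      }, numeric(1))
    }
    out <- data.frame(
      gene_id = candidates,
      mse = unname(obs),
      p_literal = unname(k) / n_perm,
      p_corrected = (unname(k) + 1) / (n_perm + 1),
      slope = unname(slopes),
      slope_sign = ifelse(slopes > 0, "+", ifelse(slopes < 0, "-", "0")),
      direction = ifelse(slopes < 0, "down", "up"),
      zero_slope = slopes == 0,
      row.names = NULL)
    if (any(out$zero_slope))
      warning(sprintf("%d candidate(s) with exactly zero slope assigned direction 'up'",
                      sum(out$zero_slope)), call. = FALSE)
    class(out) <- c("cw_fishing", "data.frame")
    out
  })
}

#' Rank fished candidates within each trend direction
#'
#' Splits the fishing results into up- and down-regulated genes by linear
#' slope sign and ranks each group by ascending observed MSE (permutation
#' p-value, then gene ID, as tie-breakers), returning the top `top_k` of
#' each.
#'
#' @param results Output of [permutation_pvalues()].
#' @param top_k Number of genes per direction (default 25).
#' @return List with data.frames `up` and `down`, each with a 1-based `rank`
#'   column.
#' @export
rank_candidates <- function(results, top_k = 25) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  pick <- function(dir) {
    d <- results[results$direction == dir, , drop = FALSE]
    d <- d[order(d$mse, d$p_literal, d$gene_id), , drop = FALSE]
    d <- utils::head(d, top_k)
    if (nrow(d)) d$rank <- seq_len(nrow(d))
    rownames(d) <- NULL
    d
  }
  list(up = pick("up"), down = pick("down"))
}
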