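#' Remove low-complexity cells by TPM quality control
#'
#' A cell is kept if at least `min_genes` genes exceed `tpm_threshold` TPM in
#' that cell; cells with fewer detected genes are discarded.  The rule is
#' strict on the threshold (`> tpm_threshold`) and inclusive on the count
#' (`>= min_genes`), so a cell with exactly `min_genes` detected genes passes.
#'
#' @param m A [expression_matrix()] with `unit == "TPM"`.
#' @param min_genes Minimum number of detected genes per cell.
#' @param tpm_threshold Detection threshold (TPM strictly above this counts).
#' @return The filtered `cw_matrix`, with the IDs of removed cells in
#'   attribute `"removed_cells"`.
#' @export
qc_filter_cells <- function(m, min_genes = 5000, tpm_threshold = 1) {
  stopifnot(inherits(m, "cw_matrix"))
  if (m$unit != "TPM")
    cw_stop("qc_filter_cells requires TPM values (unit is \"%s\")", m$unit)
  detected <- colSums(m$values > tpm_threshold)
  keep <- detected >= min_genes
  out <- subset_cells(m, keep)
  attr(out, "removed_cells") <- colnames(m$values)[!keep]
  out
}

#' Median-by-ratio normalization
#'
#' Computes one size factor per cell as the median, across reference genes, of
#' that cell's expression divided by the gene's geometric mean, then divides
#' each cell's column by its size factor.  Reference genes are by default the
#' genes strictly positive in every cell (the classical median-of-ratios
#' reference set); `min_frac` relaxes this to genes positive in at least that
#' fraction of cells, with geometric means and ratios then taken over the
#' positive entries only.
#'
#' @param m A [expression_matrix()] of counts.
#' @param min_frac Fraction of cells in which a reference gene must be
#'   positive (default 1 = all cells).
#' @return A list with `matrix` (the normalized `cw_matrix`, unit
#'   `"normalized"`) and `size_factors` (named positive reals, one per cell).
#' @export
median_by_ratio_normalize <- function(m, min_frac = 1) {
  stopifnot(inherits(m, "cw_matrix"))
  v <- m$values
  pos_frac <- rowMeans(v > 0)
  ref <- pos_frac >= min_frac & pos_frac > 0
  if (!any(ref))
    cw_stop(paste("no gene is positive in all cells; relax the reference-gene",
                  "rule with min_frac < 1"))
  vr <- v[ref, , drop = FALSE]
  logv <- log(vr)
  logv[!is.finite(logv)] <- NA   # zeros excluded when min_frac < 1
  geo <- exp(rowMeans(logv, na.rm = TRUE))
  ratios <- vr / geo
  ratios[vr == 0] <- NA
  sf <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  if (anyNA(sf) || any(!is.finite(sf)) || any(sf <= 0))
    cw_stop("size factors must be finite and > 0; check the reference-gene set")
  names(sf) <- colnames(v)
  norm <- sweep(v, 2L, sf, "/")
  list(matrix = expression_matrix(norm, as.character(m$time),
                                  time_levels = levels(m$time),
                                  unit = "normalized"),
       size_factors = sf)
}

#' Drop genes with low median expression
#'
#' Keeps genes whose median expression across cells is at least `min_median`
#' (strictly lower medians are removed).
#'
#' @param m A normalized [expression_matrix()].
#' @param min_median Minimum per-gene median.
#' @return The filtered `cw_matrix`, dropped gene IDs in attribute
#'   `"dropped_genes"`.
#' @export
filter_low_median_genes <- function(m, min_median = 10) {
  stopifnot(inherits(m, "cw_matrix"))
  med <- apply(m$values, 1L, stats::median)
  keep <- med >= min_median
  out <- subset_genes(m, keep)
  attr(out, "dropped_genes") <- rownames(m$values)[!keep]
  out
}

#' Standardize each gene to mean 0, variance 1
#'
#' Optionally log-transforms (`log2(x + 1)`) and then rescales every gene row
#' to mean 0 and unit sample variance (`n - 1` denominator), so that mean
#' squared errors are comparable across genes.  Genes with zero variance
#' carry no ordering information and are dropped (and listed) rather than
#' kept as zero rows.
#'
#' @param m A [expression_matrix()].
#' @param log_transform Apply `log2(x + 1)` before standardizing
#'   (default `TRUE`, the scale on which expression profiles are displayed
#'   and ordered).
#' @return An object of class `cw_rescaled`: list with `values` (the
#'   standardized matrix), `time`, `gene_mean`, `gene_sd` (statistics on the
#'   possibly log scale), `log_transform`, and `dropped_genes`.
#' @export
rescale_genes <- function(m, log_transform = TRUE) {
  stopifnot(inherits(m, "cw_matrix"))
  if (ncol(m$values) < 2) cw_stop("rescaling needs at least 2 cells")
  v <- m$values
  if (log_transform) v <- log2(v + 1)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  keep <- sdv > 0
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  structure(
    list(values = z, time = m$time,
         gene_mean = mu[keep], gene_sd = sdv[keep],
         log_transform = log_transform,
         dropped_genes = rownames(v)[!keep]),
    class = "cw_rescaled")
}

#' @export
print.cw_rescaled <- function(x, ...) {
  cat(sprintf("<cw_rescaled> %d genes x %d cells (mean 0, sd 1 per gene%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_transform) ", log2(x+1) scale" else ""))
  invisible(x)
}

#' Differentiation Score for a knockdown condition
#'
#' Ratio of the percentage of CXCR4-positive cells to the percentage of
#' T-reporter (EGFP)-positive cells, normalized by the same ratio in the
#' non-targeting control so that the control scores exactly 1.  Scores below
#' 1 indicate that the perturbation slowed progression toward definitive
#' endoderm.
#'
#' @param pct_cxcr4,pct_egfp Percentages of CXCR4+ and EGFP+ cells in the
#'   perturbed condition, each in (0, 100].
#' @param control_pct_cxcr4,control_pct_egfp The same percentages in the
#'   non-targeting control.
#' @return A single number; the control evaluated against itself returns 1.
#' @examples
#' differentiation_score(40, 20, 30, 30)  # 2: relatively more CXCR4+ cells
#' @export
differentiation_score <- function(pct_cxcr4, pct_egfp,
                                  control_pct_cxcr4, control_pct_egfp) {
  p <- c(pct_cxcr4, pct_egfp, control_pct_cxcr4, control_pct_egfp)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 100))
    cw_stop("all percentages must lie in (0, 100]")
  (pct_cxcr4 / pct_egfp) / (control_pct_cxcr4 / control_pct_egfp)
}
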