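#' Fit PCA on standardized bulk RNA-seq
#'
#' Standardizes every gene of the bulk matrix to mean 0, standard deviation 1
#' across samples and decomposes the result by PCA, with samples as
#' observations and genes as variables.  The per-gene loadings define fixed
#' axes onto which single cells are later projected with [project_cells()],
#' so that the low-dimensional embedding of the cells is supervised by the
#' (much less noisy) bulk data.  Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making outputs reproducible across
#' linear-algebra backends.
#'
#' @param bulk A normalized [expression_matrix()] of bulk samples (genes x
#'   samples).
#' @param n_components Number of components to keep; at most
#'   `min(#samples - 1, #genes)`.
#' @param log_transform Apply `log2(x + 1)` before standardizing (default
#'   `FALSE`: bulk values are already on a comparable scale after
#'   normalization; set `TRUE` to match log-scale single-cell rescaling).
#' @return An object of class `cw_pca`: list with `genes` (IDs retained,
#'   constant genes excluded), `loadings` (gene x component matrix `W` with
#'   orthonormal columns), `explained_variance` (per component), `bulk_mean`
#'   and `bulk_sd` (per-gene standardization parameters), `bulk_scores`
#'   (sample x component), and `log_transform`.
#' @export
fit_bulk_pca <- function(bulk, n_components, log_transform = FALSE) {
  stopifnot(inherits(bulk, "cw_matrix"))
  if (ncol(bulk$values) < 2) cw_stop("need at least 2 bulk samples")
  rs <- rescale_genes(bulk, log_transform = log_transform)
  z <- rs$values                      # genes x samples, each row mean 0 sd 1
  max_comp <- min(ncol(z) - 1L, nrow(z))
  if (n_components < 1 || n_components > max_comp)
    cw_stop("n_components must be in 1..%d for %d samples", max_comp, ncol(z))
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(W, 2L, function(w) sign(w[which.max(abs(w))]))
  W <- sweep(W, 2L, flip, "*")
  scores <- t(z) %*% W
  colnames(W) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(
    list(genes = rownames(z), loadings = W,
         explained_variance = pc$sdev[seq_len(n_components)]^2,
         bulk_mean = rs$gene_mean, bulk_sd = rs$gene_sd,
         bulk_scores = scores, log_transform = log_transform),
    class = "cw_pca")
}

#' @export
print.cw_pca <- function(x, ...) {
  cat(sprintf("<cw_pca> %d genes, %d components\n",
              length(x$genes), ncol(x$loadings)))
  ev <- x$explained_variance / sum(x$explained_variance)
  cat("  variance share:", paste(sprintf("%.1f%%", 100 * ev), collapse = " "), "\n")
  invisible(x)
}

#' Project standardized single cells onto bulk-derived components
#'
#' The score of cell `j` on component `n` is the inner product over shared
#' genes of the bulk loading vector with the cell's standardized expression:
#' `score[j, n] = sum_g W[g, n] * Z[g, j]`.  Cells must be standardized with
#' their own per-gene statistics (see [rescale_genes()]); genes absent from
#' either side are dropped and reported.
#'
#' @param model A [fit_bulk_pca()] model.
#' @param cells A `cw_rescaled` object (single cells standardized per gene).
#' @return Cell-by-component numeric matrix of scores, with the IDs of genes
#'   used in attribute `"genes_used"` and dropped IDs in `"genes_dropped"`.
#' @export
project_cells <- function(model, cells) {
  stopifnot(inherits(model, "cw_pca"), inherits(cells, "cw_rescaled"))
  shared <- intersect(model$genes, rownames(cells$values))
  if (!length(shared)) cw_stop("no genes shared between model and cells")
  scores <- t(cells$values[shared, , drop = FALSE]) %*%
    model$loadings[shared, , drop = FALSE]
  attr(scores, "genes_used") <- shared
  attr(scores, "genes_dropped") <- union(setdiff(model$genes, shared),
                                         setdiff(rownames(cells$values), shared))
  scores
}

#' Absolute loading weights of one component
#'
#' Returns `|W[g, n]|` per gene, the weight of each gene's contribution to
#' the chosen component, as a two-column table suitable for weighted
#' gene-set enrichment tools.
#'
#' @param model A [fit_bulk_pca()] model.
#' @param component Component index.
#' @return A data.frame with columns `gene_id` and `weight` (>= 0), sorted by
#'   decreasing weight.
#' @export
export_loading_weights <- function(model, component) {
  stopifnot(inherits(model, "cw_pca"))
  if (component < 1 || component > ncol(model$loadings))
    cw_stop("component must be in 1..%d", ncol(model$loadings))
  w <- abs(model$loadings[, component])
  out <- data.frame(gene_id = model$genes, weight = unname(w))
  out[order(-out$weight, out$gene_id), , drop = FALSE]
}
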