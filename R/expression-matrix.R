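#' Gene-by-cell expression matrix with collection-time labels
#'
#' The central container of the package: a dense numeric matrix with genes as
#' rows and cells (or bulk samples) as columns, where every column carries a
#' collection-time label drawn from a declared ordered set of time points.
#' Values are non-negative expression measurements; the `unit` field records
#' whether they are expected counts, TPM, or normalized counts, because the
#' quality-control and normalization steps are unit-specific.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. Must have
#'   unique, non-empty rownames (gene IDs) and colnames (cell IDs); all values
#'   finite and >= 0.
#' @param time Vector of collection-time labels, one per cell, each a level of
#'   `time_levels`.
#' @param time_levels Character vector giving the time points in course order.
#'   Defaults to the unique labels in `time` in order of first appearance.
#' @param unit One of `"counts"`, `"TPM"`, `"normalized"`.
#'
#' @return An object of class `cw_matrix`: a list with elements `values`
#'   (the matrix), `time` (an ordered factor over `time_levels`), and `unit`.
#' @examples
#' m <- expression_matrix(
#'   matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2"))),
#'   time = c("0h", "0h")
#' )
#' print(m)
#' @export
expression_matrix <- function(values, time,
                              time_levels = unique(as.character(time)),
                              unit = c("counts", "TPM", "normalized")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    cw_stop("`values` must be a numeric matrix (genes x cells)")
  storage.mode(values) <- "double"
  gid <- rownames(values); cid <- colnames(values)
  if (is.null(gid) || is.null(cid))
    cw_stop("`values` needs rownames (gene IDs) and colnames (cell IDs)")
  if (anyDuplicated(gid)) cw_stop("duplicate gene IDs: %s",
                                  paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(cid)) cw_stop("duplicate cell IDs: %s",
                                  paste(unique(cid[duplicated(cid)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    cw_stop("expression values must be finite")
  if (any(values < 0)) cw_stop("expression values must be >= 0")
  time <- as.character(time)
  if (length(time) != ncol(values))
    cw_stop("`time` must have one label per cell (%d cells, %d labels)",
            ncol(values), length(time))
  bad <- setdiff(unique(time), time_levels)
  if (length(bad))
    cw_stop("time labels not in declared ordered set: %s", paste(bad, collapse = ", "))
  structure(
    list(values = values,
         time = factor(time, levels = time_levels, ordered = TRUE),
         unit = unit),
    class = "cw_matrix")
}

#' @export
print.cw_matrix <- function(x, ...) {
  cat(sprintf("<cw_matrix> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$time)
  cat("  time points:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cw_matrix <- function(x) dim(x$values)

# Column-subset a cw_matrix, keeping time labels aligned.
subset_cells <- function(m, keep) {
  expression_matrix(m$values[, keep, drop = FALSE], as.character(m$time[keep]),
                    time_levels = levels(m$time), unit = m$unit)
}

subset_genes <- function(m, keep) {
  expression_matrix(m$values[keep, , drop = FALSE], as.character(m$time),
                    time_levels = levels(m$time), unit = m$unit)
}

#' Read an expression matrix with cell metadata
#'
#' Reads a gene-by-cell matrix from dense TSV/CSV (first column gene ID,
#' header row of cell IDs) or MatrixMarket triplet format (with sidecar
#' one-column gene-ID and cell-ID files `<path>.genes.txt` /
#' `<path>.cells.txt`), plus a metadata CSV with columns `cell_id,time_label`
#' assigning each cell to a collection time.  Cells are restricted to those
#' present in the metadata; a cell in the matrix that the metadata does not
#' cover is an error, named in the message.
#'
#' @param path Matrix file.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`.
#' @param meta_path Metadata CSV (`cell_id,time_label` header).
#' @param time_levels Ordered time points; default: order of first appearance
#'   in the metadata.
#' @param unit Unit flag stored on the result (see [expression_matrix()]).
#' @param transpose Set `TRUE` if the file stores cells in rows.
#' @return A [expression_matrix()] object.
#' @export
load_matrix <- function(path, format = c("tsv", "csv", "mtx"), meta_path,
                        time_levels = NULL,
                        unit = c("counts", "TPM", "normalized"),
                        transpose = FALSE) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  for (p in c(path, meta_path))
    if (!file.exists(p)) cw_stop("file not found: %s", p)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df)
  } else {
    gpath <- paste0(path, ".genes.txt"); cpath <- paste0(path, ".cells.txt")
    for (p in c(gpath, cpath))
      if (!file.exists(p)) cw_stop("MatrixMarket sidecar file not found: %s", p)
    vals <- as.matrix(Matrix::readMM(path))
    rownames(vals) <- readLines(gpath)
    colnames(vals) <- readLines(cpath)
  }
  if (transpose) vals <- t(vals)
  storage.mode(vals) <- "double"
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_label")
  if (!all(need %in% names(meta)))
    cw_stop("metadata must have columns %s", paste(need, collapse = ", "))
  orphan <- setdiff(colnames(vals), meta$cell_id)
  if (length(orphan))
    cw_stop("cells absent from metadata: %s", paste(orphan, collapse = ", "))
  meta <- meta[match(colnames(vals), meta$cell_id), ]
  if (is.null(time_levels)) time_levels <- unique(meta$time_label)
  expression_matrix(vals, meta$time_label, time_levels = time_levels, unit = unit)
}

#' Write an expression matrix (and its metadata) to disk
#'
#' Inverse of [load_matrix()]: dense TSV/CSV with gene IDs in the first
#' column, or MatrixMarket triplets with the two sidecar ID files.  Values are
#' written at full double precision so that a write/load round trip
#' reproduces them to within 1e-12 relative error.
#'
#' @param m A [expression_matrix()] object.
#' @param path Output matrix file.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`.
#' @param meta_path Optional path for the `cell_id,time_label` metadata CSV.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx"),
                         meta_path = NULL) {
  format <- match.arg(format)
  v <- m$values
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    chr <- matrix(num_chr(v), nrow(v), dimnames = dimnames(v))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(v)), collapse = sep), con)
    body <- apply(cbind(rownames(v), chr), 1L, paste, collapse = sep)
    writeLines(body, con)
  } else {
    nz <- which(v != 0, arr.ind = TRUE)
    con <- file(path, "w")
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(v), ncol(v), nrow(nz)), con)
    writeLines(sprintf("%d %d %s", nz[, 1L], nz[, 2L], num_chr(v[nz])), con)
    close(con)
    writeLines(rownames(v), paste0(path, ".genes.txt"))
    writeLines(colnames(v), paste0(path, ".cells.txt"))
  }
  if (!is.null(meta_path))
    utils::write.csv(
      data.frame(cell_id = colnames(v), time_label = as.character(m$time)),
      meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
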