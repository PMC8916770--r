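#' Cells-by-genes expression container
#'
#' `expr_matrix()` wraps a non-negative cells x genes matrix (dense or
#' sparse) together with unique cell and gene identifiers and a layer tag
#' saying whether the values are raw counts or normalized expression.
#' Internally values are stored as a sparse [Matrix::dgCMatrix-class] with
#' cells as rows — per-cell operations (ranking, detection counts, depth
#' scaling) dominate every workflow in this package.
#'
#' @param values numeric matrix or Matrix, cells in rows, genes in columns,
#'   all entries >= 0. Dimnames, if present, seed `cell_ids`/`gene_ids`.
#' @param gene_ids,cell_ids character vectors of unique identifiers; taken
#'   from `dimnames(values)` when omitted.
#' @param layer `"counts"` (integer-valued) or `"normalized"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(rpois(12, 2), 3, 4), layer = "counts")
#' gene_counts(m)
#' @export
expr_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                        layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  if (!inherits(values, "Matrix"))
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (length(values@x) && min(values@x) < 0)
    stop("expression values must be non-negative", call. = FALSE)
  if (layer == "counts" && length(values@x) &&
      max(abs(values@x - round(values@x))) > 1e-8)
    stop("a counts layer must contain integers", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<expr_matrix> %d cells x %d genes [%s], %.1f%% zero\n",
              nrow(v), ncol(v), x$layer,
              100 * (1 - length(v@x) / prod(dim(v)))))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) colnames(x$values)

#' @rdname expr_matrix
#' @export
cell_ids <- function(x) rownames(x$values)

#' Number of detected genes per cell
#'
#' Counts, for every cell, the genes with expression strictly above zero
#' (the complement of the cell's dropout rate). Invariant under any
#' positive per-cell rescaling.
#'
#' @param x an [expr_matrix()].
#' @return A tibble with columns `cell_id` and `n_genes`.
#' @export
gene_counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  tibble::tibble(cell_id = cell_ids(x),
                 n_genes = as.integer(Matrix::rowSums(x$values > 0)))
}

#' Rescale every cell to a common total
#'
#' Divides each cell's values by its total and multiplies by
#' `target_total`, so all cells end at identical coverage. The zero
#' pattern is unchanged; this is the "scaled back to equal total
#' coverage" step applied after down-sampling, and a generic per-cell
#' depth normalization.
#'
#' @param x an [expr_matrix()]; every cell must have a positive total.
#' @param target_total positive scalar, the common post-scaling total.
#' @return An `expr_matrix` with layer `"normalized"`.
#' @export
normalize_cells <- function(x, target_total = 1e4) {
  stopifnot(inherits(x, "expr_matrix"), target_total > 0)
  tot <- Matrix::rowSums(x$values)
  if (any(tot <= 0))
    stop("cell(s) with zero total: ",
         paste(utils::head(cell_ids(x)[tot <= 0], 5), collapse = ", "),
         call. = FALSE)
  v <- x$values * (target_total / tot)
  expr_matrix(v, layer = "normalized")
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an [expr_matrix()].
#' @param cells,genes character identifiers or index vectors; `NULL` keeps all.
#' @return An `expr_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  expr_matrix(v, layer = x$layer)
}

#' Read expression matrices and cell annotations
#'
#' `read_matrix_mtx()` reads a MatrixMarket sparse matrix with sidecar
#' one-id-per-line gene and cell files. CellRanger-style genes x cells
#' orientation is the on-disk convention, so the matrix is transposed to
#' the internal cells x rows layout on load. `read_matrix_table()` reads a
#' dense delimited table whose header row holds gene ids and whose first
#' column holds cell ids. `read_cell_annotation()` reads a TSV with
#' columns `cell_id` and `group`.
#'
#' @param mtx,genes_file,cells_file,path file paths.
#' @param layer layer tag passed to [expr_matrix()].
#' @param delim field delimiter for the dense reader.
#' @return An `expr_matrix`, or a tibble for the annotation reader.
#' @export
read_matrix_mtx <- function(mtx, genes_file, cells_file,
                            layer = c("counts", "normalized")) {
  m <- Matrix::readMM(mtx)
  g <- readr::read_lines(genes_file)
  cells <- readr::read_lines(cells_file)
  expr_matrix(Matrix::t(m), gene_ids = g, cell_ids = cells,
              layer = match.arg(layer))
}

#' @rdname read_matrix_mtx
#' @export
read_matrix_table <- function(path, layer = c("counts", "normalized"),
                              delim = "\t") {
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  expr_matrix(m, layer = match.arg(layer))
}

#' @rdname read_matrix_mtx
#' @export
read_cell_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("cell_id", "group") %in% names(ann)))
    stop("annotation file needs columns cell_id and group", call. = FALSE)
  tibble::as_tibble(ann[, c("cell_id", "group")])
}

#' Write an expression matrix as MatrixMarket plus sidecar id lists
#'
#' The on-disk orientation is genes x cells, mirroring the reader.
#'
#' @param x an [expr_matrix()].
#' @param mtx,genes_file,cells_file output paths.
#' @return `x`, invisibly.
#' @export
write_matrix_mtx <- function(x, mtx, genes_file, cells_file) {
  stopifnot(inherits(x, "expr_matrix"))
  Matrix::writeMM(Matrix::t(x$values), mtx)
  readr::write_lines(gene_ids(x), genes_file)
  readr::write_lines(cell_ids(x), cells_file)
  invisible(x)
}
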