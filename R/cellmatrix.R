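#' Single-cell count container
#'
#' A `CellMatrix` bundles a sparse genes x cells UMI count matrix with
#' per-cell and per-gene metadata, the minimal container every pipeline
#' stage consumes. Cell metadata carries the sample of origin, batch,
#' case/control status, sex, doublet flags and (after QC) mitochondrial
#' fraction and the number of detected genes (NODG).
#'
#' @param counts sparse (or dense) numeric matrix, genes in rows, cells in
#'   columns. Coerced to `dgCMatrix`. Row names are gene identifiers,
#'   column names cell barcodes.
#' @param cells data.frame with one row per cell. Must contain a
#'   `sample` column; a `barcode` column is added from the matrix
#'   column names when absent.
#' @param genes data.frame with one row per gene (optional columns:
#'   `chrom`, `pos`). A `gene` column is added from row names when absent.
#'
#' @return An object of class `CellMatrix`: a list with elements
#'   `counts`, `cells`, `genes`.
#' @export
CellMatrix <- function(counts, cells, genes = NULL) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
  if (is.null(genes)) genes <- data.frame(gene = rownames(counts))
  if (!"gene" %in% names(genes)) genes$gene <- rownames(counts)
  if (!"barcode" %in% names(cells)) cells$barcode <- colnames(counts)
  stopifnot(nrow(cells) == ncol(counts), nrow(genes) == nrow(counts))
  if (!"sample" %in% names(cells))
    stop("cell metadata must contain a 'sample' column")
  rownames(cells) <- cells$barcode
  rownames(genes) <- genes$gene
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "CellMatrix")
}

#' @exportS3Method base::print
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample))))
  extra <- setdiff(names(x$cells), c("barcode", "sample"))
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Subset a CellMatrix by gene and/or cell index
#'
#' @param cm CellMatrix
#' @param genes,cells logical, integer or character index into rows/columns;
#'   `NULL` keeps everything.
#' @return CellMatrix restricted to the selected genes and cells.
#' @export
subset_cells <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "CellMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(cm$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(cm$counts)) else cells
  CellMatrix(cm$counts[gi, ci, drop = FALSE],
             cm$cells[ci, , drop = FALSE],
             cm$genes[gi, , drop = FALSE])
}

#' Derive a per-stage sub-seed from one master seed
#'
#' Deterministic, stage-order independent, and always below 2^31, so one
#' config seed yields independent reproducible streams per pipeline
#' stage.
#' @param seed master integer seed.
#' @param stage stage name (character).
#' @return integer sub-seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647L)
}
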