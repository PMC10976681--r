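#' Write a CellMatrix as an MTX triplet directory
#'
#' Emits `matrix.mtx` (1-based MatrixMarket triplet, genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `cells.tsv` (full cell metadata).
#'
#' @param cm CellMatrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CellMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(cm$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CellMatrix from an MTX triplet directory
#'
#' Expects the layout written by [write_counts()] (1-based MatrixMarket
#' indices; `cells.tsv` optional, `barcodes.tsv` required). Duplicate
#' gene symbols are disambiguated by suffixing and reported.
#'
#' @param dir directory path.
#' @return CellMatrix.
#' @export
read_counts <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("no matrix.mtx under ", dir)
  # MatrixMarket coordinate format is 1-based by definition; a 0 index
  # means the file was written 0-based
  hdr <- readLines(mtx_path, n = 50L)
  body <- hdr[!startsWith(hdr, "%")]
  if (length(body) >= 2) {
    first <- suppressWarnings(as.numeric(strsplit(trimws(body[2]), "\\s+")[[1]]))
    if (length(first) >= 2 && any(first[1:2] == 0))
      stop("matrix.mtx contains 0-based indices; MTX triplets must be 1-based")
  }
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  bc_path <- file.path(dir, "barcodes.tsv")
  if (!file.exists(bc_path)) stop("missing barcodes.tsv")
  barcodes <- readLines(bc_path)
  if (!length(barcodes)) stop("empty barcodes file")
  if (nrow(genes) != nrow(m) || length(barcodes) != ncol(m))
    stop(sprintf(paste0("dimension mismatch: matrix %d x %d vs %d genes, ",
                        "%d barcodes"), nrow(m), ncol(m), nrow(genes),
                 length(barcodes)))
  if (anyDuplicated(genes$gene)) {
    dup <- unique(genes$gene[duplicated(genes$gene)])
    message(length(dup), " duplicate gene symbol(s) suffixed")
    genes$gene <- make.unique(genes$gene, sep = ".")
  }
  rownames(m) <- genes$gene
  colnames(m) <- barcodes
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path))
    utils::read.delim(cells_path, stringsAsFactors = FALSE)
  else data.frame(barcode = barcodes, sample = "sample1")
  CellMatrix(m, cells, genes)
}

#' Read a reference panel TSV
#'
#' First column = cell type name, remaining columns named by gene,
#' values log10 expression.
#'
#' @param path TSV path.
#' @param name panel name (default: file base name).
#' @return [reference_panel()].
#' @export
read_panel <- function(path, name = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  reference_panel(m, name = if (is.null(name))
    tools::file_path_sans_ext(basename(path)) else name)
}

#' Write a reference panel TSV
#' @param panel [reference_panel()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(cell_type = rownames(panel$mat), panel$mat,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write DEG sets as JSON (cell type -> up/down gene lists)
#' @param deg_sets per-cell-type `up`/`down` list.
#' @param path JSON path.
#' @return `path` invisibly (write); the list (read).
#' @export
write_deg_sets <- function(deg_sets, path) {
  jsonlite::write_json(deg_sets, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_deg_sets
#' @export
read_deg_sets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(s) list(up = as.character(unlist(s$up)),
                             down = as.character(unlist(s$down))))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Pipeline configuration
#'
#' A flat, JSON-serializable list of every stage parameter, seeded with
#' the conventional defaults of the analysis (kNN k = 50, min 5 cells per
#' pseudo-bulk pair, DEG thresholds |log2FC| >= log2(1.3) and q <= 0.1,
#' 8 DEG modules, 3 molecular subtypes, HLA exclusion chr6:25-35 Mb).
#' Unknown names are rejected so that configs round-trip exactly.
#'
#' @param ... overrides of the defaults.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    counts_dir = NULL, panel_path = NULL, risk_path = NULL,
    mito_max = 0.07, min_frac_genes = 0.001,
    nodg_default = c(500, 2500), nodg_windows = list(),
    knn_k = 50L, pca_d = 30L,
    min_cells = 5L, min_sample_frac = 0.05,
    lfc_min = log2(1.3), q_max = 0.1,
    kmeans_modules_k = 8L, subtype_k = 3L, kmeans_restarts = 25L,
    q_keep = 0.1, top_n_risk = 200L, des_percentile = 70,
    gwas_min_genes = 50L,
    exclude_region = "chr6:25000000-35000000",
    merge_map = NULL, compartment_map = NULL,
    simulate = NULL,
    seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "PipelineConfig")
}

#' Read/write a pipeline config as JSON
#' @param cfg PipelineConfig.
#' @param path JSON path.
#' @return `path` invisibly (write); a `PipelineConfig` (read).
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nodg_windows <- lapply(x$nodg_windows, as.numeric)
  if (!is.null(x$merge_map)) x$merge_map <- unlist(x$merge_map)
  if (!is.null(x$compartment_map)) x$compartment_map <- unlist(x$compartment_map)
  do.call(pipeline_config, x)
}
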