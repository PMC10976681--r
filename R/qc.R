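#' Cluster-specific NODG windows
#'
#' Exclusive per-cluster bounds on the number of detected genes (NODG).
#' Cells pass a window when `low < NODG < high` (strict on both sides).
#' Clusters without an entry fall back to `default_window`.
#'
#' @param windows named list of `c(low, high)` pairs, e.g.
#'   `list(pDC = c(750, 2500), platelet = c(125, 1500))`.
#' @param default_window bounds for unlisted clusters.
#' @return a `NodgWindows` object.
#' @export
nodg_windows <- function(windows = list(), default_window = c(500, 2500)) {
  chk <- c(windows, list(default_window))
  for (w in chk) {
    if (length(w) != 2 || w[1] >= w[2] || any(w <= 0))
      stop("each NODG window must be positive with low < high")
  }
  structure(list(windows = windows, default_window = default_window),
            class = "NodgWindows")
}

window_for <- function(nw, cluster) {
  w <- nw$windows[[as.character(cluster)]]
  if (is.null(w)) nw$default_window else w
}

#' Number of detected genes per cell
#'
#' NODG = number of genes with count > 0, computed on the matrix as given
#' (call before gene filtering to reflect library complexity).
#' @param cm CellMatrix
#' @return integer vector, one entry per cell.
#' @export
nodg <- function(cm) {
  Matrix::colSums(cm$counts > 0)
}

#' Per-cell mitochondrial fraction
#'
#' Fraction of UMI falling on genes whose name matches one of the
#' `prefixes` (the mitochondrial gene-name convention in use).
#' @param cm CellMatrix
#' @param prefixes character vector of gene-name prefixes.
#' @return numeric vector in `[0, 1]` per cell.
#' @export
mito_fraction <- function(cm, prefixes = c("MT-")) {
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")")
  mt <- grepl(pat, rownames(cm$counts))
  if (!any(mt))
    stop("no mitochondrial genes found; expected gene names with prefix: ",
         paste(prefixes, collapse = ", "))
  tot <- Matrix::colSums(cm$counts)
  m <- Matrix::colSums(cm$counts[mt, , drop = FALSE])
  ifelse(tot > 0, m / tot, 0)
}

#' Filter genes by prevalence
#'
#' Retains genes expressed (count > 0) in at least
#' `ceiling(min_frac * n_cells)` cells; the cell set is unchanged.
#'
#' @param cm CellMatrix
#' @param min_frac minimum fraction of cells, in `[0, 1)`. The default
#'   removes genes detected in fewer than 0.1 percent of cells.
#' @return filtered CellMatrix.
#' @export
filter_genes_by_prevalence <- function(cm, min_frac = 0.001) {
  stopifnot(inherits(cm, "CellMatrix"), min_frac >= 0, min_frac < 1)
  if (nrow(cm$counts) == 0 || ncol(cm$counts) == 0)
    stop("empty matrix")
  # min_frac = 0 gives n_min = 0: identity on genes, all-zero genes included
  n_min <- ceiling(min_frac * ncol(cm$counts))
  keep <- Matrix::rowSums(cm$counts > 0) >= n_min
  subset_cells(cm, genes = which(keep))
}

#' Filter cells on mitochondrial fraction, NODG window and doublet flag
#'
#' Keeps cells with mito fraction <= `mito_max`, strictly inside their
#' cluster's NODG window, and (when `drop_doublets`) not flagged as
#' doublets. Mito fraction and NODG are computed from the matrix unless
#' already present as `mito_frac` / `nodg` cell-metadata columns.
#'
#' @param cm CellMatrix; cluster labels are taken from the `cluster`
#'   cell-metadata column when present (else every cell uses the default
#'   window).
#' @param mito_max maximum mitochondrial fraction (kept when `<=`).
#' @param windows a [nodg_windows()] object.
#' @param drop_doublets drop cells with a TRUE `doublet` metadata flag.
#' @param mito_prefixes passed to [mito_fraction()] when recomputing.
#' @return filtered CellMatrix; attribute `"qc_report"` holds the counts
#'   of cells removed per criterion.
#' @export
filter_cells <- function(cm, mito_max = 0.07, windows = nodg_windows(),
                         drop_doublets = TRUE, mito_prefixes = c("MT-")) {
  stopifnot(inherits(cm, "CellMatrix"), inherits(windows, "NodgWindows"))
  mito <- if ("mito_frac" %in% names(cm$cells)) cm$cells$mito_frac
          else mito_fraction(cm, mito_prefixes)
  nd <- if ("nodg" %in% names(cm$cells)) cm$cells$nodg else nodg(cm)
  cl <- if ("cluster" %in% names(cm$cells)) cm$cells$cluster
        else rep("default", ncol(cm$counts))
  lo <- hi <- numeric(length(cl))
  for (u in unique(cl)) {
    w <- window_for(windows, u)
    lo[cl == u] <- w[1]; hi[cl == u] <- w[2]
  }
  pass_mito <- mito <= mito_max
  pass_nodg <- nd > lo & nd < hi
  dbl <- if ("doublet" %in% names(cm$cells)) as.logical(cm$cells$doublet)
         else rep(FALSE, ncol(cm$counts))
  pass_dbl <- if (drop_doublets) !dbl else rep(TRUE, length(dbl))
  keep <- pass_mito & pass_nodg & pass_dbl
  out <- subset_cells(cm, cells = which(keep))
  out$cells$mito_frac <- mito[keep]
  out$cells$nodg <- nd[keep]
  attr(out, "qc_report") <- data.frame(
    criterion = c("mito_fraction", "nodg_window", "doublet", "total_removed"),
    removed = c(sum(!pass_mito), sum(!pass_nodg),
                sum(pass_mito & pass_nodg & !pass_dbl), sum(!keep)))
  out
}

#' Sex-concordance check
#'
#' Per sample, the mean over cells of the summed natural-log (log1p)
#' expression of Y-chromosome genes (and likewise X genes). Samples whose
#' Y score falls on the wrong side of the midpoint between the two
#' annotated-sex group means are flagged as discordant. With a single-sex
#' cohort the threshold is undefined and no flags are produced.
#'
#' @param cm CellMatrix with `sample` and (optionally) `sex` metadata
#'   (1 = male, 0 = female).
#' @param y_genes,x_genes nonempty gene-name vectors present in the matrix.
#' @return data.frame per sample: `y_score`, `x_score`, `sex` (if
#'   annotated), `flag`.
#' @export
sex_concordance <- function(cm, y_genes = Y_GENES, x_genes = X_GENES) {
  stopifnot(inherits(cm, "CellMatrix"),
            length(y_genes) > 0, length(x_genes) > 0)
  yg <- intersect(y_genes, rownames(cm$counts))
  xg <- intersect(x_genes, rownames(cm$counts))
  if (!length(yg) || !length(xg))
    stop("Y/X gene lists not present in the matrix")
  nl <- function(idx) Matrix::colSums(log1p(cm$counts[idx, , drop = FALSE]))
  ys <- nl(yg); xs <- nl(xg)
  samp <- cm$cells$sample
  agg <- function(v) tapply(v, samp, mean)
  out <- data.frame(sample = names(agg(ys)),
                    y_score = as.numeric(agg(ys)),
                    x_score = as.numeric(agg(xs)))
  if ("sex" %in% names(cm$cells)) {
    sex <- tapply(cm$cells$sex, samp, function(s) s[1])
    out$sex <- as.integer(sex[out$sample])
    out$flag <- FALSE
    if (length(unique(out$sex)) == 2) {
      thr <- mean(c(mean(out$y_score[out$sex == 1]),
                    mean(out$y_score[out$sex == 0])))
      out$flag <- (out$sex == 1) != (out$y_score > thr)
      attr(out, "threshold") <- thr
    }
  }
  rownames(out) <- NULL
  out
}
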