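#' Per-sample cell-type proportions
#'
#' Proportion = 100 * n(type, sample) / n(sample) (% of PBMC). Optional
#' pairwise proportion ratios (e.g. effector-memory over regulatory T)
#' are appended as extra columns; a zero denominator yields NA.
#'
#' @param labels per-cell type labels.
#' @param sample_of_cell per-cell sample ids (same length).
#' @param covariates optional per-sample data.frame (rownames or `sample`
#'   column = sample id) carried into the result.
#' @param ratios named list of `c(numerator, denominator)` type pairs, or
#'   character vector like `"CD4_EM/Treg"`.
#' @param exclude labels to drop before computing proportions (e.g.
#'   `"ambiguous"`).
#' @return a `CompositionTable`: data.frame samples x (types, ratio
#'   columns) with attribute `covariates`.
#' @export
compute_proportions <- function(labels, sample_of_cell, covariates = NULL,
                                ratios = NULL, exclude = "ambiguous") {
  stopifnot(length(labels) == length(sample_of_cell))
  keep <- !is.na(labels) & !(labels %in% exclude)
  labels <- labels[keep]; sample_of_cell <- sample_of_cell[keep]
  n_samp <- table(sample_of_cell)
  if (any(n_samp == 0)) warning("samples with 0 cells excluded")
  tab <- table(sample_of_cell, labels)
  prop <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  out <- as.data.frame.matrix(prop)
  if (!is.null(ratios)) {
    if (is.character(ratios)) {
      nm <- ratios
      ratios <- lapply(strsplit(ratios, "/", fixed = TRUE), identity)
      names(ratios) <- nm
    }
    for (nm in names(ratios)) {
      pr <- ratios[[nm]]
      num <- if (pr[1] %in% colnames(out)) out[[pr[1]]] else rep(0, nrow(out))
      den <- if (pr[2] %in% colnames(out)) out[[pr[2]]] else rep(0, nrow(out))
      out[[nm]] <- ifelse(den > 0, num / den, NA_real_)
    }
  }
  if (!is.null(covariates)) {
    key <- if ("sample" %in% names(covariates)) covariates$sample
           else rownames(covariates)
    covariates <- covariates[match(rownames(out), key), , drop = FALSE]
    rownames(covariates) <- rownames(out)
  }
  structure(out, covariates = covariates,
            ratio_columns = names(ratios),
            class = c("CompositionTable", "data.frame"))
}

#' Covariate regression on cell-type proportions
#'
#' Per response column, ordinary least squares of the proportion on the
#' covariates (linear terms, Gaussian response — the additive-model
#' special case the composition analysis assumes), with per-coefficient
#' partial F-tests. p < 0.05 is flagged significant.
#'
#' @param tbl CompositionTable from [compute_proportions()].
#' @param covariates character vector of covariate column names present
#'   in `attr(tbl, "covariates")` (or a data.frame of covariates).
#' @param responses response columns (default: all type/ratio columns).
#' @return data.frame: `response`, `term`, `estimate`, `se`, `F`, `p`,
#'   `significant`.
#' @export
composition_regression <- function(tbl, covariates, responses = NULL) {
  cov_df <- if (is.data.frame(covariates)) covariates
            else attr(tbl, "covariates")[, covariates, drop = FALSE]
  if (is.null(cov_df)) stop("no covariates available")
  if (is.null(responses)) responses <- colnames(tbl)
  cc <- stats::complete.cases(cov_df)
  if (sum(cc) < ncol(cov_df) + 2)
    stop("need at least covariates + 2 complete samples")
  X <- stats::model.matrix(~ ., data = cov_df[cc, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design; aliased columns: ", paste(bad, collapse = ", "))
  }
  res <- lapply(responses, function(rv) {
    y <- tbl[[rv]][cc]
    ok <- is.finite(y)
    fit <- stats::lm(y[ok] ~ ., data = cov_df[cc, , drop = FALSE][ok, , drop = FALSE])
    sm <- summary(fit)$coefficients
    # partial F for a single coefficient equals its squared t statistic
    data.frame(response = rv, term = rownames(sm),
               estimate = sm[, 1], se = sm[, 2],
               F = sm[, 3]^2,
               p = sm[, 4], row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < 0.05
  out
}

#' PCA embedding of normalized expression
#'
#' Top principal components of the cells, computed from the centered
#' normalized matrix. Used as the expression-space coordinates for the
#' kNN case-enrichment field.
#'
#' @param norm_expr genes x cells matrix from [normalize_cells()].
#' @param d number of components (default 30; capped at the matrix rank).
#' @return cells x d coordinate matrix.
#' @export
pca_embed <- function(norm_expr, d = 30L) {
  X <- t(as.matrix(norm_expr))             # cells x genes
  X <- sweep(X, 2, colMeans(X), "-")
  d <- min(d, dim(X) - 1L)
  sv <- svd(X, nu = d, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("PC", seq_len(d))
  emb
}

#' kNN case-enrichment field in expression space
#'
#' For every cell, among its `k` nearest Euclidean neighbors (itself
#' excluded), the log2 ratio of case to control neighbors, normalized by
#' the global case/control ratio so the null is centered at zero:
#' `e = log2(((n_case + c) / (n_ctrl + c)) / (N_case / N_ctrl))` with
#' pseudocount `c` (default 0.5). Ties in neighbor distance are broken by
#' cell index for determinism.
#'
#' @param embedding cells x d coordinate matrix (e.g. [pca_embed()]).
#' @param case_flag logical/0-1 vector per cell; both classes required.
#' @param k neighborhood size (default 50, must satisfy 0 < k < n).
#' @param pseudocount smoothing constant `c`.
#' @param block cells per distance block (memory/speed trade-off).
#' @return numeric per-cell enrichment vector.
#' @export
neighborhood_enrichment <- function(embedding, case_flag, k = 50L,
                                    pseudocount = 0.5, block = 512L) {
  n <- nrow(embedding)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  case_flag <- as.logical(case_flag)
  if (!any(case_flag) || all(case_flag))
    stop("both classes must be present")
  # kept as a difference of logs so swapping the labels negates every
  # term exactly (bitwise antisymmetry at pseudocount 0)
  l_global <- log2(sum(case_flag)) - log2(sum(!case_flag))
  sq <- rowSums(embedding^2)
  e <- numeric(n)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    # squared Euclidean distances of the block against all cells
    D <- outer(sq[idx], sq, "+") - 2 * embedding[idx, , drop = FALSE] %*% t(embedding)
    for (j in seq_along(idx)) {
      i <- idx[j]
      d <- D[j, ]
      d[i] <- Inf
      nb <- order(d)[seq_len(k)]           # order() breaks ties by index
      nc <- sum(case_flag[nb])
      e[i] <- log2(nc + pseudocount) - log2(k - nc + pseudocount) - l_global
    }
  }
  names(e) <- rownames(embedding)
  e
}
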