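#' Build per-cell-type pseudo-bulk profiles
#'
#' Per (sample, cell type), gene-wise sums of UMI counts. Pairs built
#' from fewer than `min_cells` cells are excluded, and within each cell
#' type genes with a nonzero pseudo-bulk count in fewer than
#' `ceiling(min_sample_frac * n_retained_samples)` samples are dropped.
#' Cell types left with fewer than 3 retained samples in either
#' case/control group are skipped with a warning.
#'
#' @param cm CellMatrix with `sample` (and ideally `disease`) metadata.
#' @param labels per-cell type labels (cells labelled NA or
#'   `"ambiguous"` are ignored).
#' @param min_cells minimum cells per (sample, type) pair (default 5).
#' @param min_sample_frac minimum fraction of retained samples in which a
#'   gene must be detected (pseudo-bulk count > 0; default 0.05).
#' @param merge_map optional named character vector mapping fine labels
#'   to merged labels (e.g. collapsing CD4 sub-populations) applied
#'   before aggregation.
#' @return a `PseudobulkSet`: per type a list with `counts`
#'   (samples x genes), `cell_counts`, `size_factors`; plus `samples`
#'   (per-sample metadata) and `excluded` (pairs under `min_cells`).
#' @export
make_pseudobulk <- function(cm, labels, min_cells = 5L,
                            min_sample_frac = 0.05, merge_map = NULL) {
  stopifnot(inherits(cm, "CellMatrix"), length(labels) == ncol(cm$counts))
  if (!is.null(merge_map)) {
    hit <- labels %in% names(merge_map)
    labels[hit] <- merge_map[labels[hit]]
  }
  ok <- !is.na(labels) & labels != "ambiguous"
  samp <- cm$cells$sample
  meta_cols <- intersect(c("disease", "sex", "batch", "gada", "hla_risk"),
                         names(cm$cells))
  smeta <- unique(cm$cells[, c("sample", meta_cols), drop = FALSE])
  rownames(smeta) <- smeta$sample
  types <- sort(unique(labels[ok]))
  res <- list()
  excluded <- list()
  for (ty in types) {
    sel <- which(ok & labels == ty)
    ncell <- table(samp[sel])
    keep_s <- names(ncell)[ncell >= min_cells]
    excl <- names(ncell)[ncell < min_cells]
    if (length(excl))
      excluded[[ty]] <- data.frame(type = ty, sample = excl,
                                   n_cells = as.integer(ncell[excl]))
    if ("disease" %in% meta_cols) {
      grp <- smeta[keep_s, "disease"]
      if (length(keep_s) < 6 || min(table(factor(grp, levels = c(0, 1)))) < 3) {
        warning("cell type '", ty, "' skipped: fewer than 3 retained ",
                "samples per group")
        next
      }
    }
    sel <- sel[samp[sel] %in% keep_s]
    fs <- factor(samp[sel], levels = keep_s)
    agg <- Matrix::fac2sparse(fs) %*% Matrix::t(cm$counts[, sel, drop = FALSE])
    M <- as.matrix(agg)                     # samples x genes
    rownames(M) <- keep_s
    n_min <- ceiling(min_sample_frac * nrow(M))
    gkeep <- colSums(M > 0) >= n_min
    M <- M[, gkeep, drop = FALSE]
    res[[ty]] <- list(counts = M,
                      cell_counts = stats::setNames(as.integer(ncell[keep_s]), keep_s),
                      size_factors = size_factors_mor(M))
  }
  structure(list(types = res, samples = smeta,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                            else NULL,
                 min_cells = min_cells),
            class = "PseudobulkSet")
}

#' @exportS3Method base::print
print.PseudobulkSet <- function(x, ...) {
  cat(sprintf("PseudobulkSet: %d cell types, %d samples\n",
              length(x$types), nrow(x$samples)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per sample, the median ratio of its counts to the per-gene geometric
#' mean reference; genes whose reference is zero (any zero count) are
#' skipped.
#'
#' @param counts samples x genes matrix of nonnegative integers.
#' @return numeric size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  lg <- log(counts)
  use <- apply(is.finite(lg), 2, all)
  if (!any(use)) return(stats::setNames(rep(1, nrow(counts)), rownames(counts)))
  ref <- colMeans(lg[, use, drop = FALSE])  # log geometric means
  sf <- apply(lg[, use, drop = FALSE], 1, function(r) exp(stats::median(r - ref)))
  stats::setNames(sf, rownames(counts))
}

#' Log2-CPM normalization of a pseudo-bulk matrix
#'
#' @param counts samples x genes matrix.
#' @param prior pseudo-count added before the log (default 1).
#' @return samples x genes log2 counts-per-million matrix.
#' @export
pb_log2cpm <- function(counts, prior = 1) {
  lib <- rowSums(counts)
  log2(sweep(counts, 1, pmax(lib, 1), "/") * 1e6 + prior)
}

# NB log-link IRLS for a fixed dispersion phi; var = mu + phi mu^2.
# Returns coefficients on the natural-log scale, their SEs, convergence.
nb_irls <- function(y, X, offset = rep(0, length(y)), phi = 0,
                    max_iter = 50L, tol = 1e-8) {
  mu0 <- pmax(mean(y / exp(offset)), 1e-8)
  beta <- c(log(mu0), rep(0, ncol(X) - 1))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmax(pmin(drop(X %*% beta) + offset, 30), -30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) { conv <- TRUE; break }
  }
  eta <- pmax(pmin(drop(X %*% beta) + offset, 30), -30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e)
    rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, converged = conv, iter = it)
}

# Method-of-moments dispersion per gene, pooled within condition groups,
# then shrunk 50/50 (log scale) toward a fitted a0 + a1/mean trend.
estimate_dispersions <- function(counts, sf, condition) {
  q <- sweep(counts, 1, sf, "/")            # normalized counts
  grp <- factor(condition)
  n <- nrow(q); ng <- nlevels(grp)
  mu_bar <- colMeans(q)
  within_var <- rep(0, ncol(q))
  for (g in levels(grp)) {
    i <- grp == g
    m <- colMeans(q[i, , drop = FALSE])
    within_var <- within_var +
      colSums(sweep(q[i, , drop = FALSE], 2, m, "-")^2)
  }
  within_var <- within_var / (n - ng)
  pois_part <- mu_bar * mean(1 / sf)
  phi_hat <- pmax((within_var - pois_part) / pmax(mu_bar^2, 1e-12), 1e-8)
  # trend fit phi = a0 + a1 / mu on informative genes
  use <- mu_bar > 0.5 & phi_hat > 1e-8
  # no overdispersed gene at all (e.g. exactly proportional toy data):
  # stay in the Poisson limit
  if (!any(use, na.rm = TRUE))
    return(rep(1e-8, ncol(counts)))
  a0 <- stats::median(phi_hat[use], na.rm = TRUE)
  a1 <- 0
  if (sum(use) >= 10) {
    df <- data.frame(y = phi_hat[use], x = 1 / mu_bar[use])
    fit <- tryCatch(suppressWarnings(
      stats::glm(y ~ x, data = df,
                 family = stats::Gamma(link = "identity"),
                 start = c(max(a0, 1e-4), 1e-4))),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      a0 <- max(stats::coef(fit)[1], 1e-6)
      a1 <- max(stats::coef(fit)[2], 0)
    }
  }
  phi_tr <- pmax(a0 + a1 / pmax(mu_bar, 1e-8), 1e-8)
  phi <- exp(0.5 * log(phi_hat) + 0.5 * log(phi_tr))
  pmin(pmax(phi, 1e-8), 20)
}

#' Negative-binomial Wald differential expression on pseudo-bulk
#'
#' A minimal NB-Wald pipeline: median-of-ratios size factors, per-gene
#' method-of-moments dispersion shrunk 50/50 toward an `a0 + a1/mean`
#' trend, NB GLM (log link, intercept + condition) by IRLS, Wald test on
#' the condition coefficient, BH correction across genes. Optionally a
#' normal-prior shrunken log2 fold-change is added (prior variance
#' estimated from the observed LFC distribution).
#'
#' @param counts samples x genes pseudo-bulk matrix for one cell type.
#' @param condition per-sample 0/1 (control/case) vector.
#' @param size_factors optional; computed by [size_factors_mor()] when
#'   missing.
#' @param shrink_lfc also report `lfc_shrunk`.
#' @return data.frame per gene: `gene`, `base_mean`, `lfc` (log2, case vs
#'   control), `se`, `stat`, `p`, `q`, `converged` (+ `lfc_shrunk`).
#' @export
nb_de_test <- function(counts, condition, size_factors = NULL,
                       shrink_lfc = FALSE) {
  condition <- as.numeric(condition)
  stopifnot(nrow(counts) == length(condition))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (min(table(condition)) < 3)
    stop("need at least 3 samples per group")
  sf <- if (is.null(size_factors)) size_factors_mor(counts) else size_factors
  phi <- estimate_dispersions(counts, sf, condition)
  X <- cbind(intercept = 1, condition = condition)
  off <- log(sf)
  G <- ncol(counts)
  lfc <- se <- stat <- p <- rep(NA_real_, G)
  conv <- logical(G)
  for (g in seq_len(G)) {
    y <- counts[, g]
    if (all(y == 0)) next
    f <- nb_irls(y, X, offset = off, phi = phi[g])
    if (!f$converged || anyNA(f$se)) { conv[g] <- FALSE; next }
    conv[g] <- TRUE
    lfc[g] <- f$beta[2] / log(2)
    se[g] <- f$se[2] / log(2)
    stat[g] <- f$beta[2] / f$se[2]
    p[g] <- 2 * stats::pnorm(-abs(stat[g]))
  }
  q <- rep(NA_real_, G)
  q[conv] <- stats::p.adjust(p[conv], method = "BH")
  out <- data.frame(gene = colnames(counts),
                    base_mean = colMeans(sweep(counts, 1, sf, "/")),
                    lfc = lfc, se = se, stat = stat, p = p, q = q,
                    converged = conv, row.names = NULL)
  if (shrink_lfc) {
    okg <- conv & is.finite(lfc) & is.finite(se)
    tau2 <- max(mean(lfc[okg]^2) - mean(se[okg]^2), 1e-4)
    out$lfc_shrunk <- ifelse(okg, lfc * tau2 / (tau2 + se^2), NA_real_)
  }
  out
}

#' Differential expression over all cell types of a PseudobulkSet
#'
#' Runs [nb_de_test()] per cell type against the `disease` column of the
#' sample metadata.
#'
#' @param pb PseudobulkSet.
#' @param shrink_lfc passed through.
#' @return data.frame of per-(gene, cell type) test rows with a
#'   `cell_type` column.
#' @export
de_all_types <- function(pb, shrink_lfc = FALSE) {
  stopifnot(inherits(pb, "PseudobulkSet"))
  if (!"disease" %in% names(pb$samples))
    stop("sample metadata lacks a 'disease' column")
  out <- lapply(names(pb$types), function(ty) {
    el <- pb$types[[ty]]
    cond <- pb$samples[rownames(el$counts), "disease"]
    dt <- nb_de_test(el$counts, cond, size_factors = el$size_factors,
                     shrink_lfc = shrink_lfc)
    dt$cell_type <- ty
    dt
  })
  do.call(rbind, out)
}

#' Call DEGs and compute differential expression scores
#'
#' Up = `lfc >= lfc_min & q <= q_max`; down = `lfc <= -lfc_min & q <=
#' q_max` (boundaries inclusive). The differential expression score
#' `DES = |log2FC| * -log10(q)` is computed for every converged gene.
#' Two q-value conventions are in circulation for this DEG definition
#' (0.1 and 0.05); the default is 0.1 and a message records the choice.
#'
#' @param dt data.frame from [nb_de_test()]/[de_all_types()] (columns
#'   `gene`, `lfc`, `q`, optionally `cell_type`).
#' @param lfc_min minimum |log2FC| (default `log2(1.3)`).
#' @param q_max FDR threshold (default 0.1).
#' @param quiet suppress the convention message.
#' @return a `DegTable`: the input with `des`, `direction` columns and
#'   attribute `deg_sets`, a per-cell-type list of `up`/`down` gene sets.
#' @export
call_degs <- function(dt, lfc_min = log2(1.3), q_max = 0.1, quiet = FALSE) {
  if (!quiet && !isTRUE(all.equal(q_max, 0.05)) && q_max == 0.1)
    message("DEG call uses q <= 0.1; the stricter q <= 0.05 convention ",
            "is available via q_max")
  if (!"cell_type" %in% names(dt)) dt$cell_type <- "all"
  qfl <- pmax(dt$q, 1e-300)
  dt$des <- ifelse(is.finite(dt$lfc) & is.finite(dt$q),
                   abs(dt$lfc) * -log10(qfl), NA_real_)
  dt$direction <- ifelse(!is.finite(dt$lfc) | !is.finite(dt$q), NA_character_,
                  ifelse(dt$lfc >= lfc_min & dt$q <= q_max, "up",
                  ifelse(dt$lfc <= -lfc_min & dt$q <= q_max, "down", "none")))
  sets <- lapply(split(dt, dt$cell_type), function(d)
    list(up = d$gene[!is.na(d$direction) & d$direction == "up"],
         down = d$gene[!is.na(d$direction) & d$direction == "down"]))
  structure(dt, deg_sets = sets, lfc_min = lfc_min, q_max = q_max,
            class = c("DegTable", "data.frame"))
}

#' Per-cell-type marker genes
#'
#' For each cell type versus all other cells: genes detected (count > 0)
#' in at least `min_pct` of either group are tested with a cell-level NB
#' GLM (log link, type indicator plus nuisance covariates such as batch
#' and disease status, offset = log depth); markers are genes with
#' average natural-log fold-change above `lfc_min_nlog` and BH q below
#' `q_max`.
#'
#' @param cm CellMatrix.
#' @param labels per-cell type labels.
#' @param covariates character vector of cell-metadata columns to regress
#'   out (default `c("batch", "disease")`, intersected with available).
#' @param min_pct detection filter (default 0.25).
#' @param lfc_min_nlog minimum mean nlog fold-change (default 0.25).
#' @param q_max FDR threshold (default 0.05).
#' @param types cell types to test (default all).
#' @return data.frame: `cell_type`, `gene`, `nlog_fc`, `pct_in`,
#'   `pct_out`, `p`, `q`, `marker`.
#' @export
marker_genes <- function(cm, labels, covariates = c("batch", "disease"),
                         min_pct = 0.25, lfc_min_nlog = 0.25, q_max = 0.05,
                         types = NULL) {
  stopifnot(inherits(cm, "CellMatrix"))
  ok <- !is.na(labels) & labels != "ambiguous"
  if (length(unique(labels[ok])) < 2)
    stop("need at least two cell types")
  counts <- cm$counts[, ok, drop = FALSE]
  labels <- labels[ok]
  meta <- cm$cells[ok, , drop = FALSE]
  covariates <- intersect(covariates, names(meta))
  depth <- Matrix::colSums(counts)
  nl <- normalize_cells(CellMatrix(counts, meta))
  if (is.null(types)) types <- sort(unique(labels))
  base_X <- if (length(covariates))
    stats::model.matrix(~ ., data = meta[, covariates, drop = FALSE])
  else matrix(1, ncol(counts), 1)
  res <- list()
  for (ty in types) {
    ind <- as.numeric(labels == ty)
    if (sum(ind) < 2 || sum(!ind) < 2) next
    det_in <- Matrix::rowMeans(counts[, ind == 1, drop = FALSE] > 0)
    det_out <- Matrix::rowMeans(counts[, ind == 0, drop = FALSE] > 0)
    test_g <- which(pmax(det_in, det_out) >= min_pct)
    if (!length(test_g)) next
    nfc <- Matrix::rowMeans(nl[test_g, ind == 1, drop = FALSE]) -
      Matrix::rowMeans(nl[test_g, ind == 0, drop = FALSE])
    X <- cbind(base_X, type = ind)
    off <- log(pmax(depth, 1))
    p <- rep(NA_real_, length(test_g))
    for (j in seq_along(test_g)) {
      y <- counts[test_g[j], ]
      mu_off <- y / exp(off)
      m <- mean(mu_off); v <- stats::var(mu_off)
      phi <- max((v - m * mean(1 / exp(off))) / max(m^2, 1e-12), 1e-8)
      f <- nb_irls(as.numeric(y), X, offset = off, phi = phi)
      k <- ncol(X)
      if (f$converged && !anyNA(f$se))
        p[j] <- 2 * stats::pnorm(-abs(f$beta[k] / f$se[k]))
    }
    q <- stats::p.adjust(p, method = "BH")
    res[[ty]] <- data.frame(cell_type = ty,
                            gene = rownames(counts)[test_g],
                            nlog_fc = nfc, pct_in = det_in[test_g],
                            pct_out = det_out[test_g], p = p, q = q,
                            marker = !is.na(q) & nfc > lfc_min_nlog & q < q_max,
                            row.names = NULL)
  }
  do.call(rbind, res)
}
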