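#' Per-sample, per-cell-type metagene z-score (TMZ)
#'
#' For each cell type i, pseudo-bulk expression is normalized to
#' log2-CPM, each DEG is z-transformed across samples, and
#' `TMZ_i = mean(z over up-DEGs) - mean(z over down-DEGs)`. Samples whose
#' (sample, cell type) pseudo-bulk was excluded for insufficient cells
#' are missing for that cell type. The average TMZ of a sample is the
#' mean over its non-missing cell types.
#'
#' @param pb PseudobulkSet from [make_pseudobulk()].
#' @param deg_sets per-cell-type list of `up`/`down` gene-identifier
#'   sets, e.g. `attr(call_degs(...), "deg_sets")`.
#' @return a `TmzMatrix`: samples x cell types matrix with attributes
#'   `average` (per-sample mean over non-missing types), `missing`
#'   (logical mask), `dropped_genes` (zero-variance genes removed).
#' @export
compute_tmz <- function(pb, deg_sets) {
  stopifnot(inherits(pb, "PseudobulkSet"))
  types <- intersect(names(pb$types), names(deg_sets))
  if (!length(types)) stop("no cell types shared between pseudo-bulk and DEG sets")
  samples <- pb$samples$sample
  if (length(samples) < 3) stop("need at least 3 samples")
  M <- matrix(NA_real_, length(samples), length(types),
              dimnames = list(samples, types))
  dropped <- list()
  for (ty in types) {
    sets <- deg_sets[[ty]]
    if (!length(sets$up) && !length(sets$down)) {
      warning("cell type '", ty, "' has empty DEG sets; skipped")
      next
    }
    expr <- pb_log2cpm(pb$types[[ty]]$counts)
    keep <- intersect(c(sets$up, sets$down), colnames(expr))
    sd <- apply(expr[, keep, drop = FALSE], 2, stats::sd)
    flat <- c(setdiff(c(sets$up, sets$down), colnames(expr)),
              keep[sd == 0])
    if (length(flat)) {
      dropped[[ty]] <- flat
      warning("cell type '", ty, "': ", length(flat),
              " zero-variance/absent DEG(s) dropped")
    }
    Z <- scale(expr[, keep[sd > 0], drop = FALSE])
    M[rownames(expr), ty] <- tmz_from_z(Z, sets$up, sets$down)
  }
  avg <- rowMeans(M, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  structure(M, average = avg, missing = is.na(M),
            dropped_genes = dropped, class = c("TmzMatrix", class(M)))
}

#' Combine gene z-scores into a metagene score
#'
#' The metagene equation itself: per sample (row of `z`), the mean
#' z-score over up genes minus the mean z-score over down genes,
#' `sum(z_up)/|U| - sum(z_down)/|D|`. Genes absent from `z` are ignored;
#' an empty side contributes 0.
#'
#' @param z samples x genes matrix of expression z-scores.
#' @param up,down gene-identifier vectors.
#' @return numeric score per sample.
#' @export
tmz_from_z <- function(z, up, down) {
  part <- function(g) {
    g <- intersect(g, colnames(z))
    if (!length(g)) return(rep(0, nrow(z)))
    rowMeans(z[, g, drop = FALSE])
  }
  part(up) - part(down)
}

#' Cluster samples into molecular subtypes by their TMZ profiles
#'
#' Missing entries are imputed with the sample's own mean over
#' non-missing cell types (preserving its observed global activation
#' level), then k-means with restarts; clusters are ordered by mean
#' average-TMZ and named low / intermediate / high.
#'
#' @param tm TmzMatrix from [compute_tmz()].
#' @param k number of subtypes (default 3).
#' @param restarts k-means restarts (default 25).
#' @param seed integer seed.
#' @return factor of subtype labels per sample (levels low <
#'   intermediate < high for k = 3, otherwise `tier1 < ... < tierk`);
#'   all-missing samples are NA and reported via attribute `excluded`.
#' @export
subtype_samples <- function(tm, k = 3L, restarts = 25L, seed = 1L) {
  X <- unclass(tm)
  row_mean <- rowMeans(X, na.rm = TRUE)
  excluded <- rownames(X)[!is.finite(row_mean)]
  ok <- is.finite(row_mean)
  Xi <- X[ok, , drop = FALSE]
  for (j in seq_len(ncol(Xi)))
    Xi[is.na(Xi[, j]), j] <- row_mean[ok][is.na(Xi[, j])]
  if (nrow(Xi) < k) stop("need at least k samples with a score")
  if (all(apply(Xi, 2, stats::sd) == 0)) {
    warning("all samples identical; single degenerate cluster returned")
    lab <- factor(rep("low", nrow(Xi)), levels = c("low", "intermediate", "high"))
    out <- factor(rep(NA, nrow(X)), levels = levels(lab))
    out[ok] <- lab
    names(out) <- rownames(X)
    attr(out, "excluded") <- excluded
    return(out)
  }
  set.seed(seed)
  km <- stats::kmeans(Xi, centers = k, nstart = restarts, iter.max = 100)
  lev <- if (k == 3) c("low", "intermediate", "high")
         else paste0("tier", seq_len(k))
  ord <- order(tapply(rowMeans(Xi), km$cluster, mean))
  lab <- lev[match(km$cluster, ord)]
  out <- factor(rep(NA_character_, nrow(X)), levels = lev)
  out[ok] <- factor(lab, levels = lev)
  names(out) <- rownames(X)
  attr(out, "excluded") <- excluded
  out
}

#' Associate TMZ scores with clinical covariates
#'
#' Per cell type (and the per-sample average): OLS of the TMZ score on
#' the covariates with per-coefficient partial F-test p-values; Spearman
#' rank correlation of TMZ against the `gada` covariate; Kruskal-Wallis
#' of TMZ across `hla_risk` categories. Constant covariates are dropped
#' with a warning; a single HLA category yields a missing Kruskal-Wallis
#' entry.
#'
#' @param tm TmzMatrix.
#' @param covariates per-sample data.frame (rownames or `sample` column
#'   matching the TMZ rows) with e.g. `sex`, `gada`, `hla_risk`,
#'   optionally `age`.
#' @param samples optional subset of samples (e.g. cases only).
#' @return list: `regression` (long data.frame), `spearman`
#'   (per-cell-type rho and p vs GADA), `kruskal` (per-cell-type H and p
#'   across HLA categories).
#' @export
tmz_association <- function(tm, covariates, samples = NULL) {
  X <- unclass(tm)
  key <- if ("sample" %in% names(covariates)) covariates$sample
         else rownames(covariates)
  cov <- covariates[match(rownames(X), key), , drop = FALSE]
  cov$sample <- NULL
  rownames(cov) <- rownames(X)
  if (!is.null(samples)) {
    X <- X[rownames(X) %in% samples, , drop = FALSE]
    cov <- cov[rownames(X), , drop = FALSE]
  }
  const <- vapply(cov, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(names(cov)[const], collapse = ", "))
    cov <- cov[, !const, drop = FALSE]
  }
  scores <- cbind(X, average = rowMeans(X, na.rm = TRUE))
  reg <- lapply(colnames(scores), function(ty) {
    y <- scores[, ty]
    okr <- is.finite(y) & stats::complete.cases(cov)
    if (sum(okr) < ncol(cov) + 2) return(NULL)
    fit <- stats::lm(y[okr] ~ ., data = cov[okr, , drop = FALSE])
    sm <- summary(fit)$coefficients
    data.frame(score = ty, term = rownames(sm), estimate = sm[, 1],
               se = sm[, 2], F = sm[, 3]^2, p = sm[, 4], row.names = NULL)
  })
  regression <- do.call(rbind, reg)
  spearman <- kruskal <- NULL
  if ("gada" %in% names(cov)) {
    spearman <- do.call(rbind, lapply(colnames(scores), function(ty) {
      y <- scores[, ty]; g <- as.numeric(cov$gada)
      okr <- is.finite(y) & is.finite(g)
      if (sum(okr) < 3) return(NULL)
      ct <- suppressWarnings(stats::cor.test(y[okr], g[okr], method = "spearman"))
      data.frame(score = ty, rho = unname(ct$estimate), p = ct$p.value)
    }))
  }
  if ("hla_risk" %in% names(cov)) {
    kruskal <- do.call(rbind, lapply(colnames(scores), function(ty) {
      y <- scores[, ty]; h <- factor(cov$hla_risk)
      okr <- is.finite(y) & !is.na(h)
      if (length(unique(h[okr])) < 2)
        return(data.frame(score = ty, H = NA_real_, p = NA_real_))
      kt <- stats::kruskal.test(y[okr], droplevels(h[okr]))
      data.frame(score = ty, H = unname(kt$statistic), p = kt$p.value)
    }))
  }
  list(regression = regression, spearman = spearman, kruskal = kruskal)
}

#' Collapse per-cell-type DEG sets into compartment sets
#'
#' Unions the up (and down) DEG sets of cell types belonging to each
#' compartment (canonically T/NK, B, monocyte). Genes landing in both
#' the up and the down set of a compartment are dropped from both (sign
#' ambiguity).
#'
#' @param deg_sets per-cell-type `up`/`down` list.
#' @param compartment_of named character vector: cell type -> compartment.
#' @return per-compartment `up`/`down` list (`CompartmentDegSets`);
#'   empty compartments are flagged with a warning.
#' @export
compartment_deg_sets <- function(deg_sets, compartment_of) {
  comps <- unique(compartment_of[names(deg_sets)])
  comps <- comps[!is.na(comps)]
  out <- lapply(comps, function(cp) {
    members <- names(compartment_of)[compartment_of == cp]
    members <- intersect(members, names(deg_sets))
    up <- unique(unlist(lapply(deg_sets[members], `[[`, "up")))
    dn <- unique(unlist(lapply(deg_sets[members], `[[`, "down")))
    both <- intersect(up, dn)
    list(up = setdiff(up, both), down = setdiff(dn, both))
  })
  names(out) <- comps
  empty <- vapply(out, function(s) !length(s$up) && !length(s$down), logical(1))
  if (any(empty))
    warning("empty compartment DEG set(s): ",
            paste(names(out)[empty], collapse = ", "))
  structure(out, class = "CompartmentDegSets")
}

#' Project bulk RNA-seq expression onto the TMZ reference distribution
#'
#' Computes compartment metagene scores on bulk expression and maps them
#' onto the reference (single-cell derived) TMZ distribution by a
#' rank-preserving empirical-quantile transform: the bulk score at
#' empirical quantile q maps to the q-th quantile of the reference
#' scores (linear interpolation between order statistics). With fewer
#' than 3 bulk samples, gene z-scores are anchored to supplied reference
#' gene means/sds so that a single sample can be scored. A paired
#' pre/post design can be tested downstream with a paired t-test.
#'
#' @param bulk_expr genes x samples numeric matrix (any monotone
#'   expression scale; log2 recommended).
#' @param cds [compartment_deg_sets()] output.
#' @param reference per-compartment numeric vectors of reference TMZ
#'   scores (the target distributions), named like `cds`.
#' @param ref_gene_stats optional list per compartment with `mean`/`sd`
#'   named numeric vectors per gene, used when `ncol(bulk_expr) < 3`.
#' @param min_genes minimum overlapping genes per compartment
#'   (default 10).
#' @return list per compartment: `raw` (bulk metagene score) and
#'   `projected` (quantile-mapped onto the reference distribution);
#'   compartments with insufficient overlap are skipped with a warning.
#' @export
project_bulk_tmz <- function(bulk_expr, cds, reference,
                             ref_gene_stats = NULL, min_genes = 10L) {
  stopifnot(inherits(cds, "CompartmentDegSets"))
  out <- list()
  for (cp in names(cds)) {
    genes <- c(cds[[cp]]$up, cds[[cp]]$down)
    shared <- intersect(genes, rownames(bulk_expr))
    if (length(shared) < min_genes) {
      warning("compartment '", cp, "' skipped: fewer than ", min_genes,
              " overlapping genes")
      next
    }
    E <- t(bulk_expr[shared, , drop = FALSE])   # samples x genes
    if (nrow(E) >= 3) {
      sd <- apply(E, 2, stats::sd)
      Ez <- scale(E[, sd > 0, drop = FALSE])
    } else {
      if (is.null(ref_gene_stats) || is.null(ref_gene_stats[[cp]]))
        stop("fewer than 3 bulk samples: reference gene statistics required")
      st <- ref_gene_stats[[cp]]
      g <- intersect(colnames(E), names(st$mean))
      Ez <- sweep(sweep(E[, g, drop = FALSE], 2, st$mean[g], "-"),
                  2, pmax(st$sd[g], 1e-8), "/")
    }
    up <- intersect(cds[[cp]]$up, colnames(Ez))
    dn <- intersect(cds[[cp]]$down, colnames(Ez))
    part <- function(g) if (length(g)) rowMeans(Ez[, g, drop = FALSE]) else 0
    raw <- part(up) - part(dn)
    ref <- stats::na.omit(reference[[cp]])
    if (!length(ref)) stop("reference distribution for '", cp, "' is empty")
    # empirical quantile of each bulk score, then the reference quantile
    n <- length(raw)
    qq <- if (n > 1) (rank(raw, ties.method = "average") - 1) / (n - 1)
          else 0.5
    projected <- stats::quantile(ref, probs = qq, type = 7, names = FALSE)
    out[[cp]] <- list(raw = raw,
                      projected = stats::setNames(projected, names(raw)))
  }
  out
}

#' Per-compartment reference gene statistics from pseudo-bulk
#'
#' Mean and sd of log2-CPM expression per gene across samples, per
#' compartment, for anchoring single-sample bulk projection.
#'
#' @param pb PseudobulkSet.
#' @param compartment_of named character vector: cell type -> compartment.
#' @return list per compartment with `mean` and `sd` named vectors.
#' @export
reference_gene_stats <- function(pb, compartment_of) {
  comps <- unique(compartment_of)
  out <- list()
  for (cp in comps) {
    members <- intersect(names(compartment_of)[compartment_of == cp],
                         names(pb$types))
    if (!length(members)) next
    # average the per-type log2-CPM matrices over shared samples
    mats <- lapply(members, function(ty) pb_log2cpm(pb$types[[ty]]$counts))
    genes <- unique(unlist(lapply(mats, colnames)))
    acc_m <- acc_s <- stats::setNames(rep(0, length(genes)), genes)
    cnt <- stats::setNames(rep(0L, length(genes)), genes)
    for (m in mats) {
      mu <- colMeans(m); sd <- apply(m, 2, stats::sd)
      acc_m[colnames(m)] <- acc_m[colnames(m)] + mu
      acc_s[colnames(m)] <- acc_s[colnames(m)] + sd
      cnt[colnames(m)] <- cnt[colnames(m)] + 1L
    }
    out[[cp]] <- list(mean = acc_m / pmax(cnt, 1L), sd = acc_s / pmax(cnt, 1L))
  }
  out
}
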