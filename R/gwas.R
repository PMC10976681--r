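#' Gene-level risk score table
#'
#' Validates an externally computed gene-level GWAS score table
#' (score = -log10 of a gene-level association p-value).
#'
#' @param df data.frame with `gene`, `score`, `chrom`, `pos`.
#' @return the validated data.frame (class `GeneRiskTable`).
#' @export
gene_risk_table <- function(df) {
  need <- c("gene", "score", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("risk table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("risk table genes must be unique")
  if (any(df$score < 0)) stop("risk scores must be nonnegative")
  if (any(df$pos <= 0)) stop("positions must be positive")
  structure(df, class = c("GeneRiskTable", "data.frame"))
}

#' Filter and min-max normalize differential expression scores
#'
#' Per cell type, retains genes with `q < q_keep` and min-max normalizes
#' their DES to `[0, 1]`. (The source protocol's wording on the
#' direction of the q filter is self-contradictory; retaining the
#' significant genes is the implemented interpretation.) Cell types with
#' fewer than 2 retained genes are skipped; a degenerate all-equal DES
#' vector normalizes to all zeros with a warning.
#'
#' @param dt DegTable (or data.frame with `gene`, `cell_type`, `q`,
#'   `des`).
#' @param q_keep retention threshold (default 0.1, strict `<`).
#' @return named list per cell type: data.frame `gene`, `des`,
#'   `norm_des`.
#' @export
prepare_des <- function(dt, q_keep = 0.1) {
  stopifnot(all(c("gene", "cell_type", "q", "des") %in% names(dt)))
  out <- list()
  for (ty in unique(dt$cell_type)) {
    d <- dt[dt$cell_type == ty & !is.na(dt$q) & dt$q < q_keep &
              is.finite(dt$des), c("gene", "des")]
    if (nrow(d) < 2) next
    rng <- range(d$des)
    if (rng[1] == rng[2]) {
      warning("cell type '", ty, "': all DES equal; normalized to 0")
      d$norm_des <- 0
    } else {
      d$norm_des <- (d$des - rng[1]) / (rng[2] - rng[1])
    }
    rownames(d) <- NULL
    out[[ty]] <- d
  }
  out
}

#' Parse a genomic region string
#'
#' @param region string like `"chr6:25000000-35000000"`.
#' @return list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must look like 'chr6:25000000-35000000'")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Gene-level covariate enrichment of DEG programs for genetic risk
#'
#' Per cell type: one-sided linear regression of the gene risk score on
#' the normalized DES over the shared gene set (testing for a positive
#' coefficient), optionally excluding genes inside a region (canonically
#' the HLA locus, chr6:25-35 Mb); BH across cell types. Run it twice —
#' genome-wide and with the region excluded — to separate HLA-driven
#' from polygenic enrichment.
#'
#' @param norm_des output of [prepare_des()].
#' @param risk a [gene_risk_table()].
#' @param exclude_region optional region string or
#'   `list(chrom, start, end)`.
#' @param min_genes minimum shared genes per cell type (default 50).
#' @return data.frame per cell type: `cell_type`, `n_genes`, `beta`,
#'   `se`, `t`, `p` (one-sided), `q`.
#' @export
heritability_covariate_test <- function(norm_des, risk, exclude_region = NULL,
                                        min_genes = 50L) {
  risk <- gene_risk_table(as.data.frame(risk))
  if (!is.null(exclude_region)) {
    if (is.character(exclude_region)) exclude_region <- parse_region(exclude_region)
    drop <- risk$chrom == exclude_region$chrom &
      risk$pos >= exclude_region$start & risk$pos <= exclude_region$end
    risk <- risk[!drop, , drop = FALSE]
  }
  rows <- lapply(names(norm_des), function(ty) {
    d <- norm_des[[ty]]
    i <- match(d$gene, risk$gene)
    okg <- !is.na(i)
    if (sum(okg) == 0) stop("empty intersection of DES and risk genes for '",
                            ty, "'")
    if (sum(okg) < min_genes) return(NULL)
    x <- d$norm_des[okg]
    y <- risk$score[i[okg]]
    if (stats::var(x) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    tv <- sm["x", 3]
    data.frame(cell_type = ty, n_genes = sum(okg), beta = sm["x", 1],
               se = sm["x", 2], t = tv,
               p = stats::pt(tv, df = fit$df.residual, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cell type had enough shared genes")
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Select effector genes
#'
#' Effector genes of a cell type are the intersection of the `top_n`
#' genes by genetic risk score with the genes at or above the
#' `des_percentile`-th percentile of that cell type's normalized DES
#' ("upper 30 percent" = 70th percentile and above). Monotone in both
#' knobs: growing `top_n` or lowering `des_percentile` never removes an
#' effector.
#'
#' @param norm_des output of [prepare_des()].
#' @param risk a [gene_risk_table()].
#' @param top_n number of top-risk genes (default 200).
#' @param des_percentile percentile threshold on normalized DES
#'   (default 70).
#' @return named list per cell type of effector gene vectors.
#' @export
select_effector_genes <- function(norm_des, risk, top_n = 200L,
                                  des_percentile = 70) {
  risk <- gene_risk_table(as.data.frame(risk))
  top <- if (top_n > 0)
    risk$gene[order(-risk$score)][seq_len(min(top_n, nrow(risk)))]
  else character()
  lapply(norm_des, function(d) {
    thr <- stats::quantile(d$norm_des, probs = des_percentile / 100,
                           type = 7, names = FALSE)
    high <- d$gene[d$norm_des >= thr]
    intersect(top, high)
  })
}
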