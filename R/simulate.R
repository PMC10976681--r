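#' Configure a synthetic case/control PBMC cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults describe the cohort the downstream analysis assumes: a
#' case/control PBMC study with 13 annotated immune cell types, per-sample
#' shared immune-activation strength in cases, planted per-cell-type
#' up/down differentially expressed (DE) gene programs, composition
#' shifts, sex-linked marker genes, doublets and mitochondrial content.
#'
#' Counts are negative binomial with `var = mu + phi * mu^2`. Case samples
#' carry a log-normal activation scalar `alpha_s` with mean 1 (controls:
#' `alpha_s = 0`) that scales every planted log2 fold-change in that
#' sample, producing the shared-program structure in which the per-cell-type
#' metagene scores of one sample move together.
#'
#' @param n_case,n_control number of case / control samples.
#' @param cells_per_sample cells drawn per sample.
#' @param cell_types named numeric vector of base abundance fractions
#'   (must sum to 1).
#' @param genes size of the gene universe (includes 10 mitochondrial,
#'   5 Y-linked and 5 X-linked reserved genes).
#' @param n_feature_genes_per_type marker genes elevated per cell type.
#' @param de_spec list with `n_up`, `n_down`, `mean_lfc`: sizes of the
#'   planted up/down DE sets per cell type and the mean absolute log2
#'   fold-change. May also be a per-type named list of such lists.
#' @param activation_sd log-scale sd of the case activation scalar.
#' @param activation_tiers optional numeric vector of discrete activation
#'   levels; when given, case samples are split evenly across the tiers
#'   (recorded in the truth) instead of drawing log-normal `alpha_s`.
#' @param composition_shift named numeric, additive case-vs-control shift
#'   on log abundance (log-odds scale) per cell type; 0 = no shift.
#' @param doublet_rate fraction of cells simulated as doublets, in `[0,1)`.
#' @param mito_mean,mito_sd mean/sd of the per-cell mitochondrial fraction.
#' @param dispersion per-gene NB dispersion `phi` (> 0); scalar recycled.
#' @param depth_mean expected UMI per cell.
#' @param depth_sdlog log-scale sd of the per-cell depth factor.
#' @param dirichlet_conc concentration of the per-sample Dirichlet draw
#'   around the (shifted) base composition.
#' @param seed integer seed; every generator draw derives from it.
#' @return a `SimConfig` list, validated.
#' @export
sim_config <- function(n_case = 46L, n_control = 31L,
                       cells_per_sample = 400L,
                       cell_types = default_cell_types(),
                       genes = 2000L,
                       n_feature_genes_per_type = 30L,
                       de_spec = list(n_up = 40L, n_down = 40L, mean_lfc = 1.0),
                       activation_sd = 0.4,
                       activation_tiers = NULL,
                       composition_shift = NULL,
                       doublet_rate = 0.05,
                       mito_mean = 0.03, mito_sd = 0.015,
                       dispersion = 0.3,
                       depth_mean = 1500,
                       depth_sdlog = 0.3,
                       dirichlet_conc = 150,
                       seed = 1L) {
  if (is.null(composition_shift))
    composition_shift <- stats::setNames(rep(0, length(cell_types)),
                                         names(cell_types))
  cfg <- structure(as.list(environment()), class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

#' Default 13-type PBMC composition
#'
#' Base abundance fractions for the 13 immune cell types carried through
#' the whole pipeline (T, NK, B and monocyte sub-populations).
#' @return named numeric vector summing to 1.
#' @export
default_cell_types <- function() {
  c(CD4_naive = 0.18, CD4_CM = 0.10, CD4_EM = 0.06,
    CD8_naive = 0.08, CD8_CM = 0.05, CD8_EM = 0.06,
    Treg = 0.03, MAIT = 0.03, NK = 0.12,
    B_naive = 0.08, B_SM = 0.05,
    C_mono = 0.12, NC_mono = 0.04)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_case < 1 || n_control < 1 || cells_per_sample < 1 || genes < 1)
      stop("configuration error: non-positive dimensions")
    if (abs(sum(cell_types) - 1) > 1e-9)
      stop("cell type abundance fractions must sum to 1")
    if (is.null(names(cell_types)) || anyDuplicated(names(cell_types)))
      stop("cell_types must be uniquely named")
    if (n_feature_genes_per_type < 1)
      stop("need at least 1 feature gene per cell type")
    if (doublet_rate < 0 || doublet_rate >= 1)
      stop("doublet_rate must be in [0, 1)")
    if (any(dispersion <= 0)) stop("dispersion must be positive")
    if (activation_sd < 0) stop("activation_sd must be >= 0")
    if (mito_mean <= 0 || mito_mean >= 1 || mito_sd < 0)
      stop("mitochondrial fraction parameters out of range")
    if (!all(names(composition_shift) %in% names(cell_types)))
      stop("composition_shift names must be cell types")
  })
  invisible(cfg)
}

MITO_GENES <- paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND5",
                              "CO1", "CO2", "CO3", "CYB", "ATP6"))
Y_GENES <- c("RPS4Y1", "EIF1AY", "DDX3Y", "UTY", "KDM5D")
X_GENES <- c("XIST", "TSIX", "KDM6A", "ZFX", "JPX")

# per-type de_spec lookup (scalar spec recycled over types)
de_spec_for <- function(cfg, type) {
  ds <- cfg$de_spec
  if (!is.null(ds$n_up)) ds else ds[[type]]
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic cohort
#'
#' Draws a full multi-sample case/control cohort from a [sim_config()]:
#' UMI counts are NB around depth-scaled cell-type profiles, case samples
#' scale each planted DE gene's log2FC by the sample's shared activation
#' scalar, composition is Dirichlet around (shifted) base fractions,
#' doublets are sums of two cells' expected profiles, sex marker genes
#' follow the assigned sex, and mitochondrial genes are rescaled to the
#' per-cell mitochondrial fraction. Fully reproducible from `config$seed`.
#'
#' @param config a `SimConfig` from [sim_config()].
#' @return list with elements `cm` (a [CellMatrix()]) and `truth`
#'   (a `CohortTruth` list: per-sample `alpha`, covariates and true
#'   composition; per-cell true type and doublet flag; per-type planted
#'   up/down DE tables with true log2FC; expected per-type profiles and
#'   feature genes; gene chrom/pos map; planted high-risk gene block).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  types <- names(cfg$cell_types)
  K <- length(types)

  ## ---- gene universe -------------------------------------------------
  n_special <- length(MITO_GENES) + length(Y_GENES) + length(X_GENES)
  if (cfg$genes <= n_special + K * cfg$n_feature_genes_per_type)
    stop("configuration error: gene universe too small for reserved genes")
  n_ord <- cfg$genes - n_special
  gene_names <- c(sprintf("G%05d", seq_len(n_ord)), MITO_GENES, Y_GENES, X_GENES)
  G <- length(gene_names)
  mito_idx <- match(MITO_GENES, gene_names)
  y_idx <- match(Y_GENES, gene_names)
  x_idx <- match(X_GENES, gene_names)
  ord_idx <- seq_len(n_ord)

  chrom <- c(sample(paste0("chr", 1:22), n_ord, replace = TRUE),
             rep("chrM", 10), rep("chrY", 5), rep("chrX", 5))
  pos <- c(sample.int(150e6, n_ord, replace = TRUE),
           sample.int(16e3, 10, replace = TRUE),
           sample.int(57e6, 5, replace = TRUE),
           sample.int(155e6, 5, replace = TRUE))
  # an HLA-like high-risk block on chr6:25-35Mb
  hla_block <- sample(ord_idx, min(40L, n_ord))
  chrom[hla_block] <- "chr6"
  pos[hla_block] <- sort(sample(seq(25e6, 35e6), length(hla_block)))
  gene_map <- data.frame(gene = gene_names, chrom = chrom, pos = pos)

  ## ---- type profiles -------------------------------------------------
  base_mean <- exp(stats::rnorm(G, 0, 1))
  base_mean[c(y_idx, x_idx)] <- 0          # filled per sex below
  base_mean[mito_idx] <- 0                 # filled per cell below
  feat_pool <- sample(ord_idx)             # disjoint marker blocks
  feature_genes <- list()
  profiles <- matrix(base_mean, G, K, dimnames = list(gene_names, types))
  for (k in seq_len(K)) {
    fi <- feat_pool[seq.int((k - 1) * cfg$n_feature_genes_per_type + 1,
                            k * cfg$n_feature_genes_per_type)]
    feature_genes[[types[k]]] <- gene_names[fi]
    profiles[fi, k] <- profiles[fi, k] * 8
  }

  ## ---- planted DE programs -------------------------------------------
  all_feat <- match(unlist(feature_genes), gene_names)
  de_pool <- sample(setdiff(ord_idx, all_feat))   # shuffled once; disjoint blocks
  need <- sum(vapply(types, function(ty) {
    ds <- de_spec_for(cfg, ty); ds$n_up + ds$n_down
  }, numeric(1)))
  if (need > length(de_pool))
    stop("configuration error: gene universe too small for disjoint DE sets")
  de <- list()
  used <- 0L
  for (k in seq_len(K)) {
    ds <- de_spec_for(cfg, types[k])
    n_up <- ds$n_up; n_down <- ds$n_down
    if (n_up + n_down > 0) {
      g <- de_pool[used + seq_len(n_up + n_down)]
      used <- used + n_up + n_down
      # right-skewed effect sizes: many moderate DEGs, a few strong ones
      lfc <- pmax(0.1, stats::rgamma(n_up + n_down, shape = 2,
                                     scale = ds$mean_lfc / 2))
      de[[types[k]]] <- data.frame(
        gene = gene_names[g],
        lfc = c(lfc[seq_len(n_up)], -lfc[seq_len(n_down) + n_up]))
    } else {
      de[[types[k]]] <- data.frame(gene = character(), lfc = numeric())
    }
  }

  ## ---- samples --------------------------------------------------------
  n_s <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("case%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl%02d", seq_len(cfg$n_control)))
  disease <- rep(c(1L, 0L), c(cfg$n_case, cfg$n_control))
  sex <- stats::rbinom(n_s, 1, 0.5)        # 1 = male
  alpha <- numeric(n_s)
  tier <- rep(NA_integer_, n_s)
  s <- cfg$activation_sd
  if (!is.null(cfg$activation_tiers)) {
    # discrete activation tiers (e.g. low/intermediate/high case subtypes)
    tier[disease == 1] <- sample(rep_len(seq_along(cfg$activation_tiers),
                                         cfg$n_case))
    alpha[disease == 1] <- cfg$activation_tiers[tier[disease == 1]]
  } else {
    alpha[disease == 1] <- stats::rlnorm(cfg$n_case, meanlog = -s^2 / 2,
                                         sdlog = s)
  }
  # clinical covariates linked to the latent activation in cases
  la <- rep(0, n_s)
  lac <- log(alpha[disease == 1])
  if (length(lac) > 1 && stats::sd(lac) > 0)
    la[disease == 1] <- scale(lac)[, 1]
  hla <- integer(n_s)
  hla[disease == 1] <- stats::rbinom(cfg$n_case, 2, stats::plogis(0.2 + 0.9 * la[disease == 1]))
  hla[disease == 0] <- stats::rbinom(cfg$n_control, 2, 0.35)
  gada <- numeric(n_s)
  gada[disease == 1] <- round(10^(1.5 + 0.8 * la[disease == 1] +
                                    stats::rnorm(cfg$n_case, 0, 0.3)), 1)
  batch <- rep_len(paste0("pool", 1:4), n_s)[sample.int(n_s)]

  shift <- stats::setNames(rep(0, K), types)
  shift[names(cfg$composition_shift)] <- cfg$composition_shift
  comp <- matrix(0, n_s, K, dimnames = list(sample_ids, types))
  for (i in seq_len(n_s)) {
    p <- exp(log(cfg$cell_types) + shift * disease[i])
    p <- p / sum(p)
    comp[i, ] <- rdirichlet1(cfg$dirichlet_conc * p)
  }

  ## ---- cells -----------------------------------------------------------
  phi <- rep_len(cfg$dispersion, G)
  nb_size <- 1 / phi
  # beta parameters for the mitochondrial fraction
  m_v <- max(cfg$mito_sd^2, 1e-8)
  m_ab <- cfg$mito_mean * (1 - cfg$mito_mean) / m_v - 1
  m_a <- max(cfg$mito_mean * m_ab, 0.5)
  m_b <- max((1 - cfg$mito_mean) * m_ab, 0.5)

  blocks <- vector("list", n_s)
  cell_meta <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    n_c <- cfg$cells_per_sample
    ty <- sample(types, n_c, replace = TRUE, prob = comp[i, ])
    dbl <- stats::rbinom(n_c, 1, cfg$doublet_rate) == 1
    ty2 <- ifelse(dbl, sample(types, n_c, replace = TRUE, prob = comp[i, ]), NA)
    depth <- stats::rlnorm(n_c, log(cfg$depth_mean) - cfg$depth_sdlog^2 / 2,
                           cfg$depth_sdlog)
    mito <- pmin(stats::rbeta(n_c, m_a, m_b), 0.95)

    # sample-level adjusted type profiles: DE effect scaled by alpha_s, sex genes
    prof <- profiles
    if (disease[i] == 1 && alpha[i] > 0) {
      for (k in seq_len(K)) {
        d <- de[[types[k]]]
        if (nrow(d))
          prof[match(d$gene, gene_names), k] <-
            prof[match(d$gene, gene_names), k] * 2^(d$lfc * alpha[i])
      }
    }
    med <- stats::median(base_mean[ord_idx])
    if (sex[i] == 1) {          # male
      prof[y_idx, ] <- med
      prof[x_idx, ] <- 0.02 * med
    } else {
      prof[y_idx, ] <- 1e-4 * med
      prof[x_idx, ] <- 4 * med
    }

    P <- prof[, ty, drop = FALSE]
    if (any(dbl)) {
      # expected-profile sum of the two contributing cells (double depth)
      P[, dbl] <- P[, dbl, drop = FALSE] +
        prof[, ty2[dbl], drop = FALSE]
    }
    # normalize columns, then impose the mitochondrial fraction
    cs <- colSums(P)
    P <- sweep(P, 2, cs, "/")
    non_mito <- colSums(P[-mito_idx, , drop = FALSE])
    P[-mito_idx, ] <- sweep(P[-mito_idx, , drop = FALSE], 2,
                            (1 - mito) / pmax(non_mito, 1e-12), "*")
    P[mito_idx, ] <- matrix(rep(mito / length(mito_idx), each = length(mito_idx)),
                            length(mito_idx), n_c)
    depth_eff <- depth * ifelse(dbl, 2, 1)
    mu <- sweep(P, 2, depth_eff, "*")
    cnt <- matrix(stats::rnbinom(G * n_c, mu = as.vector(mu),
                                 size = rep(nb_size, n_c)), G, n_c)
    rownames(cnt) <- gene_names
    colnames(cnt) <- sprintf("%s_c%04d", sample_ids[i], seq_len(n_c))
    blocks[[i]] <- Matrix::Matrix(cnt, sparse = TRUE)
    cell_meta[[i]] <- data.frame(
      barcode = colnames(cnt), sample = sample_ids[i], batch = batch[i],
      disease = disease[i], sex = sex[i],
      true_type = ty, doublet = dbl, true_mito = mito,
      gada = gada[i], hla_risk = hla[i])
  }

  cells <- do.call(rbind, cell_meta)
  counts <- do.call(cbind, blocks)
  cm <- CellMatrix(counts, cells, gene_map)

  truth <- structure(list(
    samples = data.frame(sample = sample_ids, disease = disease, sex = sex,
                         alpha = alpha, tier = tier, hla_risk = hla,
                         gada = gada, batch = batch),
    composition = comp,
    cells = cells[, c("barcode", "sample", "true_type", "doublet")],
    de = de,
    type_profiles = profiles,
    feature_genes = feature_genes,
    gene_map = gene_map,
    hla_block = gene_names[hla_block],
    config = cfg), class = "CohortTruth")
  list(cm = cm, truth = truth)
}

#' Build a reference panel from cohort truth
#'
#' Emulates a sorted-bulk reference panel: per cell type, the log10 of the
#' expected expression profile restricted to the union of the panel types'
#' feature genes, plus Gaussian noise. Cell types may be collapsed into
#' compartments (row = mean member profile), mirroring low-resolution
#' major panels.
#'
#' @param truth `CohortTruth` from [generate_cohort()].
#' @param noise_sd sd of Gaussian noise added on the log10 scale (>= 0).
#' @param types cell types to include (default: all in truth).
#' @param collapse optional named list compartment -> member types; when
#'   given, panel rows are compartments.
#' @param name panel name.
#' @param seed seed for the noise draw.
#' @return a [reference_panel()] object.
#' @export
generate_reference_panel <- function(truth, noise_sd = 0.05, types = NULL,
                                     collapse = NULL, name = "panel",
                                     seed = 1L) {
  stopifnot(inherits(truth, "CohortTruth"), noise_sd >= 0)
  set.seed(seed)
  prof <- truth$type_profiles
  if (is.null(types)) types <- colnames(prof)
  if (!is.null(collapse)) {
    mem <- unlist(collapse, use.names = FALSE)
    stopifnot(all(mem %in% colnames(prof)))
    rows <- vapply(collapse, function(m)
      rowMeans(prof[, m, drop = FALSE]), numeric(nrow(prof)))
    prof <- rows
    feats <- unique(unlist(truth$feature_genes[mem]))
  } else {
    stopifnot(all(types %in% colnames(prof)))
    prof <- prof[, types, drop = FALSE]
    feats <- unique(unlist(truth$feature_genes[types]))
  }
  if (length(feats) < 1) stop("no feature genes for requested types")
  cpm <- sweep(prof, 2, colSums(prof), "/") * 1e4
  m <- t(log10(cpm[feats, , drop = FALSE] + 1))
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  reference_panel(m, name = name)
}

#' Generate gene-level genetic risk scores
#'
#' Stands in for externally computed gene-level GWAS association scores
#' (-log10 of a gene-level p-value). A fraction `signal_frac` of the
#' planted DE genes of the designated causal cell types receive elevated
#' scores; the HLA-like chr6 block always scores high so that
#' region-exclusion logic is exercised.
#'
#' @param truth `CohortTruth`.
#' @param signal_frac fraction of causal-type DE genes carrying signal,
#'   in `[0, 1]`.
#' @param causal_types cell types whose DE programs carry heritability
#'   (default: the first cell type).
#' @param effect mean elevation of signal-gene scores.
#' @param seed integer seed.
#' @return data.frame with `gene`, `score`, `chrom`, `pos`.
#' @export
generate_gene_risk_scores <- function(truth, signal_frac = 0.5,
                                      causal_types = NULL, effect = 3,
                                      seed = 1L) {
  stopifnot(inherits(truth, "CohortTruth"),
            signal_frac >= 0, signal_frac <= 1)
  set.seed(seed)
  gm <- truth$gene_map
  score <- stats::rexp(nrow(gm), rate = 1)
  if (is.null(causal_types)) causal_types <- names(truth$de)[1]
  de <- do.call(rbind, truth$de[causal_types])
  if (!is.null(de) && nrow(de) && signal_frac > 0) {
    # risk elevation scales with the planted effect size, so genes most
    # strongly differentially expressed in the causal program carry the
    # most genetic signal
    lfc_of <- tapply(abs(de$lfc), de$gene, max)
    hit <- names(lfc_of)[stats::runif(length(lfc_of)) < signal_frac]
    i <- match(hit, gm$gene)
    mean_lfc <- mean(abs(de$lfc))
    score[i] <- score[i] +
      stats::rgamma(length(i), shape = 2,
                    scale = effect * lfc_of[hit] / (2 * mean_lfc))
  }
  ib <- match(truth$hla_block, gm$gene)
  score[ib] <- score[ib] + stats::rexp(length(ib), rate = 1 / (2 * effect))
  data.frame(gene = gm$gene, score = score, chrom = gm$chrom, pos = gm$pos)
}
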