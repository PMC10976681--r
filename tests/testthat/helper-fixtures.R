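# Shared fixtures and independent oracles for the test suite.
# Cohorts are generated in code at test time; nothing is read from disk.

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  t <- table(a, b)
  N <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  expected <- si * sj / choose(N, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# brute-force unweighted GSEA running sum: independent loop
# implementation used as the oracle for the streaming version
gsea_es_bruteforce <- function(ranked, set) {
  n_hit <- sum(ranked %in% set)
  n_miss <- length(ranked) - n_hit
  rs <- 0
  best <- 0
  for (g in ranked) {
    rs <- rs + if (g %in% set) 1 / n_hit
               else if (n_miss > 0) -1 / n_miss else 0
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# exact hypergeometric upper tail by direct choose() enumeration
hyper_tail_enum <- function(x, size_a, size_b, N) {
  hi <- min(size_a, size_b)
  if (x > hi) return(0)
  k <- x:hi
  sum(choose(size_a, k) * choose(N - size_a, size_b - k)) / choose(N, size_b)
}

# small generic cohort reused across files (cheap: ~1 s)
tiny_cohort <- function(seed = 3L, ...) {
  args <- utils::modifyList(
    list(n_case = 4L, n_control = 4L, cells_per_sample = 120L,
         genes = 600L,
         cell_types = c(A = 0.4, B = 0.35, C = 0.25),
         n_feature_genes_per_type = 20L,
         de_spec = list(n_up = 15L, n_down = 15L, mean_lfc = 1),
         seed = seed),
    list(...))
  generate_cohort(do.call(sim_config, args))
}

true_labels <- function(g) {
  lab <- stats::setNames(g$cm$cells$true_type, g$cm$cells$barcode)
  lab[g$cm$cells$doublet] <- NA
  lab
}

deg_sets_from_truth <- function(truth) {
  lapply(truth$de, function(d) list(up = d$gene[d$lfc > 0],
                                    down = d$gene[d$lfc < 0]))
}

# 3-compartment / 6-subtype cohort plus panel hierarchy for annotation tests
hierarchy_cohort <- function(seed = 11L, noise_sd = 0.05,
                             n_case = 5L, n_control = 5L,
                             cells_per_sample = 250L) {
  cfg <- sim_config(
    n_case = n_case, n_control = n_control,
    cells_per_sample = cells_per_sample, genes = 800L,
    cell_types = c(T_CD4 = 0.25, T_CD8 = 0.2, B_naive = 0.15,
                   B_mem = 0.1, C_mono = 0.2, NC_mono = 0.1),
    de_spec = list(n_up = 15L, n_down = 15L, mean_lfc = 1),
    doublet_rate = 0.05, seed = seed)
  g <- generate_cohort(cfg)
  collapse <- list(Tcell = c("T_CD4", "T_CD8"),
                   Bcell = c("B_naive", "B_mem"),
                   Mono = c("C_mono", "NC_mono"))
  major <- generate_reference_panel(g$truth, noise_sd = noise_sd,
                                    collapse = collapse, name = "major",
                                    seed = seed + 1L)
  subs <- lapply(seq_along(collapse), function(i)
    list(generate_reference_panel(g$truth, noise_sd = noise_sd,
                                  types = collapse[[i]],
                                  name = names(collapse)[i],
                                  seed = seed + 1L + i)))
  names(subs) <- names(collapse)
  hier <- panel_hierarchy(major,
                          compartment_of = stats::setNames(names(collapse),
                                                           names(collapse)),
                          subpanels = subs)
  list(g = g, hier = hier)
}
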