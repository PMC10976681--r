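test_that("generation is deterministic and respects basic contracts", {
  g1 <- tiny_cohort(seed = 3)
  g2 <- tiny_cohort(seed = 3)
  expect_identical(as.matrix(g1$cm$counts), as.matrix(g2$cm$counts))
  expect_identical(g1$truth$samples, g2$truth$samples)

  g3 <- tiny_cohort(seed = 4)
  expect_false(identical(as.matrix(g1$cm$counts), as.matrix(g3$cm$counts)))

  # planted DE sets are disjoint within and across cell types
  all_de <- unlist(lapply(g1$truth$de, `[[`, "gene"))
  expect_false(anyDuplicated(all_de) > 0)
  for (d in g1$truth$de) {
    expect_true(all(d$gene %in% rownames(g1$cm$counts)))
  }
  expect_true(all(g1$cm$cells$true_type %in% c("A", "B", "C")))

  expect_error(sim_config(n_case = 0), "non-positive")
  expect_error(sim_config(cell_types = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(sim_config(n_feature_genes_per_type = 0), "feature gene")
})

test_that("doublet_rate 0 yields no doublets; rate > 0 yields some", {
  g <- tiny_cohort(seed = 5, doublet_rate = 0)
  expect_false(any(g$cm$cells$doublet))
  g2 <- tiny_cohort(seed = 5, doublet_rate = 0.15)
  expect_gt(mean(g2$cm$cells$doublet), 0.05)
})

test_that("null construction: no DE, no shift makes groups exchangeable", {
  cfg <- sim_config(n_case = 8L, n_control = 8L, cells_per_sample = 100L,
                    genes = 500L, cell_types = c(A = 0.6, B = 0.4),
                    n_feature_genes_per_type = 15L,
                    de_spec = list(n_up = 0L, n_down = 0L, mean_lfc = 0),
                    doublet_rate = 0, seed = 21L)
  g <- generate_cohort(cfg)
  # per-gene t-test on per-sample mean expression, case vs control
  cnt <- as.matrix(g$cm$counts)
  samp <- g$cm$cells$sample
  depth <- colSums(cnt)
  norm <- sweep(cnt, 2, mean(depth) / depth, "*")
  sm <- t(apply(norm, 1, function(v) tapply(v, samp, mean)))
  disease <- g$truth$samples$disease[match(colnames(sm),
                                           g$truth$samples$sample)]
  keep <- rowSums(sm) > 5 & apply(sm, 1, stats::var) > 0
  p <- apply(sm[keep, ], 1, function(v)
    stats::t.test(v[disease == 1], v[disease == 0])$p.value)
  expect_gt(length(p), 200)
  expect_lt(mean(p < 0.05), 0.12)   # nominal 0.05 plus small-n slack
  expect_gt(mean(p < 0.05), 0.005)
})

test_that("NB mean-variance: empirical var tracks mu + phi mu^2", {
  cfg <- sim_config(n_case = 1L, n_control = 1L, cells_per_sample = 800L,
                    genes = 600L, cell_types = c(A = 1),
                    n_feature_genes_per_type = 10L,
                    de_spec = list(n_up = 0L, n_down = 0L, mean_lfc = 0),
                    doublet_rate = 0, depth_sdlog = 0, mito_sd = 0,
                    dispersion = 0.4, seed = 9L)
  g <- generate_cohort(cfg)
  ctrl <- g$truth$samples$sample[g$truth$samples$disease == 0]
  cells <- g$cm$cells$sample == ctrl
  cnt <- as.matrix(g$cm$counts[, cells])
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, stats::var)
  use <- mu > 2
  phi_hat <- stats::lm(I(v[use] - mu[use]) ~ 0 + I(mu[use]^2))$coefficients
  expect_gt(phi_hat, 0.4 * 0.7)
  expect_lt(phi_hat, 0.4 * 1.3)
})

test_that("activation scalars: cases log-normal mean ~1, controls 0; tiers work", {
  cfg <- sim_config(n_case = 40L, n_control = 5L, cells_per_sample = 10L,
                    genes = 600L, cell_types = c(A = 1),
                    n_feature_genes_per_type = 5L,
                    de_spec = list(n_up = 2L, n_down = 2L, mean_lfc = 1),
                    activation_sd = 0.4, seed = 13L)
  g <- generate_cohort(cfg)
  a <- g$truth$samples$alpha
  d <- g$truth$samples$disease
  expect_true(all(a[d == 0] == 0))
  expect_true(all(a[d == 1] > 0))
  expect_lt(abs(mean(a[d == 1]) - 1), 0.35)

  gt <- generate_cohort(sim_config(
    n_case = 12L, n_control = 3L, cells_per_sample = 10L, genes = 600L,
    cell_types = c(A = 1), n_feature_genes_per_type = 5L,
    de_spec = list(n_up = 2L, n_down = 2L, mean_lfc = 1),
    activation_tiers = c(0.5, 1, 2), seed = 14L))
  tiers <- gt$truth$samples$tier[gt$truth$samples$disease == 1]
  expect_equal(sort(unique(tiers)), 1:3)
  expect_equal(unname(table(tiers)), rep(4L, 3), ignore_attr = TRUE)
})

test_that("reference panels are deterministic and noiseless projection is exact", {
  g <- tiny_cohort(seed = 6)
  p1 <- generate_reference_panel(g$truth, noise_sd = 0, seed = 2)
  p2 <- generate_reference_panel(g$truth, noise_sd = 0, seed = 2)
  expect_identical(p1$mat, p2$mat)
  p3 <- generate_reference_panel(g$truth, noise_sd = 0.1, seed = 2)
  expect_false(identical(p1$mat, p3$mat))

  # a type's own expected profile correlates best with its panel row
  prof <- g$truth$type_profiles
  feats <- colnames(p1$mat)
  for (ty in colnames(prof)) {
    r <- apply(p1$mat, 1, function(row)
      stats::cor(log10(prof[feats, ty] + 1e-8), row))
    expect_equal(names(which.max(r)), ty)
  }
})

test_that("risk scores: nonnegative, deterministic, null when signal_frac 0", {
  g <- tiny_cohort(seed = 8)
  r0 <- generate_gene_risk_scores(g$truth, signal_frac = 0, seed = 1)
  expect_true(all(r0$score >= 0))
  expect_identical(r0, generate_gene_risk_scores(g$truth, signal_frac = 0,
                                                 seed = 1))

  # permutation oracle: with signal_frac 0 the causal genes' mean score is
  # not elevated (excluding the always-elevated HLA-like block)
  causal <- g$truth$de[[1]]$gene
  rej <- vapply(1:40, function(s) {
    rr <- generate_gene_risk_scores(g$truth, signal_frac = 0, seed = s)
    rr <- rr[!(rr$gene %in% g$truth$hla_block), ]
    is_c <- rr$gene %in% causal
    obs <- mean(rr$score[is_c])
    null <- replicate(500, mean(sample(rr$score, sum(is_c))))
    mean(null >= obs) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.2)   # nominal 0.05; 40 replicates

  r1 <- generate_gene_risk_scores(g$truth, signal_frac = 1, effect = 5,
                                  seed = 1)
  is_c <- r1$gene %in% causal
  expect_gt(mean(r1$score[is_c]), mean(r1$score[!is_c]) + 2)
})
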