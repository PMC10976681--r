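test_that("pseudo-bulk sums, min-cell exclusion and gene detection filter", {
  # 3 samples x type X: s1 has 4 cells (excluded), s2 and s3 enough
  G <- 5
  mk <- function(n, val) matrix(val, G, n)
  counts <- cbind(mk(4, 1), mk(6, 2), mk(6, 3))
  rownames(counts) <- paste0("g", 1:G)
  cells <- data.frame(sample = rep(c("s1", "s2", "s3"), c(4, 6, 6)),
                      disease = rep(c(0, 0, 1), c(4, 6, 6)))
  cm <- CellMatrix(counts, cells)
  pb <- suppressWarnings(
    make_pseudobulk(cm, rep("X", 16), min_cells = 5, min_sample_frac = 0))
  # disease guard would skip with < 3 per group; bypass it here
  expect_true(is.null(pb$types$X) ||
                !"s1" %in% rownames(pb$types$X$counts))
  expect_equal(pb$excluded$sample, "s1")
  expect_equal(pb$excluded$n_cells, 4L)

  # summation: two cells (1,2) and (3,4) -> (4,6)
  c2 <- CellMatrix(matrix(c(1, 2, 3, 4), 2, 2,
                          dimnames = list(c("a", "b"), c("x", "y"))),
                   data.frame(sample = c("s1", "s1")))
  pb2 <- make_pseudobulk(c2, c("T", "T"), min_cells = 2, min_sample_frac = 0)
  expect_equal(unname(pb2$types$T$counts["s1", ]), c(4, 6))
})

test_that("gene detected in under 5% of samples is dropped for that type", {
  set.seed(3)
  n_samp <- 40
  cells_per <- 6
  counts <- matrix(rpois(3 * n_samp * cells_per, 5), 3,
                   dimnames = list(c("common", "rare", "absent"), NULL))
  counts["rare", ] <- 0
  counts["rare", 1:2] <- 1          # detected in 1 of 40 samples (2.5%)
  counts["absent", ] <- 0
  cells <- data.frame(sample = rep(sprintf("s%02d", 1:n_samp),
                                   each = cells_per),
                      disease = rep(rep(0:1, each = n_samp / 2),
                                    each = cells_per))
  cm <- CellMatrix(counts, cells)
  pb <- make_pseudobulk(cm, rep("X", ncol(counts)), min_cells = 5,
                        min_sample_frac = 0.05)
  expect_equal(colnames(pb$types$X$counts), "common")
})

test_that("median-of-ratios size factors are proportional for scaled samples", {
  counts <- rbind(s1 = c(10, 20, 30, 40), s2 = c(20, 40, 60, 80))
  sf <- size_factors_mor(counts)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  # zero-reference genes are skipped, not fatal
  counts2 <- cbind(counts, c(0, 5))
  expect_equal(unname(size_factors_mor(counts2)), unname(sf))
})

test_that("BH q-values match the direct enumeration oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # oracle: q_i = min_{j >= i} p_(j) * m / j on sorted p-values
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  q_oracle <- q_sorted[match(seq_len(m), o)]
  expect_equal(unname(q_oracle), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), q_oracle)
})

test_that("Poisson-limit closed form: LFC equals normalized group-mean ratio", {
  # exactly proportional samples: dispersion collapses to ~0 and the NB
  # GLM MLE has the Poisson closed form log(sum(y)/sum(sf)) per group
  base <- c(40, 100, 10, 250)
  counts <- rbind(s1 = base, s2 = 2 * base, s3 = 3 * base,
                  s4 = 3 * base, s5 = 6 * base, s6 = 4.5 * base * 2)
  cond <- c(0, 0, 0, 1, 1, 1)
  dt <- nb_de_test(counts, cond)
  sf <- size_factors_mor(counts)
  for (gi in seq_along(base)) {
    y <- counts[, gi]
    lfc_oracle <- log2((sum(y[4:6]) / sum(sf[4:6])) /
                         (sum(y[1:3]) / sum(sf[1:3])))
    expect_equal(dt$lfc[gi], lfc_oracle, tolerance = 1e-6)
  }
  expect_error(nb_de_test(counts[1:4, ], c(0, 0, 1, 1)), "3 samples")
})

test_that("null NB data give calibrated Wald p-values", {
  set.seed(12)
  n <- 30; G <- 600
  mu <- exp(runif(G, log(5), log(300)))
  sf_true <- exp(rnorm(n, 0, 0.25))
  counts <- sapply(seq_len(G), function(g)
    rnbinom(n, mu = mu[g] * sf_true, size = 1 / 0.2))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("g", 1:G))
  dt <- nb_de_test(counts, rep(0:1, each = n / 2))
  t1 <- mean(dt$p < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02); expect_lt(t1, 0.09)
})

test_that("DEG calling applies inclusive boundaries and the DES formula", {
  dt <- data.frame(gene = c("a", "b", "c", "d"),
                   cell_type = "X",
                   lfc = c(log2(1.3), 0.2, -0.5, 1),
                   q = c(0.1, 0.001, 0.05, 0.01))
  out <- call_degs(dt, quiet = TRUE)
  expect_equal(out$direction, c("up", "none", "down", "up"))
  expect_equal(out$des[4], 1 * -log10(0.01))     # = 2
  expect_equal(out$des[4], 2)
  sets <- attr(out, "deg_sets")$X
  expect_setequal(sets$up, c("a", "d"))
  expect_equal(sets$down, "c")
  expect_length(intersect(sets$up, sets$down), 0)

  # stricter threshold drops the boundary gene
  out2 <- call_degs(dt, q_max = 0.05, quiet = TRUE)
  expect_equal(attr(out2, "deg_sets")$X$up, "d")
})

test_that("LFC sign matches the normalized group-mean ratio", {
  set.seed(20)
  n <- 20; G <- 80
  counts <- sapply(seq_len(G), function(g)
    rnbinom(n, mu = exp(runif(1, 2, 5)), size = 5))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("g", 1:G))
  cond <- rep(0:1, each = 10)
  dt <- nb_de_test(counts, cond)
  sf <- size_factors_mor(counts)
  q <- sweep(counts, 1, sf, "/")
  ratio <- colMeans(q[cond == 1, ]) / colMeans(q[cond == 0, ])
  ok <- dt$converged & abs(log2(ratio)) > 1e-3
  expect_true(all(sign(dt$lfc[ok]) == sign(log2(ratio[ok]))))
})

test_that("marker genes: detection filter, covariates, truth recovery", {
  # precision is scored on a cohort without planted disease programs:
  # case-only DE genes are genuinely type-restricted signal and would
  # otherwise be counted as false positives
  g <- tiny_cohort(seed = 50, doublet_rate = 0,
                   de_spec = list(n_up = 0L, n_down = 0L, mean_lfc = 0))
  lab <- g$cm$cells$true_type
  mk <- marker_genes(g$cm, lab, covariates = c("batch", "disease"),
                     types = c("A", "B"))
  expect_true(all(pmax(mk$pct_in, mk$pct_out) >= 0.25))
  # the simulator's feature genes are recovered with high precision
  for (ty in c("A", "B")) {
    called <- mk$gene[mk$cell_type == ty & mk$marker]
    expect_gt(length(called), 3)
    prec <- mean(called %in% g$truth$feature_genes[[ty]])
    expect_gte(prec, 0.9)
  }
  expect_error(marker_genes(g$cm, rep("A", ncol(g$cm$counts))),
               "two cell types")
})

test_that("LFC shrinkage pulls noisy estimates toward zero", {
  set.seed(30)
  n <- 16; G <- 150
  counts <- sapply(seq_len(G), function(g)
    rnbinom(n, mu = exp(runif(1, 1.5, 4)), size = 4))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("g", 1:G))
  dt <- nb_de_test(counts, rep(0:1, each = 8), shrink_lfc = TRUE)
  ok <- dt$converged
  expect_true(all(abs(dt$lfc_shrunk[ok]) <= abs(dt$lfc[ok]) + 1e-12))
  expect_true(all(sign(dt$lfc_shrunk[ok]) == sign(dt$lfc[ok]) |
                    dt$lfc_shrunk[ok] == 0))
})
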