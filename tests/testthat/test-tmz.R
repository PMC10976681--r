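test_that("the metagene equation combines z-scores as stated", {
  # hand example: up z-scores {1, 3}, down z-scores {-1, -3} -> 2 - (-2) = 4
  z <- matrix(c(1, 3, -1, -3), 1, 4,
              dimnames = list("s1", c("u1", "u2", "d1", "d2")))
  expect_equal(unname(tmz_from_z(z, c("u1", "u2"), c("d1", "d2"))), 4)
  # all-up +1, all-down -1 -> 2
  z2 <- matrix(c(1, 1, -1, -1), 1, 4,
               dimnames = list("s1", c("u1", "u2", "d1", "d2")))
  expect_equal(unname(tmz_from_z(z2, c("u1", "u2"), c("d1", "d2"))), 2)
  # empty down set contributes 0
  expect_equal(unname(tmz_from_z(z, c("u1", "u2"), character())), 2)
})

test_that("compute_tmz matches a manual z-score oracle and centers at 0", {
  g <- tiny_cohort(seed = 60)
  lab <- true_labels(g)
  pb <- make_pseudobulk(g$cm, lab, min_cells = 3)
  sets <- deg_sets_from_truth(g$truth)
  tm <- compute_tmz(pb, sets)
  ty <- names(pb$types)[1]
  # independent recomputation: log2-CPM, z per gene, mean difference
  expr <- pb_log2cpm(pb$types[[ty]]$counts)
  up <- intersect(sets[[ty]]$up, colnames(expr))
  dn <- intersect(sets[[ty]]$down, colnames(expr))
  zs <- scale(expr[, c(up, dn)])
  manual <- rowMeans(zs[, up]) - rowMeans(zs[, dn])
  expect_equal(tm[rownames(expr), ty], manual, tolerance = 1e-12)
  # z-scores are centered: each column of the TMZ matrix has mean ~0
  cm_means <- colMeans(unclass(tm), na.rm = TRUE)
  expect_true(all(abs(cm_means) < 1e-9))
  # average is the row mean over non-missing entries
  expect_equal(attr(tm, "average"),
               rowMeans(unclass(tm), na.rm = TRUE))
})

test_that("TMZ is invariant to constant expression offsets (z-score identity)", {
  set.seed(61)
  expr <- matrix(rnorm(8 * 6, 5), 8, 6,
                 dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  up <- paste0("g", 1:3); dn <- paste0("g", 4:6)
  t1 <- tmz_from_z(scale(expr), up, dn)
  t2 <- tmz_from_z(scale(expr + 7.3), up, dn)        # global offset
  t3 <- tmz_from_z(scale(sweep(expr, 2, rnorm(6), "+")), up, dn)  # per-gene
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_equal(t1, t3, tolerance = 1e-12)
})

test_that("subtyping orders labels by mean score and handles degeneracy", {
  set.seed(4)
  base <- c(rep(-2, 10), rep(0, 10), rep(2, 10))
  X <- matrix(base + rnorm(30 * 4, sd = 0.2), 30, 4,
              dimnames = list(paste0("s", 1:30), paste0("t", 1:4)))
  tm <- structure(X, average = rowMeans(X), missing = is.na(X),
                  class = c("TmzMatrix", "matrix", "array"))
  lab <- subtype_samples(tm, k = 3, seed = 2)
  expect_equal(levels(lab), c("low", "intermediate", "high"))
  expect_equal(ari(lab, rep(1:3, each = 10)), 1)
  m <- tapply(rowMeans(X), lab, mean)
  expect_true(m["low"] < m["intermediate"] &
                m["intermediate"] < m["high"])

  # identical samples: degenerate single cluster, warned
  X0 <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  tm0 <- structure(X0, class = c("TmzMatrix", "matrix", "array"))
  expect_warning(lab0 <- subtype_samples(tm0, k = 3), "identical")
  expect_equal(length(unique(as.character(lab0))), 1)

  # missing values are imputed with the sample's own mean
  Xm <- X; Xm[1, 2] <- NA
  tmm <- structure(Xm, class = c("TmzMatrix", "matrix", "array"))
  labm <- subtype_samples(tmm, k = 3, seed = 2)
  expect_equal(ari(labm, rep(1:3, each = 10)), 1)
})

test_that("clinical association: Spearman, Kruskal-Wallis and OLS behave", {
  set.seed(5)
  n <- 24
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(paste0("s", 1:n), c("t1", "t2")))
  gada <- 1:n
  X[, "t1"] <- gada + 0.0          # strictly increasing in GADA
  cov <- data.frame(sample = rownames(X), sex = rep(0:1, n / 2),
                    gada = gada, hla_risk = rep(c(0, 1, 2), each = n / 3))
  tm <- structure(X, class = c("TmzMatrix", "matrix", "array"))
  out <- tmz_association(tm, cov)
  expect_equal(out$spearman$rho[out$spearman$score == "t1"], 1)
  expect_true(all(c("sex", "gada", "hla_risk") %in% out$regression$term))
  expect_false(any(is.na(out$kruskal$p)))

  # constant covariate dropped with a warning
  cov2 <- cov; cov2$sex <- 1
  expect_warning(out2 <- tmz_association(tm, cov2), "constant")
  expect_false("sex" %in% out2$regression$term)

  # single HLA category: Kruskal-Wallis missing
  cov3 <- cov; cov3$hla_risk <- 2
  expect_warning(out3 <- tmz_association(tm, cov3), "constant")
  expect_true(is.null(out3$kruskal) || all(is.na(out3$kruskal$p)))
})

test_that("F-test calibration under permuted covariates", {
  set.seed(6)
  n <- 40
  X <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "t1"))
  tm <- structure(X, class = c("TmzMatrix", "matrix", "array"))
  rej <- replicate(400, {
    cov <- data.frame(sample = rownames(X), sex = sample(rep(0:1, n / 2)),
                      gada = sample(n))
    out <- tmz_association(tm, cov)
    out$regression$p[out$regression$score == "t1" &
                       out$regression$term == "gada"] < 0.05
  })
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)
})

test_that("compartment DEG sets union types and drop sign conflicts", {
  sets <- list(A = list(up = c("g1", "g2"), down = c("g3")),
               B = list(up = c("g4", "g3"), down = c("g5")),
               M = list(up = c("g6"), down = c("g7")))
  cds <- compartment_deg_sets(sets, c(A = "TNK", B = "TNK", M = "Mono"))
  # g3 is up in B but down in A: dropped from both TNK sets
  expect_setequal(cds$TNK$up, c("g1", "g2", "g4"))
  expect_equal(cds$TNK$down, "g5")
  expect_equal(cds$Mono$up, "g6")
})

test_that("bulk projection maps quantiles onto the reference distribution", {
  set.seed(7)
  genes <- paste0("g", 1:40)
  cds <- structure(list(C = list(up = genes[1:20], down = genes[21:40])),
                   class = "CompartmentDegSets")
  bulk <- matrix(rnorm(40 * 11), 40, 11,
                 dimnames = list(genes, paste0("b", 1:11)))
  ref <- list(C = sort(rnorm(50, 2, 1)))
  out <- project_bulk_tmz(bulk, cds, ref)
  # the median bulk sample maps to the reference median
  med_i <- which(rank(out$C$raw, ties.method = "average") == 6)
  expect_equal(unname(out$C$projected[med_i]),
               unname(stats::quantile(ref$C, 0.5)))
  # a monotone transform of bulk expression preserves projected ranks
  out2 <- project_bulk_tmz(bulk * 3 + 1, cds, ref)
  expect_equal(rank(out2$C$projected), rank(out$C$projected))
  expect_equal(sort(names(out$C$projected)), sort(colnames(bulk)))

  # too few overlapping genes: compartment skipped with warning
  expect_warning(
    none <- project_bulk_tmz(bulk[1:5, ], cds, ref), "fewer than")
  expect_length(none, 0)

  # single-sample input requires reference gene statistics
  expect_error(project_bulk_tmz(bulk[, 1, drop = FALSE], cds, ref),
               "reference gene statistics")
  st <- list(C = list(mean = setNames(rep(0, 40), genes),
                      sd = setNames(rep(1, 40), genes)))
  out1 <- project_bulk_tmz(bulk[, 1, drop = FALSE], cds, ref,
                           ref_gene_stats = st)
  expect_length(out1$C$projected, 1)
})

test_that("paired treatment design: planted score reduction is detected", {
  set.seed(8)
  genes <- paste0("g", 1:60)
  cds <- structure(list(C = list(up = genes[1:30], down = genes[31:60])),
                   class = "CompartmentDegSets")
  n_pairs <- 10
  # pre samples express the up program; treatment shrinks it
  pre <- rbind(matrix(rnorm(30 * n_pairs, 2), 30),
               matrix(rnorm(30 * n_pairs, -2), 30))
  post <- rbind(matrix(rnorm(30 * n_pairs, 0.8), 30),
                matrix(rnorm(30 * n_pairs, -0.8), 30))
  bulk <- cbind(pre, post)
  dimnames(bulk) <- list(genes, c(paste0("pre", 1:n_pairs),
                                  paste0("post", 1:n_pairs)))
  ref <- list(C = rnorm(60))
  out <- project_bulk_tmz(bulk, cds, ref)
  pt <- t.test(out$C$projected[1:n_pairs],
               out$C$projected[n_pairs + 1:n_pairs], paired = TRUE,
               alternative = "greater")
  expect_lt(pt$p.value, 0.05)
})
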