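test_that("normalization is depth-invariant and handles zero cells", {
  # genes x cells: c1 = (1,2,0), c2 = (2,4,0) proportional, c3 = (3,6,0)
  m <- matrix(c(1, 2, 0,
                2, 4, 0,
                3, 6, 0), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  cm <- CellMatrix(m, data.frame(sample = rep("s", 3)))
  expect_warning(nn <- normalize_cells(CellMatrix(
    cbind(m, c4 = c(0, 0, 0)), data.frame(sample = rep("s", 4)))),
    "all-zero")
  expect_true(all(as.matrix(nn)[, "c4"] == 0))
  ne <- normalize_cells(cm)
  # proportional cells normalize identically
  expect_equal(as.numeric(ne[, 1]), as.numeric(ne[, 2]))
  # doubling every count leaves normalized values unchanged
  ne2 <- normalize_cells(CellMatrix(2 * m, data.frame(sample = rep("s", 3))))
  expect_equal(as.matrix(ne), as.matrix(ne2), ignore_attr = TRUE)
})

test_that("projection applies sign-preserving power and row z-transform", {
  set.seed(4)
  genes <- paste0("g", 1:50)
  ref <- rnorm(50)
  # craft cells with known correlation to the panel row
  refc <- scale(ref)[, 1]
  noise <- scale(stats::residuals(stats::lm(rnorm(50) ~ refc)))[, 1]
  cell_pos <- 2 + 3 * refc                       # r = 1
  cell_neg <- -0.5 * refc + sqrt(0.75) * noise   # r = -0.5
  E <- cbind(pos = cell_pos, neg = cell_neg, rand = rnorm(50))
  rownames(E) <- genes
  panel <- reference_panel(matrix(ref, 1, 50,
                                  dimnames = list("T1", genes)))
  pr <- project_to_panel(E, panel, power = 4, z_rows = FALSE)
  expect_equal(pr["T1", "pos"], 1, tolerance = 1e-12)
  expect_equal(pr["T1", "neg"], -0.0625, tolerance = 1e-10)

  # permuting gene order consistently leaves scores unchanged
  perm <- sample(50)
  panel_p <- reference_panel(matrix(ref[perm], 1, 50,
                                    dimnames = list("T1", genes[perm])))
  pr2 <- project_to_panel(E[perm, ], panel_p, z_rows = FALSE)
  expect_equal(as.numeric(pr2), as.numeric(pr), tolerance = 1e-12)

  # constant cell over feature genes: flagged, NA
  E2 <- cbind(E, flat = rep(1, 50))
  prf <- project_to_panel(E2, panel, z_rows = FALSE)
  expect_true(is.na(prf["T1", "flat"]))
  expect_equal(attr(prf, "degenerate_cells"), "flat")

  # z-transformed rows have mean 0 and sd 1
  g <- tiny_cohort(seed = 40)
  pan <- generate_reference_panel(g$truth, noise_sd = 0.05)
  pz <- project_to_panel(normalize_cells(g$cm), pan)
  expect_true(all(abs(rowMeans(pz)) < 1e-8))
  expect_true(all(abs(apply(pz, 1, sd) - 1) < 1e-6))
})

test_that("projection is invariant to per-cell scaling of raw counts", {
  g <- tiny_cohort(seed = 41)
  pan <- generate_reference_panel(g$truth, noise_sd = 0)
  sc <- g$cm
  set.seed(1)
  f <- runif(ncol(sc$counts), 0.5, 3)
  sc$counts <- sc$counts %*% Matrix::Diagonal(x = f)
  dimnames(sc$counts) <- dimnames(g$cm$counts)
  p1 <- project_to_panel(normalize_cells(g$cm), pan)
  p2 <- project_to_panel(normalize_cells(sc), pan)
  expect_equal(as.matrix(p1), as.matrix(p2), tolerance = 1e-10)
})

test_that("dynamic clustering splits real blocks and nothing else", {
  set.seed(7)
  # two blocks of identical projection columns
  a <- rnorm(8); b <- rnorm(8)
  X <- cbind(matrix(a, 8, 30), matrix(b, 8, 30)) +
    matrix(rnorm(8 * 60, sd = 0.01), 8)
  colnames(X) <- paste0("c", 1:60)
  lab <- cluster_by_projection(X, min_cluster_size = 10)
  expect_equal(length(unique(lab)), 2)
  expect_equal(ari(lab, rep(1:2, each = 30)), 1)

  # all columns identical: a single cluster
  X1 <- matrix(a, 8, 40, dimnames = list(NULL, paste0("c", 1:40)))
  expect_equal(length(unique(cluster_by_projection(X1, 10))), 1)

  # label assignment is invariant to input order up to relabelling
  perm <- sample(60)
  lab_p <- cluster_by_projection(X[, perm], min_cluster_size = 10)
  expect_equal(ari(lab_p, lab[perm]), 1)

  # fixed-k fallback
  lab_k <- cluster_by_projection(X, min_cluster_size = 10, k = 2)
  expect_equal(length(unique(lab_k)), 2)

  # fewer cells than min_cluster_size: one cluster
  expect_equal(unique(cluster_by_projection(X[, 1:5], 10)), 1L)
})

test_that("cluster annotation assigns argmax or declares ambiguity", {
  proj <- rbind(A = c(2, 2, -1, -1, 0.5, 0.5),
                B = c(-1, -1, 2, 2, 0.4, 0.4),
                C = c(-1, -1, -1, -1, 0.45, 0.45))
  colnames(proj) <- paste0("c", 1:6)
  lab <- c(1, 1, 2, 2, 3, 3)
  ann <- annotate_clusters(proj, lab, z_min = 0.25, margin = 0.25)
  expect_equal(ann$type[ann$cluster == 1], "A")
  expect_equal(ann$type[ann$cluster == 2], "B")
  # cluster 3: three types tied within the margin
  expect_equal(ann$type[ann$cluster == 3], "ambiguous")
  expect_true(ann$ambiguous[ann$cluster == 3])
})

test_that("multiresolution annotation equals major annotation without subpanels", {
  h <- hierarchy_cohort(seed = 51, n_case = 3, n_control = 3,
                        cells_per_sample = 150)
  only_major <- panel_hierarchy(h$hier$major)
  lab1 <- multiresolution_annotate(h$g$cm, only_major)
  ne <- normalize_cells(h$g$cm)
  lab2 <- scmetaz:::project_annotate_once(ne, h$hier$major, 20, 0.25, 0.25)
  expect_identical(lab1, lab2)

  # full hierarchy: sub-labels are within the right compartment
  lab <- multiresolution_annotate(h$g$cm, h$hier)
  tt <- h$g$cm$cells$true_type
  ok <- lab != "ambiguous" & !h$g$cm$cells$doublet
  expect_gt(mean(lab[ok] == tt[ok]), 0.95)
})

test_that("panel hierarchy validates its structure", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("g1", "g2")))
  p <- reference_panel(m)
  expect_error(panel_hierarchy("x"), "ReferencePanel")
  expect_error(panel_hierarchy(p, subpanels = list(A = list(p))),
               "compartment_of")
})
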