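#' Reference panel of sorted bulk transcriptomes
#'
#' A panel is a cell types x feature genes matrix of log10 reference
#' expression, against which single cells are projected by correlation.
#'
#' @param mat numeric matrix, rows = cell types, columns = feature genes,
#'   both named; entries finite.
#' @param name panel name.
#' @param parent_compartment optional named character vector mapping each
#'   panel type to a higher-level compartment.
#' @return a `ReferencePanel` object.
#' @export
reference_panel <- function(mat, name = "panel", parent_compartment = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("panel rows must be uniquely named cell types")
  if (is.null(colnames(mat)) || ncol(mat) == 0)
    stop("panel must have a nonempty named feature-gene list")
  if (!all(is.finite(mat))) stop("panel entries must be finite")
  structure(list(name = name, mat = mat,
                 parent_compartment = parent_compartment),
            class = "ReferencePanel")
}

#' @exportS3Method base::print
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("ReferencePanel '%s': %d cell types x %d feature genes\n",
              x$name, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Depth-normalize and log-transform cells
#'
#' Per cell, counts are scaled to a fixed target depth (10,000 by
#' default) and natural-log1p transformed ("nlog" expression). This
#' documented replacement for a model-based normalization is
#' deterministic, exactly depth-invariant (rescaling any cell's counts,
#' or all counts globally, leaves the output unchanged) and monotone per
#' cell, which is all the downstream correlation projection requires.
#'
#' @param cm CellMatrix (nonnegative counts).
#' @param target depth every cell is scaled to (default 1e4).
#' @return sparse genes x cells matrix of normalized expression. All-zero
#'   cells come back as zero vectors with a warning.
#' @export
normalize_cells <- function(cm, target = 1e4) {
  stopifnot(inherits(cm, "CellMatrix"))
  depth <- Matrix::colSums(cm$counts)
  if (any(depth == 0)) warning(sum(depth == 0), " all-zero cell(s)")
  sf <- ifelse(depth > 0, target / depth, 0)
  x <- cm$counts %*% Matrix::Diagonal(x = sf)
  dimnames(x) <- dimnames(cm$counts)
  x@x <- log1p(x@x)
  x
}

#' Project cells onto a reference panel
#'
#' For every cell, the Pearson correlation between its normalized
#' expression and each panel row over the shared feature genes, sharpened
#' by a sign-preserving power (`sign(r) * |r|^power`) and then z-scored
#' within each panel row across cells.
#'
#' @param norm_expr genes x cells normalized matrix from
#'   [normalize_cells()].
#' @param panel a [reference_panel()].
#' @param power sharpening exponent (default 4).
#' @param z_rows apply the row-wise z-transform (default TRUE).
#' @return a `ProjectionMatrix`: cell types x cells score matrix with
#'   attributes `power`, `z_rows`, and `degenerate_cells` (cells whose
#'   expression is constant over the feature genes; their scores are NA).
#' @export
project_to_panel <- function(norm_expr, panel, power = 4L, z_rows = TRUE) {
  stopifnot(inherits(panel, "ReferencePanel"))
  shared <- intersect(colnames(panel$mat), rownames(norm_expr))
  if (length(shared) < 3)
    stop("fewer than 3 shared feature genes between cells and panel")
  E <- as.matrix(norm_expr[shared, , drop = FALSE])
  P <- panel$mat[, shared, drop = FALSE]          # types x genes
  # columnwise Pearson r between each cell and each panel row
  n <- length(shared)
  Ec <- sweep(E, 2, colMeans(E), "-")
  sdE <- sqrt(colSums(Ec^2))
  Pc <- P - rowMeans(P)
  sdP <- sqrt(rowSums(Pc^2))
  r <- (Pc %*% Ec) / (sdP %o% sdE)                # types x cells
  degen <- sdE == 0
  r[, degen] <- NA_real_
  r <- sign(r) * abs(r)^power
  if (z_rows) {
    mu <- rowMeans(r, na.rm = TRUE)
    sd <- apply(r, 1, stats::sd, na.rm = TRUE)
    flat <- !is.finite(sd) | sd == 0
    sd[flat] <- 1
    r <- (r - mu) / sd
    attr(r, "flat_rows") <- rownames(r)[flat]
  }
  structure(r, power = power, z_rows = z_rows,
            degenerate_cells = colnames(norm_expr)[degen],
            class = c("ProjectionMatrix", class(r)))
}

# mean silhouette width for a 2-way split on a precomputed distance matrix
mean_silhouette2 <- function(d, grp) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- grp == grp[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, !(grp == grp[i])])
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Cluster cells by their projection profiles
#'
#' Correlation-based distance (`1 - Pearson` between projection columns)
#' fed into average-linkage hierarchical clustering, cut by a
#' deterministic dynamic rule: a branch is split into its two dendrogram
#' children while both children have at least `min_cluster_size` cells
#' and the 2-way split has strictly positive mean silhouette width within
#' the branch. A fixed-k fallback is available via `k`.
#'
#' @param proj ProjectionMatrix (types x cells). Cells with NA scores are
#'   excluded and labelled NA.
#' @param min_cluster_size smallest admissible cluster (default 20).
#' @param k optional fixed number of clusters (bypasses the dynamic cut).
#' @return integer cluster labels named by cell, covering all projected
#'   cells.
#' @export
cluster_by_projection <- function(proj, min_cluster_size = 20L, k = NULL) {
  ok <- colSums(is.na(proj)) == 0
  X <- proj[, ok, drop = FALSE]
  n <- ncol(X)
  labels <- rep(NA_integer_, ncol(proj))
  names(labels) <- colnames(proj)
  if (n < 2 || n < min_cluster_size) {
    labels[ok] <- 1L
    return(labels)
  }
  sd0 <- apply(X, 2, stats::sd)
  cr <- suppressWarnings(stats::cor(X))
  cr[!is.finite(cr)] <- 0                 # zero-variance columns: no signal
  diag(cr) <- 1
  d <- stats::as.dist(1 - cr)
  hc <- stats::hclust(d, method = "average")
  if (!is.null(k)) {
    labels[ok] <- stats::cutree(hc, k = min(k, n))
    return(labels)
  }
  dm <- as.matrix(d)
  # leaf memberships of every merge node, built iteratively (no deep recursion)
  memb <- vector("list", nrow(hc$merge))
  for (j in seq_len(nrow(hc$merge))) {
    l <- hc$merge[j, 1]; r <- hc$merge[j, 2]
    memb[[j]] <- c(if (l < 0) -l else memb[[l]], if (r < 0) -r else memb[[r]])
  }
  node_members <- function(nd) if (nd < 0) -nd else memb[[nd]]
  # recursive dynamic cut on the dendrogram merge structure
  split_rec <- function(idx, node) {
    # node: row of hc$merge (negative = leaf); returns labels within idx
    if (node < 0) return(rep(1L, length(idx)))
    left <- node_members(hc$merge[node, 1])
    right <- node_members(hc$merge[node, 2])
    if (length(left) < min_cluster_size || length(right) < min_cluster_size)
      return(stats::setNames(rep(1L, length(idx)), idx))
    grp <- stats::setNames(c(rep(1L, length(left)), rep(2L, length(right))),
                           c(left, right))[as.character(idx)]
    if (mean_silhouette2(dm[idx, idx, drop = FALSE], grp) <= 0)
      return(stats::setNames(rep(1L, length(idx)), idx))
    l1 <- split_rec(left, hc$merge[node, 1])
    l2 <- split_rec(right, hc$merge[node, 2])
    out <- stats::setNames(integer(length(idx)), idx)
    out[as.character(left)] <- l1
    out[as.character(right)] <- l2 + max(l1)
    out
  }
  res <- split_rec(seq_len(n), nrow(hc$merge))
  assign <- res[as.character(seq_len(n))]
  labels[which(ok)] <- as.integer(assign)
  labels
}

#' Annotate clusters by their panel scores
#'
#' Per cluster, the mean projection z-score per panel type; the argmax
#' type is assigned when its mean score reaches `z_min` and beats the
#' runner-up by at least `margin`; otherwise the cluster is "ambiguous"
#' (no correlation, or strong correlation with more than one type) and
#' its cells are meant to be excluded downstream.
#'
#' @param proj ProjectionMatrix.
#' @param labels cluster labels from [cluster_by_projection()].
#' @param z_min minimum mean z-score for an assignment (default 0.25).
#' @param margin minimum lead over the second-best type (default 0.25).
#' @return data.frame per cluster: `cluster`, `type`, `score`, `margin`,
#'   `ambiguous`.
#' @export
annotate_clusters <- function(proj, labels, z_min = 0.25, margin = 0.25) {
  cl <- sort(unique(labels[!is.na(labels)]))
  out <- lapply(cl, function(g) {
    m <- rowMeans(proj[, which(labels == g), drop = FALSE], na.rm = TRUE)
    o <- order(m, decreasing = TRUE)
    best <- m[o[1]]
    second <- if (length(m) > 1) m[o[2]] else -Inf
    amb <- !(best >= z_min && (best - second) >= margin)
    data.frame(cluster = g,
               type = if (amb) "ambiguous" else names(m)[o[1]],
               score = best, margin = best - second, ambiguous = amb)
  })
  do.call(rbind, out)
}

#' Panel hierarchy for multi-resolution annotation
#'
#' @param major major [reference_panel()].
#' @param compartment_of named character vector mapping each major panel
#'   type to a compartment name (types without an entry are terminal).
#' @param subpanels named list: compartment -> ordered list of
#'   [reference_panel()]s applied sequentially.
#' @return a `PanelHierarchy` object.
#' @export
panel_hierarchy <- function(major, compartment_of = NULL, subpanels = list()) {
  stopifnot(inherits(major, "ReferencePanel"))
  for (ps in subpanels) for (p in ps)
    if (!inherits(p, "ReferencePanel")) stop("subpanels must be ReferencePanels")
  if (length(subpanels) && is.null(compartment_of))
    stop("compartment_of required when subpanels are given")
  if (any(names(subpanels) %in%
          unlist(lapply(subpanels, function(ps) lapply(ps, function(p) rownames(p$mat))))))
    stop("configuration error: cycle in panel hierarchy")
  structure(list(major = major, compartment_of = compartment_of,
                 subpanels = subpanels), class = "PanelHierarchy")
}

project_annotate_once <- function(norm_expr, panel, min_cluster_size,
                                  z_min, margin) {
  proj <- project_to_panel(norm_expr, panel)
  labels <- cluster_by_projection(proj, min_cluster_size = min_cluster_size)
  ann <- annotate_clusters(proj, labels, z_min = z_min, margin = margin)
  type <- stats::setNames(ann$type, ann$cluster)[as.character(labels)]
  type[is.na(labels)] <- "ambiguous"
  stats::setNames(type, colnames(norm_expr))
}

#' Multi-resolution cell-type annotation
#'
#' Projects, clusters and annotates all cells with the major panel; cells
#' of each compartment that has subpanels are then re-clustered against
#' that compartment's panels in order. Cells assigned with confidence by
#' an earlier subpanel are fixed; the remaining (ambiguous) cells are
#' passed to the next subpanel, mirroring sequential fine-typing of the
#' T-cell compartment. Cells of ambiguous major clusters are never
#' sub-annotated.
#'
#' @param cm CellMatrix.
#' @param hierarchy a [panel_hierarchy()].
#' @param min_cluster_size,z_min,margin passed to the clustering and
#'   annotation steps.
#' @return character vector of final per-cell type labels (named by
#'   barcode); unresolved cells are "ambiguous".
#' @export
multiresolution_annotate <- function(cm, hierarchy, min_cluster_size = 20L,
                                     z_min = 0.25, margin = 0.25) {
  stopifnot(inherits(hierarchy, "PanelHierarchy"))
  ne <- normalize_cells(cm)
  final <- project_annotate_once(ne, hierarchy$major, min_cluster_size,
                                 z_min, margin)
  if (!length(hierarchy$subpanels)) return(final)
  comp <- hierarchy$compartment_of
  for (cp in names(hierarchy$subpanels)) {
    members <- names(comp)[comp == cp]
    in_comp <- which(final %in% members)
    if (!length(in_comp)) next
    pending <- in_comp
    for (panel in hierarchy$subpanels[[cp]]) {
      if (!length(pending)) break
      sub <- project_annotate_once(ne[, pending, drop = FALSE], panel,
                                   min_cluster_size, z_min, margin)
      assigned <- sub != "ambiguous"
      final[pending[assigned]] <- sub[assigned]
      pending <- pending[!assigned]
    }
    final[pending] <- "ambiguous"
  }
  final
}
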