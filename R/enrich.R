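#' Gene-set collection
#'
#' Named gene sets over a declared universe, with size bounds used to
#' skip very small or very large sets during enrichment.
#'
#' @param sets named list of gene-identifier vectors.
#' @param universe gene universe; every set is intersected with it.
#' @param min_size,max_size inclusive size bounds (defaults 10 and 500).
#' @return a `GeneSetCollection` list.
#' @export
gene_set_collection <- function(sets, universe, min_size = 10L,
                                max_size = 500L) {
  stopifnot(is.list(sets), length(universe) > 0, min_size > 0,
            max_size >= min_size)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  structure(list(sets = sets, universe = unique(universe),
                 min_size = min_size, max_size = max_size),
            class = "GeneSetCollection")
}

#' k-means modules of DEG fold-change profiles
#'
#' Clusters DEGs by their per-cell-type log2 fold-change vectors with
#' multi-restart k-means (best inertia kept). Genes untested in a cell
#' type are imputed 0 (missing = no evidence of change) before
#' clustering.
#'
#' @param lfc_matrix DEGs x cell types numeric matrix (NAs allowed).
#' @param k number of modules (default 8).
#' @param restarts number of k-means restarts (default 25).
#' @param seed integer seed.
#' @return list: `modules` (named integer labels), `centers` (module mean
#'   profiles), `inertia` (total within-cluster sum of squares).
#' @export
kmeans_deg_modules <- function(lfc_matrix, k = 8L, restarts = 25L, seed = 1L) {
  if (k <= 1) stop("k must be at least 2")
  if (k >= nrow(lfc_matrix)) stop("k must be smaller than the number of DEGs")
  X <- as.matrix(lfc_matrix)
  X[is.na(X)] <- 0
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  list(modules = stats::setNames(km$cluster, rownames(X)),
       centers = km$centers, inertia = km$tot.withinss)
}

# exact one-sided (enrichment) hypergeometric tail: P[X >= x] where
# X ~ Hypergeom(N, |A|, |B|)
hyper_tail_p <- function(overlap, size_a, size_b, n_universe) {
  hi <- min(size_a, size_b)
  if (overlap > hi) return(0)
  sum(stats::dhyper(overlap:hi, size_a, n_universe - size_a, size_b))
}

#' Fisher exact overlap test between gene sets
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 membership table
#' of two sets within a universe, computed as the exact hypergeometric
#' upper tail, with BH correction across all requested pairs.
#'
#' @param pairs list of `list(a = , b = )` gene-set pairs, or a single
#'   pair given via `a`/`b`.
#' @param a,b convenience single-pair interface.
#' @param universe gene universe (sets are intersected with it first).
#' @return data.frame per pair: sizes, `overlap`, `odds_ratio`, `p`, `q`.
#' @export
overlap_test <- function(pairs = NULL, a = NULL, b = NULL, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (is.null(pairs)) pairs <- list(list(a = a, b = b))
  rows <- lapply(seq_along(pairs), function(i) {
    A <- unique(intersect(pairs[[i]]$a, universe))
    B <- unique(intersect(pairs[[i]]$b, universe))
    x <- length(intersect(A, B))
    N <- length(universe)
    # 2x2: [x, |A|-x; |B|-x, N-|A|-|B|+x]
    or_num <- x * (N - length(A) - length(B) + x)
    or_den <- (length(A) - x) * (length(B) - x)
    data.frame(pair = if (!is.null(names(pairs)[i]) && nzchar(names(pairs)[i]))
                 names(pairs)[i] else paste0("pair", i),
               size_a = length(A), size_b = length(B), overlap = x,
               odds_ratio = if (or_den > 0) or_num / or_den else Inf,
               p = hyper_tail_p(x, length(A), length(B), N))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Over-representation analysis
#'
#' Hypergeometric upper-tail test of a query gene set against every set
#' of a collection within its size bounds, BH-corrected.
#'
#' @param query_set gene identifiers (subset of the universe).
#' @param collection a [gene_set_collection()].
#' @return data.frame per tested set: `set`, `set_size`, `overlap`, `p`,
#'   `q`; sets outside the size bounds are skipped.
#' @export
ora <- function(query_set, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(intersect(query_set, collection$universe))
  if (!length(query)) stop("empty query set")
  N <- length(collection$universe)
  sz <- lengths(collection$sets)
  keep <- sz >= collection$min_size & sz <= collection$max_size
  rows <- lapply(names(collection$sets)[keep], function(nm) {
    S <- collection$sets[[nm]]
    x <- length(intersect(query, S))
    data.frame(set = nm, set_size = length(S), overlap = x,
               p = hyper_tail_p(x, length(query), length(S), N))
  })
  if (!length(rows)) return(data.frame(set = character(), set_size = integer(),
                                       overlap = integer(), p = numeric(),
                                       q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# unweighted (exponent 0) GSEA enrichment score for one set on a ranked
# gene vector: +1/|S| at hits, -1/(N-|S|) at misses; ES = running-sum
# value of maximal absolute deviation. A set covering the whole list has
# no misses; the sum climbs monotonically to 1 and ES = 1 by convention.
gsea_es <- function(ranked_genes, set) {
  hit <- ranked_genes %in% set
  n_hit <- sum(hit)
  n_miss <- length(ranked_genes) - n_hit
  step <- ifelse(hit, 1 / n_hit, if (n_miss > 0) -1 / n_miss else 0)
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Unweighted preranked gene set enrichment analysis
#'
#' Genes are ranked by a signed score (descending); with exponent 0 the
#' running sum increments `1/|S|` at set members and decrements
#' `1/(N-|S|)` otherwise, and the enrichment score (ES) is the signed
#' maximal deviation. Significance comes from a gene-label permutation
#' null; `NES = ES / mean |null ES of matching sign|`; BH across sets.
#'
#' @param scores named numeric vector of signed gene scores (no
#'   duplicated names); e.g. `sign(lfc) * DES`.
#' @param collection a [gene_set_collection()] (its `min_size`/`max_size`
#'   bound the tested sets after intersection with the ranking).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
preranked_gsea <- function(scores, collection, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (anyDuplicated(names(scores))) stop("duplicate genes in ranking")
  ranked <- names(sort(scores, decreasing = TRUE))
  set.seed(seed)
  sets <- lapply(collection$sets, intersect, ranked)
  sz <- lengths(sets)
  keep <- sz >= collection$min_size & sz <= collection$max_size
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric()))
  es <- vapply(sets, function(s) gsea_es(ranked, s), numeric(1))
  # permutation null per distinct set size (gene-label permutation)
  null_by_size <- list()
  for (m in unique(lengths(sets))) {
    null_by_size[[as.character(m)]] <- vapply(seq_len(n_perm), function(i)
      gsea_es(ranked, sample(ranked, m)), numeric(1))
  }
  p <- nes <- numeric(length(sets))
  for (i in seq_along(sets)) {
    nl <- null_by_size[[as.character(length(sets[[i]]))]]
    same <- nl[sign(nl) == sign(es[i])]
    if (!length(same)) same <- abs(nl)
    nes[i] <- es[i] / mean(abs(same))
    p[i] <- (1 + sum(abs(nl) >= abs(es[i]))) / (1 + length(nl))
  }
  out <- data.frame(set = names(sets), size = lengths(sets), es = es,
                    nes = nes, p = p, q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  out
}

#' Jaccard similarity between sets of a collection
#'
#' Companion to the enrichment tables for spotting redundant terms (no
#' pruning is applied; all terms are reported).
#'
#' @param collection a [gene_set_collection()].
#' @return symmetric matrix of Jaccard similarities.
#' @export
set_jaccard <- function(collection) {
  s <- collection$sets
  n <- length(s)
  J <- matrix(1, n, n, dimnames = list(names(s), names(s)))
  if (n < 2) return(J)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    J[i, j] <- J[j, i] <-
      length(intersect(s[[i]], s[[j]])) / max(length(union(s[[i]], s[[j]])), 1)
  }
  J
}
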