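#' Per-molecule trajectory feature matrix
#'
#' The minimal space in which the ten trajectory clusters are geometrically
#' separable: each molecule's three contrast log2 fold changes
#' (S1, S2, S3). Molecules with any non-finite fold change are dropped.
#'
#' @param contrasts data.frame from [run_contrasts()].
#' @param standardize z-score each feature column.
#' @return numeric matrix, molecules x 3, with a `standardized` attribute.
#' @export
contrast_features <- function(contrasts, standardize = FALSE) {
  cts <- attr(contrasts, "conditions")
  order_ <- if (!is.null(cts)) .contrast_names(cts) else unique(contrasts$contrast)
  ids <- unique(contrasts$molecule_id)
  f <- vapply(order_, function(ct) {
    sub <- contrasts[contrasts$contrast == ct, ]
    sub$log2fc[match(ids, sub$molecule_id)]
  }, numeric(length(ids)))
  rownames(f) <- ids
  colnames(f) <- c("log2fc_S1", "log2fc_S2", "log2fc_S3")
  f <- f[rowSums(!is.finite(f)) == 0, , drop = FALSE]
  if (standardize) f <- scale(f)
  attr(f, "standardized") <- standardize
  f
}

#' k-means over trajectory features
#'
#' Lloyd's algorithm with k-means++-style seeding (first center uniform,
#' subsequent centers with probability proportional to squared distance from
#' the nearest chosen center), best of `restarts` runs by total
#' within-cluster sum of squares. An emptied cluster is reseeded at the point
#' farthest from its assigned center. Deterministic given `seed`.
#'
#' @param features numeric matrix (rows = items).
#' @param k number of clusters (default 10, the size of the supervised
#'   trajectory taxonomy); must not exceed the number of rows.
#' @param seed integer RNG seed.
#' @param restarts independent initializations.
#' @param max_iter Lloyd iteration cap per run.
#' @return list with `labels` (integer vector named by rownames), `centers`
#'   (k x p matrix) and `tot_withinss`.
#' @export
kmeans_features <- function(features, k = 10L, seed = 1L, restarts = 10L,
                            max_iter = 100L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds number of items ", n)
  if (k < 1) stop("k must be >= 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  names(best$labels) <- rownames(x)
  best
}

.sq_dist_to <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, `+`) - 2 * x %*% t(centers)
}

.lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- pmax(0, apply(.sq_dist_to(x, centers), 1, min))
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, x[sample.int(n, 1, prob = prob), ])
  }
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- .sq_dist_to(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    dvec <- d2[cbind(seq_len(n), new_labels)]
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        # reseed emptied cluster at the point farthest from its center
        far <- which.max(dvec)
        new_labels[far] <- j
        dvec[far] <- -Inf
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k))
      if (any(labels == j))
        centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  d2 <- .sq_dist_to(x, centers)
  list(labels = labels, centers = centers,
       tot_withinss = sum(pmax(0, d2[cbind(seq_len(nrow(x)), labels)])))
}

#' Hierarchical complete-linkage clustering of samples
#'
#' Euclidean distance between samples over the `n_top` highest-variance
#' molecules, agglomerated with complete linkage (inter-cluster distance =
#' maximum pairwise distance). Cutting the tree at `k` = number of
#' conditions shows which conditions' samples are most concordant.
#'
#' @param x an `ExpressionMatrix`.
#' @param k number of flat clusters to cut; defaults to the number of
#'   conditions.
#' @param n_top use only the `n_top` highest-variance molecules (all if
#'   fewer).
#' @return list with `hclust` (a [stats::hclust] tree), `labels` (cut
#'   assignment per sample) and `condition_of`.
#' @export
hclust_samples <- function(x, k = NULL, n_top = 500L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2) stop("need at least 2 samples")
  v <- x$values
  if (nrow(v) > n_top) {
    rv <- apply(v, 1, var)
    v <- v[order(-rv)[seq_len(n_top)], , drop = FALSE]
  }
  hc <- hclust(dist(t(v), method = "euclidean"), method = "complete")
  if (is.null(k)) k <- length(conditions_of(x))
  list(hclust = hc, labels = cutree(hc, k = k), condition_of = x$condition_of)
}

#' Export a dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items under
#' the permutation model: 1 for identical partitions (up to relabeling),
#' approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("labelings differ in length: ", length(a), " vs ", length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
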