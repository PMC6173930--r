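#' Dendrogram container
#'
#' Stores an agglomerative clustering result in `hclust`-style encoding:
#' `merge` is an (n-1) x 2 matrix whose negative entries are leaves and
#' positive entries earlier merge steps, `height` the merge heights
#' (non-decreasing for complete linkage), and `support` an optional
#' per-internal-node table of bootstrap probabilities (BP) and
#' approximately unbiased (AU) p-values.
#'
#' @param labels Character leaf labels.
#' @param merge Integer merge matrix.
#' @param height Numeric merge heights.
#' @param support Optional data.frame with at least columns `node`, `bp`,
#'   `au`.
#' @param method Linkage name (informational).
#' @param dist Distance name (informational).
#' @return An object of class `cluster_tree`.
#' @export
cluster_tree <- function(labels, merge, height, support = NULL,
                         method = "complete", dist = "correlation") {
  n <- length(labels)
  if (n < 2) stopf("a tree needs at least 2 leaves")
  if (!is.matrix(merge) || nrow(merge) != n - 1 || ncol(merge) != 2)
    stopf("`merge` must be an (n-1) x 2 matrix")
  if (length(height) != n - 1) stopf("`height` must have n-1 entries")
  structure(list(labels = as.character(labels), merge = merge,
                 height = as.numeric(height), support = support,
                 method = method, dist = dist),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, %s linkage on %s distance\n",
              length(x$labels), x$method, x$dist))
  if (!is.null(x$support))
    cat(sprintf("  support annotated on %d internal node(s)\n",
                sum(!is.na(x$support$bp))))
  invisible(x)
}

#' Convert a cluster tree to a base-R `hclust` object
#'
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @return An `hclust` object (usable with `plot()`, `cutree()`, ...).
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(x$merge[node, 1]), leaf_order(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(nrow(x$merge)), labels = x$labels,
                 method = x$method, dist.method = x$dist,
                 call = match.call()),
            class = "hclust")
}

#' List the leaf set of every internal node
#'
#' The root clade (all leaves) is included last; singleton leaves are not
#' clades.
#'
#' @param tree A `cluster_tree`.
#' @return A list of sorted character vectors, one per internal node, in
#'   merge order.
#' @export
clades <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  out <- vector("list", nrow(tree$merge))
  for (step in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[step, ]
    members <- unlist(lapply(kids, function(k)
      if (k < 0) tree$labels[-k] else out[[k]]))
    out[[step]] <- sort(members)
  }
  out
}

#' Pearson correlation distance between two profiles
#'
#' `d = 1 - cor(x, y)`, in `[0, 2]`. Constant (zero-variance) profiles have
#' no defined correlation and are rejected; callers must pre-filter them.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A number in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stopf("profiles must have equal length")
  if (length(x) < 3) stopf("profiles must have length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation distance undefined for constant profiles; pre-filter zero-variance rows")
  1 - cor(x, y)
}

# Correlation-distance matrix between the rows of `profiles`
# (items x features); errors listing zero-variance items.
correlation_distance_matrix <- function(profiles) {
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0))
    stopf("zero-variance item(s): %s",
          paste(rownames(profiles)[sds == 0], collapse = ", "))
  1 - cor(t(profiles))
}

# Extract the item x feature profile matrix for a clustering axis.
axis_profiles <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  values <- if (inherits(x, "ExpressionMatrix")) x$values else x
  if (!is.matrix(values)) stopf("`x` must be a matrix or ExpressionMatrix")
  if (axis == "samples") t(values) else values
}

#' Agglomerative complete-linkage clustering with correlation distance
#'
#' Merges the closest pair of clusters at each step, with the
#' complete-linkage (maximum) update; merge height is the largest pairwise
#' distance between the joined clusters, so heights are non-decreasing and
#' the result is ultrametric. Ties are broken deterministically in favour
#' of the lowest-index pair, which makes the tree invariant to the input
#' order of the leaves.
#'
#' @param x An [expression_matrix()] or plain numeric matrix (genes x
#'   samples).
#' @param axis Cluster `"samples"` (columns) or `"genes"` (rows).
#' @return A `cluster_tree`.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  profiles <- axis_profiles(x, axis)
  n <- nrow(profiles)
  if (n < 2) stopf("need at least 2 items to cluster")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("item", seq_len(n))
  d <- correlation_distance_matrix(profiles)
  complete_linkage(d, rownames(profiles))
}

# Lance-Williams complete-linkage agglomeration on a distance matrix.
# Tie rule: among equal-distance pairs choose the one with the smallest
# first (then second) active-slot index, slots being ordered by the
# original item order and, after a merge, by the slot of the first member.
complete_linkage <- function(d, labels) {
  n <- nrow(d)
  active <- rep(TRUE, n)
  code <- -seq_len(n)            # slot -> hclust merge code
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(d) <- Inf
  d[lower.tri(d)] <- Inf         # keep upper triangle (i < j) only
  for (step in seq_len(n - 1)) {
    dmin <- min(d[active, active, drop = FALSE][is.finite(d[active, active, drop = FALSE])])
    hit <- which(d == dmin & outer(active, active, "&"), arr.ind = TRUE)
    # lowest-index pair first
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- dmin
    # complete linkage: new cluster lives in slot i
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    for (k in others) {
      dik <- if (i < k) d[i, k] else d[k, i]
      djk <- if (j < k) d[j, k] else d[k, j]
      dnew <- max(dik, djk)
      if (i < k) d[i, k] <- dnew else d[k, i] <- dnew
    }
    active[j] <- FALSE
    code[i] <- step
  }
  cluster_tree(labels = labels, merge = merge, height = height)
}

#' k-means clustering of temporal expression profiles
#'
#' Profiles are z-scored per gene (so clustering captures temporal shape,
#' not level), then partitioned with Lloyd's algorithm on Euclidean
#' distance; the best of `n_restarts` random initialisations by total
#' within-cluster sum of squares is returned. If an initialisation
#' collapses to an empty cluster it is retried with a farthest-point
#' initialisation. Fully reproducible given `seed`.
#'
#' @param x An [expression_matrix()] or numeric matrix, genes in rows.
#' @param k Number of clusters (>= 1, <= number of genes).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts.
#' @return A list of class `kmeans_profiles`: `labels` (named integer
#'   vector), `centroids` (k x timepoints), `withinss` (total), `k`,
#'   `seed`, `n_restarts`.
#' @export
kmeans_profiles <- function(x, k, seed = 1L, n_restarts = 10L) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else x
  if (!is_count(k) || k > nrow(values)) stopf("`k` must be in 1..n_genes")
  sds <- apply(values, 1, sd)
  if (any(sds == 0))
    stopf("zero-variance gene profile(s): %s",
          paste(head(rownames(values)[sds == 0], 5), collapse = ", "))
  z <- (values - rowMeans(values)) / sds
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- z[sample.int(nrow(z), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(kmeans(z, centers = centers, iter.max = 200,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) {
        # empty cluster: deterministic farthest-point initialisation
        centers <- farthest_point_init(z, k)
        fit <- tryCatch(
          suppressWarnings(kmeans(z, centers = centers, iter.max = 200,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(fit)) next
        message("kmeans_profiles: empty cluster, re-seeded by farthest point")
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stopf("k-means failed for every restart")
  labels <- setNames(as.integer(best$cluster), rownames(z))
  structure(list(labels = labels, centroids = best$centers,
                 withinss = best$tot.withinss, k = k, seed = seed,
                 n_restarts = n_restarts),
            class = "kmeans_profiles")
}

farthest_point_init <- function(z, k) {
  idx <- which.max(rowSums(z^2))
  for (j in seq_len(k - 1)) {
    dmin <- rep(Inf, nrow(z))
    for (i in idx)
      dmin <- pmin(dmin, rowSums(sweep(z, 2, z[i, ])^2))
    idx <- c(idx, which.max(dmin))
  }
  z[idx, , drop = FALSE]
}
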