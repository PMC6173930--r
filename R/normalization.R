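#' log2 transform of non-negative expression values
#'
#' `log2(x + pseudocount)`. Only valid on raw-scale matrices; applying it
#' twice, or to negative values, is an error.
#'
#' @param mat A raw-scale [expression_matrix()].
#' @param pseudocount Non-negative pseudocount, default 1.
#' @return The matrix on `log` scale.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$scale != "raw")
    stopf("log_transform expects raw-scale input, got '%s'", mat$scale)
  if (any(mat$values < 0)) stopf("negative values cannot be log-transformed")
  if (pseudocount < 0) stopf("`pseudocount` must be >= 0")
  out <- mat
  out$values <- log2(mat$values + pseudocount)
  out$scale <- "log"
  out$steps <- c(mat$steps, sprintf("log(pseudocount=%g)", pseudocount))
  out
}

#' Per-sample background correction by low-quantile subtraction
#'
#' Subtracts each sample's `quantile` value (default the 5th percentile,
#' computed with the linear-interpolation estimator, `type = 7`) from all
#' of that sample's entries. This aligns the platform floors of count- and
#' intensity-derived log data without distorting within-sample rank order;
#' no clipping is applied because centering follows in the chain.
#'
#' @param mat A log-scale [expression_matrix()].
#' @param q Quantile in (0, 1), default 0.05.
#' @return The corrected matrix (still `log` scale).
#' @export
background_correct <- function(mat, q = 0.05) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$scale != "log")
    stopf("background_correct expects log-scale input, got '%s'", mat$scale)
  if (any(grepl("^center", mat$steps)))
    stopf("background correction must precede centering")
  if (!(is.numeric(q) && q > 0 && q < 1)) stopf("`q` must be in (0, 1)")
  floors <- apply(mat$values, 2, quantile, probs = q, names = FALSE, type = 7)
  out <- mat
  out$values <- sweep(mat$values, 2, floors)
  out$steps <- c(mat$steps, sprintf("background(q=%g)", q))
  out
}

#' Center every sample (column) on mean zero
#'
#' Aligns the distributions of samples from different platforms; the
#' operation is idempotent.
#'
#' @param mat A log-scale [expression_matrix()].
#' @return The matrix with all column means 0.
#' @export
center_samples <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!mat$scale %in% c("log"))
    stopf("center_samples expects log-scale input, got '%s'", mat$scale)
  out <- mat
  out$values <- sweep(mat$values, 2, colMeans(mat$values))
  if (!"center_samples" %in% out$steps)
    out$steps <- c(out$steps, "center_samples")
  out
}

#' Center every gene on mean zero within each species
#'
#' The cross-platform step: expression of each gene is centered on its
#' mean independently in each species, removing platform- and
#' species-level location so only temporal variation remains. Idempotent.
#' A species with a single sample would be forced to all-zero and is
#' rejected.
#'
#' @param mat A log-scale (or already `log_centered`) [expression_matrix()].
#' @param per_species If `FALSE`, genes are centered on their mean across
#'   *all* samples instead; constant species-level offsets then survive,
#'   which is what a species-axis principal component analysis needs.
#' @return The matrix on `log_centered` scale.
#' @export
center_genes_by_species <- function(mat, per_species = TRUE) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!mat$scale %in% c("log", "log_centered"))
    stopf("center_genes_by_species expects log-scale input, got '%s'", mat$scale)
  groups <- if (per_species) mat$samples$species else rep("all", n_samples(mat))
  out <- mat
  for (sp in unique(groups)) {
    idx <- which(groups == sp)
    if (length(idx) < 2)
      stopf("species '%s' has < 2 samples; centering a singleton is degenerate", sp)
    out$values[, idx] <- mat$values[, idx, drop = FALSE] -
      rowMeans(mat$values[, idx, drop = FALSE])
  }
  out$scale <- "log_centered"
  step <- if (per_species) "center_genes_by_species" else "center_genes_global"
  if (!step %in% out$steps) out$steps <- c(out$steps, step)
  out
}

#' Average replicate samples within groups
#'
#' Collapses each replicate group to the arithmetic mean of its member
#' columns; metadata is collapsed to a group representative (the first
#' member) with the group name as sample identifier. Groups appear in
#' first-occurrence order, so singleton groups leave the matrix unchanged.
#'
#' @param mat An [expression_matrix()] at any scale.
#' @param group_key Metadata column defining the groups, default
#'   `"replicate_group"`.
#' @return The averaged matrix (one column per group).
#' @export
average_replicates <- function(mat, group_key = "replicate_group") {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!nzchar(group_key) || !group_key %in% names(mat$samples))
    stopf("`group_key` must name a metadata column")
  groups <- as.character(mat$samples[[group_key]])
  if (any(is.na(groups) | !nzchar(groups)))
    stopf("every sample needs a non-empty '%s'", group_key)
  uniq <- unique(groups)
  vals <- vapply(uniq, function(g)
    rowMeans(mat$values[, groups == g, drop = FALSE]),
    numeric(n_genes(mat)))
  dimnames(vals) <- list(rownames(mat$values), uniq)
  meta <- mat$samples[match(uniq, groups), , drop = FALSE]
  meta$sample_id <- uniq
  out <- expression_matrix(vals, meta, scale = mat$scale,
                           species_tag = mat$species_tag,
                           steps = c(mat$steps, sprintf("average_replicates(%s)", group_key)))
  out
}
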