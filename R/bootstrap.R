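#' Multiscale bootstrap support (BP and AU) for a dendrogram
#'
#' Clusters the chosen axis of `x`, then for every scale `r` draws `n_boot`
#' bootstrap datasets by resampling `round(r * n_features)` features (the
#' non-clustered axis) with replacement and re-clustering. For every
#' internal clade of the original tree the fraction of replicates in which
#' the identical leaf set reappears is the bootstrap probability at that
#' scale (`BP_r`); the approximately unbiased p-value (AU) comes from the
#' two-parameter normal-quantile curve fit of [au_from_bp_curve()]. BP is
#' reported at r = 1.
#'
#' The replicate index stream is fully determined by
#' `substream_seed(seed, sprintf("boot-%02d", scale_index), replicate)`,
#' so streams are independent across scales and any single replicate can be
#' regenerated in isolation. Items that become constant within a replicate
#' (zero variance over the resampled features) are dropped for that
#' replicate only; the root clade (all leaves) is trivially supported and
#' is excluded from the support table.
#'
#' @param x An [expression_matrix()] or numeric matrix (genes x samples).
#' @param axis Cluster `"samples"` (resampling genes) or `"genes"`
#'   (resampling samples).
#' @param scales Numeric vector of resampling scales; must include 1.
#' @param n_boot Bootstrap replicates per scale (>= 100).
#' @param seed Integer seed.
#' @return The original `cluster_tree` with a `support` data.frame
#'   (`node`, `leafset`, `bp`, `au`, `v`, `c`, `degenerate`) and a
#'   `bp_by_scale` matrix attached.
#' @export
multiscale_bootstrap_support <- function(x, axis = c("samples", "genes"),
                                         scales = seq(0.5, 1.4, by = 0.1),
                                         n_boot = 1000L, seed = 1L) {
  axis <- match.arg(axis)
  if (!any(abs(scales - 1) < 1e-12)) stopf("`scales` must include 1.0")
  if (n_boot < 100) stopf("`n_boot` must be >= 100")
  profiles <- axis_profiles(x, axis) # items x features
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("item", seq_len(nrow(profiles)))
  tree <- complete_linkage(correlation_distance_matrix(profiles),
                           rownames(profiles))
  n_feat <- ncol(profiles)
  cl <- clades(tree)
  root <- length(cl)
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  counts <- matrix(0, nrow = length(cl), ncol = length(scales),
                   dimnames = list(NULL, sprintf("r=%g", scales)))
  for (si in seq_along(scales)) {
    m <- max(2L, as.integer(round(scales[si] * n_feat)))
    stream <- sprintf("boot-%02d", si)
    for (b in seq_len(n_boot)) {
      idx <- with_seed(substream_seed(seed, stream, b),
                       sample.int(n_feat, m, replace = TRUE))
      sub <- profiles[, idx, drop = FALSE]
      sds <- apply(sub, 1, sd)
      keep <- sds > 0
      if (sum(keep) < 2) next
      bt <- complete_linkage(1 - cor(t(sub[keep, , drop = FALSE])),
                             rownames(profiles)[keep])
      bkeys <- vapply(clades(bt), paste, character(1), collapse = "\r")
      counts[, si] <- counts[, si] + (keys %in% bkeys)
    }
  }
  bp_by_scale <- counts / n_boot
  at1 <- which(abs(scales - 1) < 1e-12)[1]
  fits <- lapply(seq_along(cl), function(i)
    au_from_bp_curve(bp_by_scale[i, ], scales, n_boot))
  support <- data.frame(
    node = seq_along(cl),
    leafset = vapply(cl, paste, character(1), collapse = ","),
    bp = bp_by_scale[, at1],
    au = vapply(fits, `[[`, numeric(1), "au"),
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
  never <- rowSums(counts) == 0
  if (any(never & seq_along(cl) != root))
    message(sprintf(
      "multiscale_bootstrap_support: %d clade(s) never observed at any scale (AU = 0)",
      sum(never & seq_along(cl) != root)))
  support <- support[support$node != root, , drop = FALSE]
  tree$support <- support
  attr(tree, "bp_by_scale") <- bp_by_scale
  attr(tree, "scales") <- scales
  attr(tree, "n_boot") <- n_boot
  attr(tree, "seed") <- seed
  tree
}

#' Fit the multiscale-bootstrap curve and return the AU p-value
#'
#' For clade bootstrap probabilities observed at several resampling scales
#' `r`, the normal-quantile transform `psi_r = qnorm(1 - BP_r)` is modelled
#' as psi_r = v * sqrt(r) + c / sqrt(r); `v` estimates the signed
#' distance of the data from the clade boundary and `c` its curvature. The
#' model is fitted by weighted least squares with binomial variance
#' weights `n_boot * dnorm(psi)^2 / (BP (1 - BP))`, after clipping BP to
#' `[1/(n_boot+1), 1 - 1/(n_boot+1)]`. Then `AU = 1 - pnorm(v - c)` and
#' the model's BP at r = 1 is `1 - pnorm(v + c)`.
#'
#' Scales whose raw BP is exactly 0 or 1 carry no quantile information and
#' are excluded from the fit; with fewer than two usable distinct scales
#' the fit is flagged degenerate and AU falls back to the (clipped) BP at
#' r = 1, so a clade recovered in every replicate has AU = 1 and a clade
#' never recovered has AU = 0.
#'
#' @param bp Numeric vector of bootstrap probabilities, one per scale.
#' @param scales Numeric vector of scales (same length), including 1.
#' @param n_boot Number of bootstrap replicates behind each BP.
#' @return A list: `au`, `bp_model` (model BP at r = 1), `v`, `c`,
#'   `degenerate`.
#' @export
au_from_bp_curve <- function(bp, scales, n_boot) {
  stopifnot(length(bp) == length(scales))
  if (any(bp < 0 | bp > 1)) stopf("BP values must be in [0, 1]")
  at1 <- which(abs(scales - 1) < 1e-12)
  if (!length(at1)) stopf("`scales` must include 1.0")
  eps <- 1 / (n_boot + 1)
  usable <- which(bp > 0 & bp < 1)
  if (length(unique(scales[usable])) < 2) {
    bp1 <- min(max(bp[at1[1]], 0), 1)
    return(list(au = bp1, bp_model = bp1, v = NA_real_, c = NA_real_,
                degenerate = TRUE))
  }
  bpc <- pmin(pmax(bp[usable], eps), 1 - eps)
  r <- scales[usable]
  psi <- qnorm(1 - bpc)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- n_boot * dnorm(psi)^2 / (bpc * (1 - bpc))
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% psi)
  v <- beta[1]; cc <- beta[2]
  list(au = min(max(1 - pnorm(v - cc), 0), 1),
       bp_model = min(max(1 - pnorm(v + cc), 0), 1),
       v = v, c = cc, degenerate = FALSE)
}
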