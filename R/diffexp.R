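#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must be in [0, 1] and non-missing")
  p.adjust(pvalues, method = "BH")
}

#' Intensity-difference screen for temporal differential expression
#'
#' Judges each gene's between-group expression difference against the
#' empirical distribution of differences among genes of similar average
#' intensity, so that the higher variability of weakly expressed genes is
#' accounted for without a count model. For every pair of sample groups
#' and every gene: the gene's average log intensity over all samples
#' places it on an intensity rank; the `w = max(50, round(window_fraction
#' * n_genes))` genes nearest in rank (a symmetric window, clipped at the
#' ends of the ranking, including the gene itself) supply the empirical
#' mean and SD of the between-group differences; the gene's z-score and
#' two-sided normal p-value follow. Per gene the combined p-value is the
#' minimum over group pairs (a gene differential anywhere in the time
#' course is of interest); Benjamini-Hochberg adjustment is applied once,
#' across genes, to the combined statistic.
#'
#' Windows use the unbiased (n-1) SD; intensity ties are broken by gene
#' order. A zero-SD window (constant data) yields p = 1 for the affected
#' genes, with a warning.
#'
#' @param mat A log-scale [expression_matrix()] (not yet gene-centered:
#'   the windows are defined on average intensity).
#' @param groups Metadata column naming the sample groups (default
#'   `"replicate_group"`), or a vector of group labels, one per sample.
#' @param window_fraction Window size as a fraction of genes, in (0, 1].
#' @param alpha Significance level on the adjusted p-value.
#' @param mode `"pairwise"` compares every unordered pair of groups (the
#'   two-sided p makes direction irrelevant); `"vs-rest"` compares each
#'   group against the mean of all other groups.
#' @return A data.frame of class `DEResult`: `gene_id`, `avg_intensity`,
#'   `best_pair`, `diff` (difference at the best pair), `z` (z-score at
#'   the best pair), `p_raw` (min over pairs), `p_adj`, `significant`.
#'   The full genes x pairs z-score and p-value matrices are attached as
#'   attributes `z` and `p`.
#' @export
intensity_difference_filter <- function(mat, groups = "replicate_group",
                                        window_fraction = 0.01,
                                        alpha = 0.05,
                                        mode = c("pairwise", "vs-rest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$scale != "log")
    stopf("intensity_difference_filter expects log-scale input, got '%s'", mat$scale)
  if (!(window_fraction > 0 && window_fraction <= 1))
    stopf("`window_fraction` must be in (0, 1]")
  g <- if (length(groups) == 1 && is.character(groups)) {
    if (!groups %in% names(mat$samples))
      stopf("'%s' is not a metadata column", groups)
    as.character(mat$samples[[groups]])
  } else {
    if (length(groups) != n_samples(mat))
      stopf("`groups` must have one label per sample")
    as.character(groups)
  }
  glev <- unique(g)
  if (length(glev) < 2) stopf("need at least 2 groups")
  n <- n_genes(mat)
  w <- max(50L, as.integer(round(window_fraction * n)))
  if (n < w)
    stopf("%d genes is fewer than the minimum window of %d", n, w)

  gm <- vapply(glev, function(lv)
    rowMeans(mat$values[, g == lv, drop = FALSE]), numeric(n))
  avg <- rowMeans(mat$values)
  ord <- order(avg) # ties broken by gene order (stable)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  # symmetric rank window, clipped at the ends, always of size w
  lo <- pmin(pmax(rank_of - (w - 1L) %/% 2L, 1L), n - w + 1L)
  hi <- lo + w - 1L

  pairs <- if (mode == "pairwise") {
    utils::combn(glev, 2, simplify = FALSE)
  } else {
    lapply(glev, function(lv) c(lv, ".rest"))
  }
  pair_names <- vapply(pairs, function(p) paste(p, collapse = " vs "), character(1))
  zmat <- matrix(NA_real_, n, length(pairs),
                 dimnames = list(rownames(mat$values), pair_names))
  pmat <- zmat
  dmat <- zmat
  zero_sd <- 0L
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    d <- if (mode == "pairwise") {
      gm[, pr[2]] - gm[, pr[1]]
    } else {
      gm[, pr[1]] - rowMeans(gm[, glev != pr[1], drop = FALSE])
    }
    ds <- d[ord]
    c1 <- c(0, cumsum(ds)); c2 <- c(0, cumsum(ds^2))
    s1 <- c1[hi + 1L] - c1[lo]
    s2 <- c2[hi + 1L] - c2[lo]
    mu <- s1 / w
    varw <- pmax((s2 - s1^2 / w) / (w - 1), 0)
    sdw <- sqrt(varw)
    z <- ifelse(sdw > 0, (d - mu) / sdw, 0)
    p <- ifelse(sdw > 0, 2 * pnorm(-abs(z)), 1)
    zero_sd <- zero_sd + sum(sdw == 0)
    zmat[, k] <- z; pmat[, k] <- p; dmat[, k] <- d
  }
  if (zero_sd > 0)
    warnf("zero-SD window for %d gene/pair combination(s); p set to 1", zero_sd)
  best <- max.col(-pmat, ties.method = "first")
  p_raw <- pmat[cbind(seq_len(n), best)]
  p_adj <- bh_adjust(p_raw)
  res <- data.frame(
    gene_id = rownames(mat$values),
    avg_intensity = avg,
    best_pair = pair_names[best],
    diff = dmat[cbind(seq_len(n), best)],
    z = zmat[cbind(seq_len(n), best)],
    p_raw = p_raw,
    p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE)
  attr(res, "z") <- zmat
  attr(res, "p") <- pmat
  attr(res, "window") <- w
  attr(res, "alpha") <- alpha
  attr(res, "mode") <- mode
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Write a DE result table to TSV
#'
#' @param de A `DEResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  out <- de
  for (col in c("avg_intensity", "diff", "z", "p_raw", "p_adj"))
    out[[col]] <- format_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
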