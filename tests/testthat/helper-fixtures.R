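# Small builders used across the suite.

make_meta <- function(ids, species = "sp1", age_order = seq_along(ids),
                      platform = "count", replicate_group = ids) {
  data.frame(sample_id = ids, species = species,
             age_label = paste0("T", age_order), age_order = age_order,
             platform = platform, replicate_group = replicate_group,
             stringsAsFactors = FALSE)
}

make_mat <- function(values, gene_ids = NULL, sample_ids = NULL,
                     scale = "log", ...) {
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  expression_matrix(values, make_meta(sample_ids, ...), scale = scale)
}

# two-group log-scale matrix with Gaussian noise and spread-out baselines
make_null_de_matrix <- function(n_genes, n_per_group = 3, tau = 0.3, seed = 1) {
  with_seed(seed, {
    baseline <- runif(n_genes, 5, 10)
    vals <- baseline + matrix(rnorm(n_genes * 2 * n_per_group, 0, tau),
                              n_genes, 2 * n_per_group)
  })
  ids <- c(paste0("g1s", seq_len(n_per_group)), paste0("g2s", seq_len(n_per_group)))
  rownames(vals) <- sprintf("G%04d", seq_len(n_genes))
  colnames(vals) <- ids
  expression_matrix(vals,
                    make_meta(ids, replicate_group = rep(c("grp1", "grp2"),
                                                         each = n_per_group)),
                    scale = "log")
}

# Plant paired between-group differences of exactly `delta` on genes spaced
# evenly across the intensity ranking (so planted windows do not collide).
# The symmetric +/- delta/2 shift leaves each gene's average intensity, and
# hence its window, unchanged.
plant_paired_difference <- function(mat, n_planted, delta, n_per_group = 3) {
  stopifnot(ncol(mat$values) == 2 * n_per_group)
  ord <- order(rowMeans(mat$values))
  step <- floor(nrow(mat$values) / n_planted)
  idx <- ord[seq(step %/% 2, by = step, length.out = n_planted)]
  g1 <- seq_len(n_per_group); g2 <- n_per_group + g1
  mat$values[idx, g1] <- mat$values[idx, g1] - delta / 2
  mat$values[idx, g2] <- mat$values[idx, g1] + delta
  list(mat = mat, planted = rownames(mat$values)[idx])
}

# Difference that the intensity-difference filter will score at z = target,
# accounting for the planted gene's own inflation of its window SD.
delta_for_window_z <- function(target, sigma_d, w) {
  f <- function(d) {
    mu_hat <- d / w
    sd_hat <- sqrt(sigma_d^2 + (d - mu_hat)^2 / (w - 1))
    (d - mu_hat) / sd_hat - target
  }
  uniroot(f, c(target * sigma_d, 10 * target * sigma_d))$root
}

# planted two-block sample structure: each block carries its own gene
# signature, so between-block distance >> within-block noise
make_block_matrix <- function(n_genes = 120, per_block = 4, shift = 4,
                              noise = 0.2, seed = 1) {
  half <- n_genes / 2
  with_seed(seed, {
    base <- matrix(rnorm(n_genes * 2 * per_block, 0, noise), n_genes)
    base[seq_len(half), seq_len(per_block)] <-
      base[seq_len(half), seq_len(per_block)] + shift
    base[half + seq_len(half), per_block + seq_len(per_block)] <-
      base[half + seq_len(half), per_block + seq_len(per_block)] + shift
  })
  dimnames(base) <- list(sprintf("g%03d", seq_len(n_genes)),
                         c(paste0("L", seq_len(per_block)),
                           paste0("R", seq_len(per_block))))
  base
}
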