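#' Combine two species' matrices over one-to-one orthologs
#'
#' Rows are the ortholog pairs present in both matrices (identity
#' `"geneA|geneB"`); columns are both species' samples with their metadata
#' and species tags. Both inputs must already be per-gene centered
#' (`log_centered`), the state in which cross-platform values are
#' comparable; pairs whose gene is missing on either side are dropped with
#' a message.
#'
#' @param mat_a,mat_b Gene-centered [expression_matrix()] objects.
#' @param map An [ortholog_map()] (columns `gene_a`, `gene_b`).
#' @param check_scale Set `FALSE` to combine log-scale (not yet centered)
#'   matrices, e.g. ahead of a global gene centering for species-axis
#'   analyses.
#' @return A combined [expression_matrix()] with
#'   `species_tag = "combined"`.
#' @export
combine_by_orthologs <- function(mat_a, mat_b, map, check_scale = TRUE) {
  stopifnot(inherits(mat_a, "ExpressionMatrix"),
            inherits(mat_b, "ExpressionMatrix"))
  if (check_scale && (mat_a$scale != "log_centered" || mat_b$scale != "log_centered"))
    stopf("inputs must be per-gene centered (scale 'log_centered'); got '%s'/'%s'",
          mat_a$scale, mat_b$scale)
  if (!all(c("gene_a", "gene_b") %in% names(map)))
    stopf("`map` needs columns gene_a and gene_b")
  present <- map$gene_a %in% rownames(mat_a$values) &
    map$gene_b %in% rownames(mat_b$values)
  if (!all(present))
    message(sprintf("combine_by_orthologs: dropped %d pair(s) absent from a matrix",
                    sum(!present)))
  map <- map[present, , drop = FALSE]
  if (nrow(map) == 0) stopf("no ortholog pair is present in both matrices")
  vals <- cbind(mat_a$values[map$gene_a, , drop = FALSE],
                mat_b$values[map$gene_b, , drop = FALSE])
  rownames(vals) <- paste(map$gene_a, map$gene_b, sep = "|")
  samples <- rbind(mat_a$samples, mat_b$samples)
  expression_matrix(vals, samples,
                    scale = if (check_scale) "log_centered" else mat_a$scale,
                    species_tag = "combined",
                    steps = unique(c(mat_a$steps, mat_b$steps)))
}

#' Principal component analysis of an expression matrix
#'
#' Singular value decomposition of the genes x samples grid with samples
#' as observations and genes as variables. The input must already be
#' gene-centered (per species for the shared-program view, or across all
#' samples for the species-axis view); no further centering is applied.
#' Components with negligible singular values (relative tolerance 1e-12)
#' are dropped. Sign convention: the largest-magnitude loading of each
#' component is made positive, so results are deterministic.
#'
#' @param mat A gene-centered [expression_matrix()] (or numeric matrix,
#'   genes x samples, assumed centered).
#' @param n_components Optional number of components to keep; silently
#'   truncated to the available rank, with a message.
#' @return A list of class `PCAResult`: `scores` (samples x components),
#'   `loadings` (genes x components, orthonormal columns),
#'   `variance_explained` (fractions of total variance, non-increasing),
#'   `samples` (the metadata).
#' @export
pca <- function(mat, n_components = NULL) {
  if (inherits(mat, "ExpressionMatrix")) {
    if (mat$scale != "log_centered")
      stopf("pca expects gene-centered input (scale 'log_centered'), got '%s'",
            mat$scale)
    values <- mat$values
    samples <- mat$samples
  } else {
    values <- mat
    samples <- NULL
  }
  x <- t(values) # samples x genes
  sv <- svd(x)
  tot <- sum(sv$d^2)
  keep <- which(sv$d > sv$d[1] * 1e-12)
  if (!is.null(n_components)) {
    if (n_components > length(keep))
      message(sprintf("pca: %d component(s) requested but rank is %d; truncated",
                      n_components, length(keep)))
    keep <- keep[seq_len(min(n_components, length(keep)))]
  }
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  for (k in seq_along(keep)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(values)
  rownames(loadings) <- rownames(values)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(keep))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = sv$d[keep]^2 / tot,
                 samples = samples),
            class = "PCAResult")
}

#' Retrieve genes with large absolute loadings on a component
#'
#' The species-differential gene screen: genes whose absolute loading on
#' the species-separating component exceeds `threshold` (loadings are
#' unit-column-norm, which fixes the threshold's scale). Sorted by
#' decreasing absolute loading; an unreachable threshold returns an empty
#' set with a message, not an error.
#'
#' @param pca_result A [pca()] result.
#' @param component Component index (or `"PC2"`-style name).
#' @param threshold Absolute-loading cutoff, default 0.04.
#' @return data.frame `gene_id`, `loading`, sorted by `abs(loading)`
#'   descending.
#' @export
retrieve_pc_loading_genes <- function(pca_result, component = 2, threshold = 0.04) {
  stopifnot(inherits(pca_result, "PCAResult"))
  if (is.character(component))
    component <- match(component, colnames(pca_result$loadings))
  if (is.na(component) || component < 1 || component > ncol(pca_result$loadings))
    stopf("component out of range (%d available)", ncol(pca_result$loadings))
  l <- pca_result$loadings[, component]
  sel <- which(abs(l) > threshold)
  if (!length(sel))
    message(sprintf("retrieve_pc_loading_genes: no |loading| above %g", threshold))
  sel <- sel[order(-abs(l[sel]))]
  data.frame(gene_id = names(l)[sel], loading = unname(l[sel]),
             stringsAsFactors = FALSE)
}

#' Assign samples to early / intermediate / late phases
#'
#' Builds a phase map from an explicit configuration: a nested list
#' `species -> phase -> age labels` (the format of the shipped
#' `extdata/phase_map_default.yaml`, which encodes the published
#' opossum/mouse stage grouping). Every sample of every species must be
#' covered, and each species must have at least one sample per phase.
#'
#' @param samples A sample metadata data.frame (or [expression_matrix()]).
#' @param config_mapping Nested list: `config_mapping[[species]][[phase]]`
#'   is a character vector of `age_label`s.
#' @return A data.frame `sample_id`, `species`, `phase`, class `PhaseMap`.
#' @export
assign_phases <- function(samples, config_mapping) {
  if (inherits(samples, "ExpressionMatrix")) samples <- samples$samples
  phases <- c("early", "intermediate", "late")
  phase <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sp <- as.character(samples$species[i])
    mapping <- config_mapping[[sp]]
    if (is.null(mapping))
      stopf("no phase mapping for species '%s'", sp)
    for (ph in names(mapping)) {
      if (samples$age_label[i] %in% mapping[[ph]]) phase[i] <- ph
    }
    if (is.na(phase[i]))
      stopf("sample '%s' (age '%s', species '%s') is not assigned by the mapping",
            samples$sample_id[i], samples$age_label[i], sp)
  }
  if (!all(phase %in% phases))
    stopf("phases must be one of: %s", paste(phases, collapse = ", "))
  out <- data.frame(sample_id = samples$sample_id,
                    species = samples$species,
                    phase = factor(phase, levels = phases),
                    stringsAsFactors = FALSE)
  for (sp in unique(out$species)) {
    got <- unique(out$phase[out$species == sp])
    if (length(got) < 3)
      stopf("species '%s' lacks samples in phase(s): %s", sp,
            paste(setdiff(phases, as.character(got)), collapse = ", "))
  }
  class(out) <- c("PhaseMap", "data.frame")
  out
}

#' Default phase map by age-rank terciles
#'
#' Splits each species' ordered time points into early / intermediate /
#' late thirds (sizes `ceiling(T/3)`, then the middle, then the rest; for
#' seven stages this gives the 3/2/2 split used for the published
#' time courses). Replicates share their time point's phase.
#'
#' @param samples A sample metadata data.frame (or [expression_matrix()]).
#' @return A `PhaseMap` data.frame.
#' @export
default_phase_map <- function(samples) {
  if (inherits(samples, "ExpressionMatrix")) samples <- samples$samples
  mapping <- list()
  for (sp in unique(samples$species)) {
    idx <- samples$species == sp
    ages <- unique(samples$age_label[idx][order(samples$age_order[idx])])
    tt <- length(ages)
    if (tt < 3) stopf("species '%s' needs >= 3 time points for phases", sp)
    n_early <- ceiling(tt / 3)
    n_late <- floor(tt / 3)
    n_mid <- tt - n_early - n_late
    mapping[[sp]] <- list(
      early = ages[seq_len(n_early)],
      intermediate = ages[n_early + seq_len(n_mid)],
      late = ages[n_early + n_mid + seq_len(n_late)])
  }
  assign_phases(samples, mapping)
}

#' Phase-averaged expression per species
#'
#' Collapses each species' samples to the arithmetic mean over the early,
#' intermediate and late phases: one genes x 3 grid per species.
#'
#' @param mat An [expression_matrix()].
#' @param phases A `PhaseMap` covering the matrix's samples.
#' @return Named list (one per species) of genes x 3 matrices with
#'   columns `early`, `intermediate`, `late`.
#' @export
phase_average <- function(mat, phases) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(phases, "PhaseMap"))
  idx <- match(mat$samples$sample_id, phases$sample_id)
  if (anyNA(idx))
    stopf("phase map does not cover sample(s): %s",
          paste(mat$samples$sample_id[is.na(idx)], collapse = ", "))
  ph <- phases$phase[idx]
  out <- list()
  for (sp in unique(mat$samples$species)) {
    grid <- vapply(c("early", "intermediate", "late"), function(p) {
      cols <- which(mat$samples$species == sp & ph == p)
      rowMeans(mat$values[, cols, drop = FALSE])
    }, numeric(n_genes(mat)))
    if (!is.matrix(grid)) grid <- matrix(grid, nrow = 1) # single-gene input
    dimnames(grid) <- list(rownames(mat$values),
                           c("early", "intermediate", "late"))
    out[[sp]] <- grid
  }
  out
}

#' Correlate phase-averaged ortholog profiles and classify conservation
#'
#' Pearson correlation over the three matched phase means of each ortholog
#' pair, classified at fixed thresholds: `conserved_strict` (cor > 0.9),
#' `conserved` (cor > 0.8), `not_conserved`, or `undefined` when either
#' profile has zero variance (Pearson undefined). When per-species DE
#' results are supplied, the table gains a `de_both` column and the screen
#' mirrors the published procedure: the conserved counts are read off the
#' genes differentially expressed in both species.
#'
#' @param avg_a,avg_b genes x 3 phase-mean grids sharing ortholog-pair row
#'   identity (as from [phase_average()] on a combined matrix, or two
#'   per-species grids with matching rows).
#' @param de_a,de_b Optional `DEResult`s for species A and B; `de_both`
#'   marks pairs whose genes are significant in both.
#' @return data.frame of class `ConservationTable`: `pair_id`, the three
#'   phase means per species, `cor`, `class`, and `de_both` (if masks
#'   given).
#' @export
ortholog_profile_correlation <- function(avg_a, avg_b, de_a = NULL, de_b = NULL) {
  if (!identical(rownames(avg_a), rownames(avg_b)))
    stopf("phase grids must share ortholog-pair row identity")
  if (ncol(avg_a) != 3 || ncol(avg_b) != 3)
    stopf("phase grids must have exactly 3 columns")
  sda <- apply(avg_a, 1, sd)
  sdb <- apply(avg_b, 1, sd)
  cc <- rep(NA_real_, nrow(avg_a))
  ok <- sda > 0 & sdb > 0
  for (i in which(ok)) cc[i] <- cor(avg_a[i, ], avg_b[i, ])
  cls <- ifelse(!ok, "undefined",
         ifelse(cc > 0.9, "conserved_strict",
         ifelse(cc > 0.8, "conserved", "not_conserved")))
  out <- data.frame(pair_id = rownames(avg_a),
                    early_a = avg_a[, 1], intermediate_a = avg_a[, 2],
                    late_a = avg_a[, 3],
                    early_b = avg_b[, 1], intermediate_b = avg_b[, 2],
                    late_b = avg_b[, 3],
                    cor = cc, class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(de_a) && !is.null(de_b)) {
    parts <- strsplit(out$pair_id, "|", fixed = TRUE)
    ga <- vapply(parts, `[`, character(1), 1)
    gb <- vapply(parts, function(p) p[length(p)], character(1))
    sig_a <- de_a$gene_id[de_a$significant]
    sig_b <- de_b$gene_id[de_b$significant]
    out$de_both <- ga %in% sig_a & gb %in% sig_b
  }
  class(out) <- c("ConservationTable", "data.frame")
  out
}

#' Count conserved ortholog pairs at the screen thresholds
#'
#' Applies the published screen: among pairs differentially expressed in
#' both species (all pairs, if no `de_both` column), how many exceed each
#' correlation threshold. `conserved_strict` is always nested inside
#' `conserved`.
#'
#' @param conservation A `ConservationTable`.
#' @param thresholds Correlation thresholds, default `c(0.8, 0.9)`.
#' @return Named integer vector, one count per threshold, plus
#'   `n_screened`.
#' @export
conservation_counts <- function(conservation, thresholds = c(0.8, 0.9)) {
  screened <- if ("de_both" %in% names(conservation))
    conservation[conservation$de_both, , drop = FALSE] else conservation
  ok <- !is.na(screened$cor)
  counts <- vapply(thresholds, function(th)
    sum(screened$cor[ok] > th), integer(1))
  c(setNames(counts, sprintf("cor_gt_%g", thresholds)),
    n_screened = nrow(screened))
}
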