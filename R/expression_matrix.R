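#' Gene-by-sample expression matrix with sample metadata
#'
#' The universal currency of the package: a numeric genes x samples grid
#' plus per-sample metadata (species, developmental age, platform,
#' replicate group) and a scale tag tracking where the matrix sits in the
#' normalisation chain (`raw` values, `log` values, or `log_centered`
#' values after per-gene centering).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). All entries must be
#'   finite.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `species`, `age_label`, `age_order`, `platform` (`"count"` or
#'   `"intensity"`), `replicate_group`. Rows must match the columns of
#'   `values` (same identifiers, same order).
#' @param scale One of `"raw"`, `"log"`, `"log_centered"`.
#' @param species_tag Species of the matrix, or `"combined"` for a
#'   cross-species matrix.
#' @param steps Character vector of normalisation steps already applied
#'   (used to enforce pipeline order).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples,
                              scale = c("raw", "log", "log_centered"),
                              species_tag = "unknown",
                              steps = character()) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stopf("`values` must have unique gene identifiers as rownames")
  if (is.null(colnames(values)))
    stopf("`values` must have sample identifiers as colnames")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("non-finite value at gene '%s', sample '%s'",
          rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  samples <- validate_sample_meta(samples)
  if (nrow(samples) != ncol(values) ||
      !identical(as.character(samples$sample_id), colnames(values)))
    stopf("sample metadata rows must match matrix columns (same ids, same order)")
  structure(
    list(values = values, samples = samples, scale = scale,
         species_tag = species_tag, steps = steps),
    class = "ExpressionMatrix"
  )
}

validate_sample_meta <- function(samples) {
  required <- c("sample_id", "species", "age_label", "age_order",
                "platform", "replicate_group")
  if (!is.data.frame(samples)) stopf("`samples` must be a data.frame")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stopf("sample metadata lacks column(s): %s", paste(missing, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample_id in metadata: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  if (!all(samples$platform %in% c("count", "intensity")))
    stopf("platform must be 'count' or 'intensity'")
  if (any(is.na(samples$age_order)) || any(samples$age_order != round(samples$age_order)))
    stopf("age_order must be integer ranks")
  samples$age_order <- as.integer(samples$age_order)
  rownames(samples) <- NULL
  samples
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$species_tag, x$scale))
  if (length(x$steps))
    cat("  steps:", paste(x$steps, collapse = " -> "), "\n")
  sp <- table(x$samples$species)
  cat("  samples:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

n_genes <- function(mat) nrow(mat$values)
n_samples <- function(mat) ncol(mat$values)

gene_ids <- function(mat) rownames(mat$values)

# Subset samples, keeping metadata aligned.
subset_samples <- function(mat, idx) {
  expression_matrix(mat$values[, idx, drop = FALSE],
                    mat$samples[idx, , drop = FALSE],
                    scale = mat$scale, species_tag = mat$species_tag,
                    steps = mat$steps)
}

subset_genes <- function(mat, idx) {
  expression_matrix(mat$values[idx, , drop = FALSE], mat$samples,
                    scale = mat$scale, species_tag = mat$species_tag,
                    steps = mat$steps)
}
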