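#' Read an expression matrix and its sample metadata from TSV
#'
#' Expression files have a header row of sample identifiers, a first column
#' of gene identifiers, and tab-separated numeric values. Gene identifiers
#' are upper-cased before anything else so that joins across sources are
#' case-insensitive; duplicated gene rows are collapsed to their per-sample
#' mean with a warning. Malformed input (non-numeric or missing cells,
#' header samples absent from the metadata) is rejected rather than
#' silently coerced; missing cells can optionally be imputed by the
#' per-gene mean for intensity-like inputs.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV (columns
#'   `sample_id`, `species`, `age_label`, `age_order`, `platform`,
#'   `replicate_group`).
#' @param scale Scale tag to attach, default `"raw"`.
#' @param species_tag Species tag; defaults to the single species found in
#'   the metadata (or `"combined"` when there are several).
#' @param impute_missing If `TRUE`, missing cells are replaced by the
#'   per-gene mean of the observed cells; the default rejects them.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, metadata_path,
                                scale = "raw", species_tag = NULL,
                                impute_missing = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(raw) < 2) stopf("'%s': expected a gene column plus sample columns", path)
  ids <- toupper(as.character(raw[[1]]))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals) & vals != "" & toupper(vals) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("'%s': non-numeric value '%s' at row %d (gene '%s'), column '%s'",
          path, vals[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
          colnames(vals)[bad[1, 2]])
  }
  if (anyNA(num)) {
    if (impute_missing) {
      for (i in which(rowSums(is.na(num)) > 0)) {
        row <- num[i, ]
        if (all(is.na(row)))
          stopf("'%s': gene '%s' has no observed values to impute from", path, ids[i])
        row[is.na(row)] <- mean(row, na.rm = TRUE)
        num[i, ] <- row
      }
      warnf("'%s': imputed missing cells by per-gene mean", path)
    } else {
      miss <- which(is.na(num), arr.ind = TRUE)[1, ]
      stopf("'%s': missing value at gene '%s', column '%s' (set impute_missing = TRUE to impute)",
            path, ids[miss[1]], colnames(num)[miss[2]])
    }
  }
  rownames(num) <- ids
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warnf("'%s': %d duplicated gene id(s) collapsed by per-sample mean (%s%s)",
          path, length(dup), paste(head(dup, 3), collapse = ", "),
          if (length(dup) > 3) ", ..." else "")
    num <- rowsum(num, group = ids) / as.vector(table(ids)[sort(unique(ids))])
    num <- num[match(unique(ids), rownames(num)), , drop = FALSE]
  }

  meta <- read.delim(metadata_path, header = TRUE, sep = "\t",
                     check.names = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)
  absent <- setdiff(colnames(num), meta$sample_id)
  if (length(absent))
    stopf("sample(s) in '%s' header missing from metadata: %s",
          path, paste(absent, collapse = ", "))
  meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]
  if (is.null(species_tag)) {
    sp <- unique(meta$species)
    species_tag <- if (length(sp) == 1) sp else "combined"
  }
  expression_matrix(num, meta, scale = scale, species_tag = species_tag)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' Values are rendered with a fixed `%.10g` format so identical matrices
#' always produce byte-identical files; gene and sample order is preserved
#' as-is, making `write(read(x))` idempotent on canonical files.
#'
#' @param mat An [expression_matrix()].
#' @param path Output TSV path.
#' @param metadata_path Optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path, metadata_path = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  out <- cbind(gene_id = rownames(mat$values),
               as.data.frame(apply(mat$values, 2, format_num),
                             check.names = FALSE, optional = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(mat$samples, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Two-column TSV (`gene_a`, `gene_b`). Identifiers are upper-cased; any
#' identifier participating in more than one pair makes all of its pairs
#' ambiguous, and every such pair is dropped entirely so the result is
#' strictly one-to-one.
#'
#' @param path Path to the map TSV.
#' @return A data.frame with columns `gene_a`, `gene_b` and class
#'   `OrthologMap`.
#' @export
read_ortholog_map <- function(path) {
  map <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(map) == 0) stopf("'%s': ortholog map is empty", path)
  if (ncol(map) < 2) stopf("'%s': expected two columns (gene_a, gene_b)", path)
  ortholog_map(toupper(as.character(map[[1]])), toupper(as.character(map[[2]])))
}

#' Construct a one-to-one ortholog map from identifier vectors
#'
#' @param gene_a,gene_b Equal-length character vectors of paired gene
#'   identifiers in species A and B.
#' @return A data.frame of retained one-to-one pairs, class `OrthologMap`.
#' @export
ortholog_map <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  pairs <- unique(data.frame(gene_a = as.character(gene_a),
                             gene_b = as.character(gene_b),
                             stringsAsFactors = FALSE))
  amb_a <- pairs$gene_a[duplicated(pairs$gene_a)]
  amb_b <- pairs$gene_b[duplicated(pairs$gene_b)]
  keep <- !(pairs$gene_a %in% amb_a) & !(pairs$gene_b %in% amb_b)
  if (any(!keep))
    warnf("dropped %d ambiguous ortholog pair(s) (identifier in >1 pair)",
          sum(!keep))
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("OrthologMap", "data.frame")
  pairs
}

#' Write a dendrogram to Newick with AU|BP internal-node labels
#'
#' Internal nodes carrying support are labelled `"AU|BP"` as rounded
#' percentages (e.g. `95|90`); branch lengths are differences of merge
#' heights, so the file round-trips through [read_newick_annotated()] with
#' topology and heights intact.
#'
#' @param tree A `cluster_tree` (see [hierarchical_cluster()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_annotated <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  labels <- tree$labels
  if (is.null(labels) || any(is.na(labels)) || any(!nzchar(labels)))
    stopf("all leaves must be labelled")
  if (any(grepl("[(),:;\\s]", labels)))
    stopf("leaf labels must not contain Newick metacharacters or whitespace")
  support <- tree$support
  node_label <- function(step) {
    if (is.null(support)) return("")
    row <- support[support$node == step, , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$au[1]) || is.na(row$bp[1])) return("")
    sprintf("%.0f|%.0f", 100 * row$au[1], 100 * row$bp[1])
  }
  render <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%s", labels[-node], format_num(parent_height))
    } else {
      h <- tree$height[node]
      kids <- tree$merge[node, ]
      inner <- paste(render(kids[1], h), render(kids[2], h), sep = ",")
      sprintf("(%s)%s:%s", inner, node_label(node), format_num(parent_height - h))
    }
  }
  root <- nrow(tree$merge)
  kids <- tree$merge[root, ]
  h <- tree$height[root]
  newick <- sprintf("(%s,%s)%s;", render(kids[1], h), render(kids[2], h),
                    node_label(root))
  writeLines(newick, path)
  invisible(path)
}

#' Read an annotated Newick dendrogram back into a cluster tree
#'
#' Parses the file with `ape::read.tree`, recovers merge heights from the
#' (ultrametric) branch lengths, and decodes `"AU|BP"` internal labels.
#'
#' @param path Path to a Newick file written by [write_newick_annotated()].
#' @return A `cluster_tree`.
#' @export
read_newick_annotated <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stopf("'%s': could not parse Newick", path)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  depth <- numeric(ntip + nnode)
  for (i in seq_len(nrow(phy$edge)))
    depth[phy$edge[i, 2]] <- depth[phy$edge[i, 1]] + phy$edge.length[i]
  total <- max(depth[seq_len(ntip)])
  height <- total - depth # per phylo node id
  children <- split(phy$edge[, 2], phy$edge[, 1])
  internal <- order(height[(ntip + 1):(ntip + nnode)]) + ntip
  merge <- matrix(0L, nnode, 2)
  heights <- numeric(nnode)
  code <- integer(ntip + nnode) # phylo node id -> merge code
  code[seq_len(ntip)] <- -seq_len(ntip)
  for (step in seq_along(internal)) {
    node <- internal[step]
    kids <- children[[as.character(node)]]
    if (length(kids) != 2)
      stopf("'%s': tree is not strictly binary at node %d", path, node)
    merge[step, ] <- sort(code[kids])
    heights[step] <- height[node]
    code[node] <- step
  }
  support <- NULL
  if (!is.null(phy$node.label) && any(nzchar(phy$node.label))) {
    lab <- phy$node.label[internal - ntip]
    parsed <- strsplit(lab, "|", fixed = TRUE)
    au <- vapply(parsed, function(p)
      if (length(p) == 2) as.numeric(p[1]) / 100 else NA_real_, numeric(1))
    bp <- vapply(parsed, function(p)
      if (length(p) == 2) as.numeric(p[2]) / 100 else NA_real_, numeric(1))
    support <- data.frame(node = seq_len(nnode), au = au, bp = bp)
  }
  cluster_tree(labels = phy$tip.label, merge = merge, height = heights,
               support = support)
}
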