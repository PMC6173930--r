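#' Default end-to-end run configuration
#'
#' A nested list configuring every stage: the synthetic dataset (see
#' [simulation_config()] for the study design it emulates), the
#' normalisation chain, the intensity-difference screen, temporal k-means,
#' multiscale-bootstrap co-clustering, the combined PCA with loading-based
#' retrieval, and the phase-averaged conservation screen. The single
#' global `seed` is expanded into named substreams per stage
#' ([substream_seed()]), so stages can be re-run in isolation with
#' identical randomness. Configurations can also be written/read as YAML
#' with [write_run_config()] / [read_run_config()].
#'
#' @param seed Global integer seed.
#' @param ... Named overrides for top-level entries (`simulation`,
#'   `normalization`, `de`, `kmeans`, `bootstrap`, `loading`,
#'   `thresholds`).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulation = list(), # overrides to simulation_config(); seed is derived
    normalization = list(pseudocount = 1, background_quantile = 0.05),
    de = list(alpha = 0.05, window_fraction = 0.01, mode = "pairwise"),
    kmeans = list(k = 4L, n_restarts = 10L),
    bootstrap = list(scales = seq(0.5, 1.4, by = 0.1), n_boot = 1000L),
    loading = list(threshold = 0.04),
    thresholds = c(0.8, 0.9))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stopf("unknown config entry '%s'", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stopf("config must set `seed`")
  do.call(default_run_config, c(list(seed = raw$seed),
                                raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full cross-species analysis pipeline
#'
#' simulate -> normalise -> screen differential expression per species ->
#' k-means temporal clusters -> combine over orthologs -> co-cluster
#' samples with multiscale-bootstrap support -> combined PCA (shared
#' per-species-centered view for variance structure; globally centered
#' view for the species axis) -> loading-based retrieval of
#' species-differential genes -> phase-averaged conservation screen on
#' genes differentially expressed in both species.
#'
#' All stage outputs are written as TSV/Newick/JSON under `out_dir` with
#' fixed numeric formatting and no timestamps, so re-running with the same
#' config byte-reproduces every file.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory.
#' @param verbose Emit progress messages.
#' @return The summary list, invisibly (also written to `summary.json`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.txt")
  loglines <- character()
  note <- function(fmt, ...) {
    loglines <<- c(loglines, sprintf(fmt, ...))
    say(fmt, ...)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    sim_cfg <- do.call(simulation_config,
                       c(config$simulation,
                         list(seed = substream_seed(config$seed, "simulate"))))
    note("simulate: n_genes=%d seed=%d", sim_cfg$n_genes, sim_cfg$seed)
    generate_timecourse_pair(sim_cfg)
  })
  write_simulation(sim, file.path(out_dir, "sim"))

  # -- normalise -----------------------------------------------------------
  pc <- config$normalization$pseudocount
  bq <- config$normalization$background_quantile
  norm <- stage("normalize", {
    note("normalize: log(pseudocount=%g) background(q=%g) center_samples center_genes_by_species", pc, bq)
    lapply(list(a = sim$a, b = sim$b), function(m)
      center_samples(background_correct(log_transform(m, pc), bq)))
  })
  centered <- lapply(norm, center_genes_by_species)
  for (sp in names(centered))
    write_expression_tsv(centered[[sp]],
                         file.path(out_dir, sprintf("norm_%s.tsv", sp)))

  # -- differential expression --------------------------------------------
  de <- stage("diffexp", {
    note("diffexp: alpha=%g window=%g mode=%s", config$de$alpha,
         config$de$window_fraction, config$de$mode)
    lapply(norm, intensity_difference_filter,
           groups = "replicate_group",
           window_fraction = config$de$window_fraction,
           alpha = config$de$alpha, mode = config$de$mode)
  })
  write_de_tsv(de$a, file.path(out_dir, "de_a.tsv"))
  write_de_tsv(de$b, file.path(out_dir, "de_b.tsv"))

  # -- temporal k-means on species-A DE genes -----------------------------
  km_sizes <- integer(0)
  km <- stage("kmeans", {
    sig <- de$a$gene_id[de$a$significant]
    if (length(sig) >= config$kmeans$k + 1) {
      profs <- centered$a$values[sig, , drop = FALSE]
      profs <- profs[apply(profs, 1, sd) > 0, , drop = FALSE]
      fit <- kmeans_profiles(profs, k = config$kmeans$k,
                             seed = substream_seed(config$seed, "kmeans"),
                             n_restarts = config$kmeans$n_restarts)
      km_sizes <- as.integer(table(factor(fit$labels,
                                          levels = seq_len(config$kmeans$k))))
      note("kmeans: k=%d on %d DE genes, sizes=%s", config$kmeans$k,
           length(fit$labels), paste(km_sizes, collapse = "/"))
      write.table(data.frame(gene_id = names(fit$labels),
                             cluster = fit$labels),
                  file.path(out_dir, "kmeans_a.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      fit
    } else {
      note("kmeans: skipped (%d DE genes < k+1)", length(sig))
      NULL
    }
  })
  if (!is.null(km))
    km_sizes <- as.integer(table(factor(km$labels,
                                        levels = seq_len(config$kmeans$k))))

  # -- combine over orthologs (replicate-averaged) ------------------------
  avg_centered <- lapply(centered, average_replicates)
  combined <- stage("combine", {
    cm <- combine_by_orthologs(avg_centered$a, avg_centered$b, sim$orthologs)
    note("combine: %d ortholog pairs x %d samples", nrow(cm$values),
         ncol(cm$values))
    cm
  })

  # -- co-clustering with multiscale bootstrap ----------------------------
  tree <- stage("bootstrap", {
    note("bootstrap: scales=%s n_boot=%d",
         paste(config$bootstrap$scales, collapse = ","),
         config$bootstrap$n_boot)
    multiscale_bootstrap_support(combined, axis = "samples",
                                 scales = config$bootstrap$scales,
                                 n_boot = config$bootstrap$n_boot,
                                 seed = substream_seed(config$seed, "bootstrap"))
  })
  write_newick_annotated(tree, file.path(out_dir, "combined_tree.nwk"))
  sup <- tree$support
  sup$bp <- format_num(sup$bp); sup$au <- format_num(sup$au)
  sup$v <- format_num(sup$v); sup$c <- format_num(sup$c)
  write.table(sup, file.path(out_dir, "clade_support.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # -- combined PCA: shared-program view ----------------------------------
  pca_shared <- stage("pca", pca(combined))
  age_rank <- combined$samples$age_order
  cor_pc1_age <- suppressWarnings(cor(pca_shared$scores[, 1], age_rank))
  note("pca: PC1 %.1f%%, PC2 %.1f%% of variance; cor(PC1, age rank)=%.3f",
       100 * pca_shared$variance_explained[1],
       100 * pca_shared$variance_explained[2], cor_pc1_age)
  write.table(data.frame(component = paste0("PC", seq_along(pca_shared$variance_explained)),
                         variance_explained = format_num(pca_shared$variance_explained)),
              file.path(out_dir, "pca_variance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # -- species-axis PCA on the globally centered combination --------------
  avg_log <- lapply(norm, average_replicates)
  combined_global <- center_genes_by_species(
    combine_by_orthologs(avg_log$a, avg_log$b, sim$orthologs,
                         check_scale = FALSE),
    per_species = FALSE)
  pca_global <- stage("pca_species_axis", pca(combined_global))
  is_a <- combined_global$samples$species == unique(sim$a$samples$species)
  species_component <- NA_integer_
  for (k in seq_len(min(3, ncol(pca_global$scores)))) {
    sc <- pca_global$scores[, k]
    if (all(sc[is_a] > 0) && all(sc[!is_a] < 0) ||
        all(sc[is_a] < 0) && all(sc[!is_a] > 0)) {
      species_component <- k
      break
    }
  }
  retrieved <- if (!is.na(species_component)) {
    retrieve_pc_loading_genes(pca_global, species_component,
                              config$loading$threshold)
  } else {
    note("pca_species_axis: no leading component splits the species by score sign")
    data.frame(gene_id = character(), loading = numeric())
  }
  note("pca_species_axis: component=%s, %d gene(s) with |loading| > %g",
       ifelse(is.na(species_component), "none", species_component),
       nrow(retrieved), config$loading$threshold)
  rt <- retrieved; rt$loading <- format_num(rt$loading)
  write.table(rt, file.path(out_dir, "species_loading_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- phase-averaged conservation screen ---------------------------------
  conservation <- stage("conservation", {
    phases <- default_phase_map(combined)
    avg <- phase_average(combined, phases)
    sp_names <- unique(combined$samples$species)
    ortholog_profile_correlation(avg[[sp_names[1]]], avg[[sp_names[2]]],
                                 de_a = de$a, de_b = de$b)
  })
  ct <- conservation
  for (col in c("early_a", "intermediate_a", "late_a",
                "early_b", "intermediate_b", "late_b", "cor"))
    ct[[col]] <- format_num(ct[[col]])
  write.table(ct, file.path(out_dir, "conservation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- conservation_counts(conservation, config$thresholds)
  note("conservation: %d screened (DE in both), %s",
       counts[["n_screened"]],
       paste(sprintf("%s=%d", names(counts)[-length(counts)],
                     counts[-length(counts)]), collapse = ", "))

  # -- summary -------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    n_genes_a = n_genes(sim$a), n_genes_b = n_genes(sim$b),
    n_de_a = sum(de$a$significant), n_de_b = sum(de$b$significant),
    kmeans_cluster_sizes = km_sizes,
    n_ortholog_pairs = nrow(sim$orthologs),
    n_ortholog_pairs_used = nrow(combined$values),
    n_de_both = sum(conservation$de_both),
    n_conserved = as.list(counts[-length(counts)]),
    n_loading_retrieved = nrow(retrieved),
    species_component = species_component,
    pc1_variance_explained = pca_shared$variance_explained[1],
    pc2_variance_explained = pca_shared$variance_explained[2],
    cor_pc1_age_rank = cor_pc1_age,
    parameters = list(de = config$de, kmeans = config$kmeans,
                      bootstrap = config$bootstrap[c("n_boot")],
                      loading = config$loading,
                      normalization = config$normalization))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(loglines, logf)
  invisible(summary)
}

#' Render a human-readable report for a pipeline run
#'
#' Writes `report.md` summarising the run (sample sizes, screen results,
#' variance structure, clade support) plus, when a graphics device is
#' available, a `report_figures.pdf` with the variance scree, the
#' co-clustering dendrogram and the PC1/PC2 score plot. Figures are
#' illustrative; the tables restate `summary.json`. Regeneration is
#' idempotent.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @return Path to `report.md`, invisibly.
#' @export
report <- function(out_dir) {
  sj <- file.path(out_dir, "summary.json")
  if (!file.exists(sj)) stopf("missing artifact: %s", sj)
  s <- jsonlite::read_json(sj, simplifyVector = TRUE)
  lines <- c(
    "# Cross-species developmental transcriptome run",
    "",
    sprintf("- Seed: %s", s$seed),
    sprintf("- Genes simulated: %d (species A) / %d (species B)",
            s$n_genes_a, s$n_genes_b),
    sprintf("- Differentially expressed: %d (A), %d (B); %d in both species",
            s$n_de_a, s$n_de_b, s$n_de_both),
    sprintf("- Temporal k-means cluster sizes (A): %s",
            if (length(s$kmeans_cluster_sizes)) paste(s$kmeans_cluster_sizes, collapse = ", ") else "not run"),
    sprintf("- Ortholog pairs: %d mapped, %d used in the combined matrix",
            s$n_ortholog_pairs, s$n_ortholog_pairs_used),
    if (length(s$n_conserved)) {
      sprintf("- Conserved temporal profiles among DE-in-both genes: %s",
              paste(sprintf("%s: %d", sub("cor_gt_", "cor > ", names(s$n_conserved)),
                            unlist(s$n_conserved)), collapse = "; "))
    } else "- Conserved temporal profiles: zero conserved genes",
    sprintf("- Species-axis component: %s; %d gene(s) retrieved by |loading|",
            ifelse(is.na(s$species_component) || is.null(s$species_component),
                   "none", s$species_component),
            s$n_loading_retrieved),
    sprintf("- Combined PCA: PC1 %.1f%% (cor with age rank %.2f), PC2 %.1f%%",
            100 * s$pc1_variance_explained, s$cor_pc1_age_rank,
            100 * s$pc2_variance_explained),
    "",
    "Artifacts: sim/ (inputs + truth), norm_*.tsv, de_*.tsv, kmeans_a.tsv,",
    "combined_tree.nwk, clade_support.tsv, pca_variance.tsv,",
    "species_loading_genes.tsv, conservation.tsv, summary.json.")
  writeLines(lines, file.path(out_dir, "report.md"))
  tryCatch({
    pdf(file.path(out_dir, "report_figures.pdf"), width = 7, height = 5)
    on.exit(dev.off(), add = TRUE)
    var_tab <- read.delim(file.path(out_dir, "pca_variance.tsv"))
    barplot(var_tab$variance_explained, names.arg = var_tab$component,
            ylab = "fraction of variance", main = "Combined PCA")
    tree <- read_newick_annotated(file.path(out_dir, "combined_tree.nwk"))
    plot(stats::as.hclust(tree), main = "Co-clustering (AU|BP)",
         xlab = "", sub = "")
  }, error = function(e)
    message("report: figures skipped (", conditionMessage(e), ")"))
  invisible(file.path(out_dir, "report.md"))
}
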