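#' Configuration for the two-species time-course simulator
#'
#' Defines the synthetic study: species A is sampled once per developmental
#' time point on a count platform (RNA-seq-like, negative-binomial noise
#' around the expected expression, per-sample library sizes), species B is
#' sampled with replicate animals per time point on a continuous intensity
#' platform (lognormal noise plus an additive background). A shared "age"
#' expression program drives a configurable fraction of genes identically
#' in both species (after proportional mapping of time ranks); other gene
#' classes carry species-A-specific late activation (muscle-like),
#' species-B-specific elevation around the time of birth, or no signal.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints_a,n_timepoints_b Ordered developmental ages per
#'   species (>= 2).
#' @param n_replicates_b Replicate animals per time point in species B.
#' @param fractions Named proportions over the six gene classes
#'   `conserved_up`, `conserved_down`, `conserved_peak`, `species_a_late`,
#'   `birth_b`, `flat`; must sum to 1. Remainder genes left over by
#'   rounding are assigned to `flat`.
#' @param effect_size log2-scale amplitude of every temporal program.
#' @param species_offset_sd Magnitude of the per-gene species-level offset
#'   planted on the divergent subset (offsets are `+/- species_offset_sd`
#'   with random sign, so their standard deviation equals this value).
#' @param n_divergent Number of divergent genes carrying a species offset;
#'   drawn from the flat class so offsets are not confounded with temporal
#'   programs.
#' @param noise_sd Residual log2-scale noise SD (both platforms).
#' @param nb_dispersion Negative-binomial dispersion of species A counts
#'   (`size = 1/nb_dispersion`).
#' @param background_level Additive background of species B intensities.
#' @param library_size_sd SD of per-sample log library-size factors for
#'   species A (lognormal, mean 0 on the log scale).
#' @param baseline_log2_range Range of per-gene baseline log2 expression.
#' @param ortholog_fraction Fraction (< 1) of genes present in the
#'   ortholog map.
#' @param transition_index_a Time index after which `species_a_late`
#'   genes activate; default `ceiling(0.6 * n_timepoints_a)`.
#' @param birth_index_b Last prenatal time index of species B; the birth
#'   window is the two following (earliest postnatal) time points.
#'   Default `ceiling(n_timepoints_b / 2)`.
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              n_timepoints_a = 7L,
                              n_timepoints_b = 7L,
                              n_replicates_b = 3L,
                              fractions = c(conserved_up = 0.07,
                                            conserved_down = 0.07,
                                            conserved_peak = 0.06,
                                            species_a_late = 0.10,
                                            birth_b = 0.05,
                                            flat = 0.65),
                              effect_size = 2,
                              species_offset_sd = 1,
                              n_divergent = 50L,
                              noise_sd = 0.3,
                              nb_dispersion = 0.02,
                              background_level = 16,
                              library_size_sd = 0.2,
                              baseline_log2_range = c(5, 10),
                              ortholog_fraction = 0.9,
                              transition_index_a = NULL,
                              birth_index_b = NULL,
                              seed = 1L) {
  classes <- c("conserved_up", "conserved_down", "conserved_peak",
               "species_a_late", "birth_b", "flat")
  for (v in c("n_genes", "n_timepoints_a", "n_timepoints_b", "n_replicates_b"))
    if (!is_count(get(v))) stopf("`%s` must be a positive integer", v)
  if (n_timepoints_a < 2 || n_timepoints_b < 2)
    stopf("each species needs at least 2 time points")
  if (!identical(sort(names(fractions)), sort(classes)))
    stopf("`fractions` must be named exactly: %s", paste(classes, collapse = ", "))
  fractions <- fractions[classes]
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1 (within 1e-9)")
  for (v in c("effect_size", "noise_sd", "nb_dispersion", "library_size_sd"))
    if (!(is.numeric(get(v)) && get(v) > 0)) stopf("`%s` must be positive", v)
  if (species_offset_sd < 0) stopf("`species_offset_sd` must be >= 0")
  if (background_level < 0) stopf("`background_level` must be >= 0")
  if (!(ortholog_fraction > 0 && ortholog_fraction < 1))
    stopf("`ortholog_fraction` must be in (0, 1)")
  if (n_divergent < 0 || n_divergent > n_genes)
    stopf("`n_divergent` must be in 0..n_genes")
  transition_index_a <- transition_index_a %||% ceiling(0.6 * n_timepoints_a)
  birth_index_b <- birth_index_b %||% ceiling(n_timepoints_b / 2)
  if (transition_index_a < 1 || transition_index_a >= n_timepoints_a)
    stopf("`transition_index_a` must be in 1..(n_timepoints_a - 1)")
  if (birth_index_b < 1 || birth_index_b >= n_timepoints_b)
    stopf("`birth_index_b` must be in 1..(n_timepoints_b - 1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_timepoints_a = as.integer(n_timepoints_a),
                 n_timepoints_b = as.integer(n_timepoints_b),
                 n_replicates_b = as.integer(n_replicates_b),
                 fractions = fractions, effect_size = effect_size,
                 species_offset_sd = species_offset_sd,
                 n_divergent = as.integer(n_divergent),
                 noise_sd = noise_sd, nb_dispersion = nb_dispersion,
                 background_level = background_level,
                 library_size_sd = library_size_sd,
                 baseline_log2_range = baseline_log2_range,
                 ortholog_fraction = ortholog_fraction,
                 transition_index_a = as.integer(transition_index_a),
                 birth_index_b = as.integer(birth_index_b),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Mean log2 temporal template for a gene class
#'
#' Templates are evaluated on the normalised rank grid
#' `s = (i-1)/(T-1)`, so the same class produces proportionally aligned
#' profiles on two species sampled at different numbers of stages (stage
#' alignment, not absolute age). Monotone classes span exactly
#' `[0, effect_size]`; the peak class is a Gaussian bump rescaled to the
#' same range with a strictly interior maximum; `species_a_late` is zero
#' through `transition` and rises linearly afterwards; `birth_b` equals
#' `effect_size` inside `birth_window` and zero elsewhere; `flat` is
#' constant zero.
#'
#' @param class_label One of `conserved_up`, `conserved_down`,
#'   `conserved_peak`, `species_a_late`, `birth_b`, `flat`.
#' @param timepoints Ordered ages (only their number and order are used);
#'   length >= 2.
#' @param effect_size Amplitude on the log2 scale.
#' @param peak Peak position for `conserved_peak`, as a fraction of the
#'   time course in `(0, 1)`.
#' @param transition Last inactive time index for `species_a_late`.
#' @param birth_window Integer indices of the elevated window for
#'   `birth_b`.
#' @return Numeric vector of log2 mean expression, one entry per time
#'   point.
#' @export
profile_template <- function(class_label, timepoints, effect_size,
                             peak = 0.5, transition = NULL,
                             birth_window = NULL) {
  tt <- length(timepoints)
  if (tt < 2) stopf("need at least 2 time points")
  s <- seq(0, 1, length.out = tt)
  e <- effect_size
  switch(class_label,
    conserved_up = e * s,
    conserved_down = e * (1 - s),
    conserved_peak = {
      if (peak <= 0 || peak >= 1) stopf("`peak` must be in (0, 1)")
      g <- exp(-(s - peak)^2 / (2 * 0.18^2))
      e * (g - min(g)) / (max(g) - min(g))
    },
    species_a_late = {
      tr <- transition %||% ceiling(0.6 * tt)
      if (tr < 1 || tr >= tt) stopf("`transition` must be in 1..(T-1)")
      ifelse(seq_len(tt) <= tr, 0, e * (seq_len(tt) - tr) / (tt - tr))
    },
    birth_b = {
      win <- birth_window %||% (ceiling(tt / 2) + 1):min(ceiling(tt / 2) + 2, tt)
      if (any(win < 1 | win > tt)) stopf("`birth_window` out of range")
      ifelse(seq_len(tt) %in% win, e, 0)
    },
    flat = rep(0, tt),
    stopf("unknown gene class '%s'", class_label)
  )
}

#' Generate a planted two-species developmental time course
#'
#' Draws everything downstream of the configuration under one seed:
#' gene classes (counts are `round(fraction * n_genes)`, remainder to
#' `flat`, assigned in blocks over the gene index), per-gene baselines and
#' peak positions, species offsets on the divergent subset, a count matrix
#' for species A, a replicate intensity matrix for species B, a one-to-one
#' ortholog map over a random `ortholog_fraction` subset of genes, and a
#' truth table labelling every gene.
#'
#' @param config A [simulation_config()].
#' @return A list of class `timecourse_simulation`: `a` and `b`
#'   ([expression_matrix()], raw scale), `orthologs` ([ortholog_map()]),
#'   `truth` (data.frame: `gene`, `gene_a`, `gene_b`, `class`, `peak`,
#'   `offset`, `in_map`), and `config`.
#' @export
generate_timecourse_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n <- cfg$n_genes
  ta <- cfg$n_timepoints_a; tb <- cfg$n_timepoints_b; rb <- cfg$n_replicates_b

  counts <- round(cfg$fractions * n)
  counts["flat"] <- counts["flat"] + (n - sum(counts)) # remainder rule
  if (counts["flat"] < 0) stopf("fraction rounding left no room for flat genes")
  class_vec <- rep(names(counts), counts)
  if (cfg$n_divergent > counts["flat"])
    stopf("`n_divergent` (%d) exceeds the number of flat genes (%d)",
          cfg$n_divergent, counts["flat"])

  base_id <- toupper(sprintf("g%05d", seq_len(n)))
  gene_a <- paste0("A_", base_id)
  gene_b <- paste0("B_", base_id)
  birth_window <- (cfg$birth_index_b + 1):min(cfg$birth_index_b + 2, tb)

  with_seed(cfg$seed, {
    baseline <- runif(n, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
    peaks <- ifelse(class_vec == "conserved_peak", runif(n, 0.25, 0.75), NA)
    flat_idx <- which(class_vec == "flat")
    divergent <- sort(sample(flat_idx, cfg$n_divergent))
    offset <- numeric(n)
    offset[divergent] <- cfg$species_offset_sd *
      sample(c(-1, 1), cfg$n_divergent, replace = TRUE)

    tmpl_a <- matrix(0, n, ta)
    tmpl_b <- matrix(0, n, tb)
    for (i in seq_len(n)) {
      cls <- class_vec[i]
      if (cls == "flat") next
      if (cls %in% c("conserved_up", "conserved_down", "conserved_peak")) {
        tmpl_a[i, ] <- profile_template(cls, seq_len(ta), cfg$effect_size,
                                        peak = peaks[i] %||% 0.5)
        tmpl_b[i, ] <- profile_template(cls, seq_len(tb), cfg$effect_size,
                                        peak = peaks[i] %||% 0.5)
      } else if (cls == "species_a_late") {
        tmpl_a[i, ] <- profile_template(cls, seq_len(ta), cfg$effect_size,
                                        transition = cfg$transition_index_a)
      } else if (cls == "birth_b") {
        tmpl_b[i, ] <- profile_template(cls, seq_len(tb), cfg$effect_size,
                                        birth_window = birth_window)
      }
    }
    # NA peaks arise only for non-peak classes where `peak` is unused
    libsize <- exp(rnorm(ta, 0, cfg$library_size_sd))
    mu_a <- sweep(2^(baseline + tmpl_a + matrix(rnorm(n * ta, 0, cfg$noise_sd), n, ta)),
                  2, libsize, "*")
    vals_a <- matrix(rnbinom(n * ta, mu = mu_a, size = 1 / cfg$nb_dispersion),
                     n, ta)

    log_b <- baseline + tmpl_b[, rep(seq_len(tb), each = rb)] + offset +
      matrix(rnorm(n * tb * rb, 0, cfg$noise_sd), n, tb * rb)
    vals_b <- 2^log_b + cfg$background_level

    in_map <- sort(sample.int(n, round(cfg$ortholog_fraction * n)))
  })

  rownames(vals_a) <- gene_a
  colnames(vals_a) <- sprintf("A_T%02d", seq_len(ta))
  meta_a <- data.frame(sample_id = colnames(vals_a), species = "speciesA",
                       age_label = sprintf("TA%02d", seq_len(ta)),
                       age_order = seq_len(ta), platform = "count",
                       replicate_group = sprintf("A_T%02d", seq_len(ta)),
                       stringsAsFactors = FALSE)

  rownames(vals_b) <- gene_b
  tp_b <- rep(seq_len(tb), each = rb)
  colnames(vals_b) <- sprintf("B_T%02d_R%d", tp_b, rep(seq_len(rb), times = tb))
  meta_b <- data.frame(sample_id = colnames(vals_b), species = "speciesB",
                       age_label = sprintf("TB%02d", tp_b),
                       age_order = tp_b, platform = "intensity",
                       replicate_group = sprintf("B_T%02d", tp_b),
                       stringsAsFactors = FALSE)

  truth <- data.frame(gene = base_id, gene_a = gene_a, gene_b = gene_b,
                      class = class_vec,
                      peak = peaks,
                      offset = offset,
                      in_map = seq_len(n) %in% in_map,
                      stringsAsFactors = FALSE)

  structure(list(
    a = expression_matrix(vals_a, meta_a, scale = "raw", species_tag = "speciesA"),
    b = expression_matrix(vals_b, meta_b, scale = "raw", species_tag = "speciesB"),
    orthologs = ortholog_map(gene_a[in_map], gene_b[in_map]),
    truth = truth, config = cfg),
    class = "timecourse_simulation")
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Produces the package's standard file formats: one expression TSV and
#' one metadata TSV per species, the ortholog map, and the truth table.
#'
#' @param sim A `timecourse_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "timecourse_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(sim$a, file.path(dir, "expr_a.tsv"),
                       file.path(dir, "meta_a.tsv"))
  write_expression_tsv(sim$b, file.path(dir, "expr_b.tsv"),
                       file.path(dir, "meta_b.tsv"))
  write.table(as.data.frame(sim$orthologs), file.path(dir, "orthologs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$offset <- format_num(truth$offset)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
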