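test_that("profile templates have the declared shapes across grids and amplitudes", {
  for (tt in c(4, 7, 9)) {
    for (e in c(2, 3)) {
      up <- profile_template("conserved_up", seq_len(tt), e)
      expect_true(all(diff(up) >= 0))
      expect_equal(diff(range(up)), e)
      down <- profile_template("conserved_down", seq_len(tt), e)
      expect_true(all(diff(down) <= 0))
      expect_equal(diff(range(down)), e)
      pk <- profile_template("conserved_peak", seq_len(tt), e, peak = 0.5)
      am <- which.max(pk)
      expect_gt(am, 1)
      expect_lt(am, tt)
      # unimodal: rises to the peak then falls
      expect_true(all(diff(pk[seq_len(am)]) >= 0))
      expect_true(all(diff(pk[am:tt]) <= 0))
      late <- profile_template("species_a_late", seq_len(tt), e, transition = tt - 2)
      expect_true(all(late[seq_len(tt - 2)] == 0))
      expect_true(all(diff(late[(tt - 2):tt]) > 0))
      bb <- profile_template("birth_b", seq_len(tt), e, birth_window = c(2, 3))
      expect_equal(which(bb > 0), c(2, 3))
      expect_true(all(bb[c(2, 3)] == e))
      expect_equal(profile_template("flat", seq_len(tt), e), rep(0, tt))
    }
  }
})

test_that("peak argmax is strictly interior over the drawn peak range", {
  for (p in seq(0.25, 0.75, by = 0.05)) {
    v <- profile_template("conserved_peak", 1:7, 3, peak = p)
    expect_gt(which.max(v), 1)
    expect_lt(which.max(v), 7)
  }
})

test_that("unknown class labels and bad template arguments are rejected", {
  expect_error(profile_template("nope", 1:5, 2), "unknown gene class")
  expect_error(profile_template("conserved_up", 1, 2), "2 time points")
  expect_error(profile_template("conserved_peak", 1:5, 2, peak = 1.2), "peak")
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(fractions = c(conserved_up = 0.5, flat = 0.5)),
               "must be named exactly")
  bad <- c(conserved_up = 0.2, conserved_down = 0.2, conserved_peak = 0.2,
           species_a_late = 0.2, birth_b = 0.2, flat = 0.1)
  expect_error(simulation_config(fractions = bad), "sum to 1")
  expect_error(simulation_config(n_timepoints_a = 1), "at least 2 time points")
  expect_error(simulation_config(noise_sd = 0), "positive")
  expect_error(simulation_config(ortholog_fraction = 1), "in \\(0, 1\\)")
  expect_error(simulation_config(n_genes = 100, n_divergent = 200), "0..n_genes")
})

test_that("the same config and seed give byte-identical output", {
  cfg <- simulation_config(n_genes = 120, seed = 9, n_divergent = 10)
  s1 <- generate_timecourse_pair(cfg)
  s2 <- generate_timecourse_pair(cfg)
  expect_identical(s1$a$values, s2$a$values)
  expect_identical(s1$b$values, s2$b$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$orthologs, s2$orthologs)
})

test_that("truth-table class counts follow the fractions with remainder to flat", {
  cfg <- simulation_config(n_genes = 1000, seed = 2)
  sim <- generate_timecourse_pair(cfg)
  counts <- table(sim$truth$class)
  expect_equal(sum(grepl("^conserved", sim$truth$class)), 200)
  expect_equal(unname(counts["species_a_late"]), 100, ignore_attr = TRUE)
  expect_equal(unname(counts["birth_b"]), 50, ignore_attr = TRUE)
  expect_equal(unname(counts["flat"]), 650, ignore_attr = TRUE)
  # non-integer products: remainder genes land in flat
  cfg2 <- simulation_config(n_genes = 103, seed = 2, n_divergent = 5)
  sim2 <- generate_timecourse_pair(cfg2)
  expect_equal(nrow(sim2$truth), 103)
  expect_true(all(table(sim2$truth$class) > 0))
})

test_that("count matrix is integer and non-negative; intensities sit above background", {
  sim <- generate_timecourse_pair(simulation_config(n_genes = 150, seed = 4,
                                                    n_divergent = 10))
  expect_true(all(sim$a$values >= 0))
  expect_true(all(sim$a$values == round(sim$a$values)))
  expect_true(all(sim$b$values > sim$config$background_level))
  expect_equal(ncol(sim$b$values),
               sim$config$n_timepoints_b * sim$config$n_replicates_b)
  # divergent offsets have the configured magnitude and live on flat genes
  div <- sim$truth[sim$truth$offset != 0, ]
  expect_equal(nrow(div), 10)
  expect_true(all(abs(div$offset) == sim$config$species_offset_sd))
  expect_true(all(div$class == "flat"))
})

test_that("a flat-only simulation has no temporal trend in the sample means", {
  cfg <- simulation_config(n_genes = 400, seed = 5, n_divergent = 0,
                           fractions = c(conserved_up = 0, conserved_down = 0,
                                         conserved_peak = 0, species_a_late = 0,
                                         birth_b = 0, flat = 1))
  sim <- generate_timecourse_pair(cfg)
  expect_true(all(sim$truth$class == "flat"))
  # species B carries no library-size factor, so its sample means are flat
  slope <- coef(lm(colMeans(log2(sim$b$values - sim$config$background_level)) ~
                     sim$b$samples$age_order))[2]
  expect_lt(abs(slope), 0.05)
})

test_that("simulated datasets round-trip through the TSV writers and readers", {
  sim <- generate_timecourse_pair(simulation_config(n_genes = 60, seed = 6,
                                                    n_divergent = 5))
  dir <- tempfile()
  write_simulation(sim, dir)
  back <- read_expression_tsv(file.path(dir, "expr_a.tsv"),
                              file.path(dir, "meta_a.tsv"))
  expect_equal(back$values, sim$a$values, tolerance = 1e-9)
  expect_equal(back$samples$replicate_group, sim$a$samples$replicate_group)
  map <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
  expect_equal(nrow(map), nrow(sim$orthologs))
})
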