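centered_pair <- function(seed = 1, n_genes = 6) {
  vals_a <- with_seed(seed, matrix(rnorm(n_genes * 4, 5), n_genes, 4))
  dimnames(vals_a) <- list(paste0("A_G", seq_len(n_genes)), paste0("a", 1:4))
  a <- expression_matrix(vals_a, make_meta(paste0("a", 1:4), species = "spA"),
                         scale = "log")
  vals_b <- with_seed(seed + 1, matrix(rnorm(n_genes * 6, 8), n_genes, 6))
  dimnames(vals_b) <- list(paste0("B_G", seq_len(n_genes)), paste0("b", 1:6))
  b <- expression_matrix(vals_b, make_meta(paste0("b", 1:6), species = "spB",
                                           platform = "intensity"),
                         scale = "log")
  list(a = center_genes_by_species(a), b = center_genes_by_species(b))
}

test_that("ortholog combination joins centered rows across species", {
  p <- centered_pair()
  map <- ortholog_map(paste0("A_G", 1:3), paste0("B_G", 1:3))
  comb <- combine_by_orthologs(p$a, p$b, map)
  expect_equal(dim(comb), c(3L, 10L))
  expect_equal(rownames(comb$values)[1], "A_G1|B_G1")
  expect_equal(comb$species_tag, "combined")
  # per-species row means stay zero after the column subset
  for (sp in c("spA", "spB"))
    expect_true(all(abs(rowMeans(comb$values[, comb$samples$species == sp])) < 1e-9))
})

test_that("pairs missing from a matrix are dropped; bad inputs are rejected", {
  p <- centered_pair()
  map <- ortholog_map(c("A_G1", "A_G2", "A_G99"), c("B_G1", "B_G2", "B_G3"))
  expect_message(comb <- combine_by_orthologs(p$a, p$b, map), "dropped 1")
  expect_equal(nrow(comb$values), 2L)
  none <- ortholog_map("A_G98", "B_G99")
  expect_error(combine_by_orthologs(p$a, p$b, none), "no ortholog pair")
  raw_a <- make_mat(matrix(1:8, 2, 4), gene_ids = c("A_G1", "A_G2"), scale = "log")
  expect_error(combine_by_orthologs(raw_a, p$b, map), "log_centered")
})

test_that("PCA satisfies the rank and energy identities", {
  p <- centered_pair(seed = 3, n_genes = 12)
  # 2 samples in one species -> after centering, rank 1
  vals <- p$a$values[, 1:2]
  m2 <- expression_matrix(vals, p$a$samples[1:2, ], scale = "log")
  m2 <- center_genes_by_species(m2)
  res2 <- pca(m2)
  expect_equal(length(res2$variance_explained), 1L)
  expect_equal(res2$variance_explained, 1)
  # energy conservation and orthonormal loadings
  res <- pca(p$a)
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  gram <- crossprod(res$loadings)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("an excess component request is truncated with a message", {
  p <- centered_pair(seed = 4, n_genes = 10)
  expect_message(res <- pca(p$a, n_components = 99), "truncated")
  expect_lte(ncol(res$scores), 4L)
})

test_that("loading retrieval respects thresholds and component sign", {
  p <- centered_pair(seed = 5, n_genes = 10)
  res <- pca(p$a)
  expect_message(none <- retrieve_pc_loading_genes(res, 1, threshold = 1.1),
                 "no \\|loading\\|")
  expect_equal(nrow(none), 0L)
  got <- retrieve_pc_loading_genes(res, 2, threshold = 0.05)
  flipped <- res
  flipped$loadings[, 2] <- -flipped$loadings[, 2]
  got2 <- retrieve_pc_loading_genes(flipped, 2, threshold = 0.05)
  expect_setequal(got$gene_id, got2$gene_id)
  expect_true(all(diff(abs(got$loading)) <= 1e-12))
  expect_error(retrieve_pc_loading_genes(res, 99), "out of range")
})

test_that("the shipped default phase map places opossum day 3 in early development", {
  mapping <- yaml::read_yaml(system.file("extdata", "phase_map_default.yaml",
                                         package = "xdevo"))
  ids <- c("o1", "o2", "o3", "o4", "o5", "o6", "o7")
  meta <- make_meta(ids, species = "monodelphis")
  meta$age_label <- c("D3", "D8", "D14", "D29", "D35", "D63", "ADULT")
  ph <- assign_phases(meta, mapping)
  expect_equal(as.character(ph$phase[ph$sample_id == "o1"]), "early")
  expect_equal(as.character(ph$phase), c("early", "early", "early",
                                         "intermediate", "intermediate",
                                         "late", "late"))
})

test_that("phase assignment validates coverage per species", {
  meta <- make_meta(c("s1", "s2", "s3"), species = "spX")
  meta$age_label <- c("D3", "D8", "D99")
  mapping <- list(spX = list(early = "D3", intermediate = "D8", late = "D14"))
  expect_error(assign_phases(meta, mapping), "s3")
  mapping2 <- list(spX = list(early = c("D3", "D8", "D99")))
  expect_error(assign_phases(meta, mapping2), "lacks samples")
})

test_that("rank-tercile phases split seven stages 3/2/2 and cover replicates", {
  sim <- generate_timecourse_pair(simulation_config(n_genes = 60, seed = 2,
                                                    n_divergent = 0))
  ph <- default_phase_map(sim$b)
  tab <- table(ph$phase) / sim$config$n_replicates_b
  expect_equal(as.integer(tab), c(3L, 2L, 2L))
})

test_that("phase averaging is the arithmetic mean of member samples", {
  vals <- matrix(c(1, 3, 2, 4, 10, 20), 1, 6,
                 dimnames = list("G1", paste0("s", 1:6)))
  meta <- make_meta(paste0("s", 1:6), species = "spA")
  m <- expression_matrix(vals, meta, scale = "log")
  mapping <- list(spA = list(early = c("T1", "T2"), intermediate = c("T3", "T4"),
                             late = c("T5", "T6")))
  ph <- assign_phases(meta, mapping)
  avg <- phase_average(m, ph)
  expect_equal(unname(avg$spA["G1", ]), c(2, 3, 15))
  expect_equal(colnames(avg$spA), c("early", "intermediate", "late"))
})

test_that("conservation classes follow the fixed correlation thresholds", {
  a <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 3), p3 = c(1, 2, 3))
  b <- rbind(p1 = c(2, 4, 6), p2 = c(3, 2, 1), p3 = c(2, 2, 2))
  ct <- ortholog_profile_correlation(a, b)
  expect_equal(ct$class, c("conserved_strict", "not_conserved", "undefined"))
  expect_equal(ct$cor[1], 1)
  expect_equal(ct$cor[2], -1)
  expect_true(is.na(ct$cor[3]))
  expect_error(ortholog_profile_correlation(a, b[c(2, 1, 3), ]), "row identity")
})

test_that("cor > 0.8 over three phases is the documented angular condition", {
  with_seed(31, {
    for (i in 1:50) {
      x <- rnorm(3); y <- rnorm(3)
      cx <- x - mean(x); cy <- y - mean(y)
      angle <- acos(pmin(pmax(sum(cx * cy) /
                                sqrt(sum(cx^2) * sum(cy^2)), -1), 1))
      ct <- ortholog_profile_correlation(rbind(p = x), rbind(p = y))
      expect_equal(ct$class == "conserved_strict" | ct$class == "conserved",
                   angle < acos(0.8))
    }
  })
})

test_that("strict conservation is nested and the DE mask restricts the counts", {
  a <- rbind("GA1|GB1" = c(1, 2, 3), "GA2|GB2" = c(1, 2, 3.2),
             "GA3|GB3" = c(3, 2, 1))
  b <- a + 0.01
  rownames(b) <- rownames(a)
  de_a <- data.frame(gene_id = c("GA1", "GA2", "GA3"),
                     significant = c(TRUE, FALSE, TRUE))
  de_b <- data.frame(gene_id = c("GB1", "GB2", "GB3"),
                     significant = c(TRUE, TRUE, TRUE))
  ct <- ortholog_profile_correlation(a, b, de_a, de_b)
  expect_equal(ct$de_both, c(TRUE, FALSE, TRUE))
  counts <- conservation_counts(ct, c(0.8, 0.9))
  expect_equal(unname(counts["n_screened"]), 2)
  expect_lte(counts[["cor_gt_0.9"]], counts[["cor_gt_0.8"]])
  strict <- ct$class == "conserved_strict"
  expect_true(all(ct$cor[strict] > 0.8)) # strict subset of conserved
})
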