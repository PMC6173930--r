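write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

meta_lines <- c("sample_id\tspecies\tage_label\tage_order\tplatform\treplicate_group",
                "S1\tsp1\tD3\t1\tcount\tS1",
                "S2\tsp1\tD8\t2\tcount\tS2")

test_that("a well-formed expression TSV parses with metadata joined", {
  ep <- write_tsv_fixture(c("gene_id\tS1\tS2",
                            "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"))
  mp <- write_tsv_fixture(meta_lines)
  mat <- read_expression_tsv(ep, mp)
  expect_s3_class(mat, "ExpressionMatrix")
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(rownames(mat$values), c("G1", "G2", "G3")) # upper-cased
  expect_equal(mat$samples$age_label, c("D3", "D8"))
  expect_equal(mat$scale, "raw")
})

test_that("duplicated gene rows collapse to the per-sample mean with a warning", {
  ep <- write_tsv_fixture(c("gene_id\tS1\tS2",
                            "GENE1\t1\t2", "gene1\t3\t6", "G2\t5\t6"))
  mp <- write_tsv_fixture(meta_lines)
  expect_warning(mat <- read_expression_tsv(ep, mp), "collapsed")
  expect_equal(dim(mat)[1], 2L)
  expect_equal(unname(mat$values["GENE1", ]), c(2, 4))
})

test_that("header samples missing from metadata are named in the error", {
  ep <- write_tsv_fixture(c("gene_id\tS1\tS9", "g1\t1\t2"))
  mp <- write_tsv_fixture(meta_lines)
  expect_error(read_expression_tsv(ep, mp), "S9")
})

test_that("non-numeric cells are rejected with coordinates", {
  ep <- write_tsv_fixture(c("gene_id\tS1\tS2",
                            "g1\t1\t2", "g2\tabc\t4"))
  mp <- write_tsv_fixture(meta_lines)
  err <- tryCatch(read_expression_tsv(ep, mp), error = conditionMessage)
  expect_match(err, "abc")
  expect_match(err, "G2")
  expect_match(err, "S1")
})

test_that("missing cells are rejected by default and imputable on request", {
  ep <- write_tsv_fixture(c("gene_id\tS1\tS2",
                            "g1\t1\tNA", "g2\t3\t4"))
  mp <- write_tsv_fixture(meta_lines)
  expect_error(read_expression_tsv(ep, mp), "missing value")
  expect_warning(mat <- read_expression_tsv(ep, mp, impute_missing = TRUE),
                 "imputed")
  expect_equal(unname(mat$values["G1", ]), c(1, 1))
})

test_that("write(read(x)) is byte-idempotent on canonical files", {
  sim <- generate_timecourse_pair(simulation_config(n_genes = 40, seed = 3,
                                                    n_divergent = 4))
  p1 <- tempfile(); m1 <- tempfile()
  write_expression_tsv(sim$b, p1, m1)
  back <- read_expression_tsv(p1, m1)
  p2 <- tempfile()
  write_expression_tsv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ortholog maps enforce strict one-to-one pairing", {
  ok <- write_tsv_fixture(c("gene_a\tgene_b", "a1\tb1", "a2\tb2"))
  expect_equal(nrow(read_ortholog_map(ok)), 2L)
  amb_a <- write_tsv_fixture(c("gene_a\tgene_b", "a1\tb1", "a1\tb2"))
  expect_warning(m <- read_ortholog_map(amb_a), "ambiguous")
  expect_equal(nrow(m), 0L)
  amb_b <- write_tsv_fixture(c("gene_a\tgene_b", "a1\tb1", "a2\tb1"))
  expect_warning(m <- read_ortholog_map(amb_b), "ambiguous")
  expect_equal(nrow(m), 0L)
  empty <- write_tsv_fixture("gene_a\tgene_b")
  expect_error(read_ortholog_map(empty), "empty")
})

test_that("two-leaf trees serialise to the canonical Newick form", {
  tree <- cluster_tree(labels = c("A", "B"),
                       merge = matrix(c(-1L, -2L), 1),
                       height = 0.5)
  f <- tempfile()
  write_newick_annotated(tree, f)
  expect_equal(readLines(f), "(A:0.5,B:0.5);")
})

test_that("internal nodes carry AU|BP percentage labels", {
  tree <- cluster_tree(labels = c("A", "B", "C"),
                       merge = rbind(c(-1L, -2L), c(-3L, 1L)),
                       height = c(0.2, 0.8),
                       support = data.frame(node = 1, au = 0.95, bp = 0.90))
  f <- tempfile()
  write_newick_annotated(tree, f)
  expect_match(readLines(f), "95|90", fixed = TRUE)
  # an independent parser sees the same branch lengths
  phy <- ape::read.tree(f)
  expect_equal(sort(phy$edge.length), sort(c(0.2, 0.2, 0.6, 0.8)))
})

test_that("annotated Newick round-trips topology, heights and support", {
  m <- with_seed(11, matrix(rnorm(8 * 30), 30, 8,
                            dimnames = list(paste0("g", 1:30), LETTERS[1:8])))
  tree <- multiscale_bootstrap_support(m, "samples", scales = c(0.7, 1, 1.3),
                                       n_boot = 100, seed = 2)
  f <- tempfile()
  write_newick_annotated(tree, f)
  back <- read_newick_annotated(f)
  expect_equal(sort(back$height), sort(tree$height), tolerance = 1e-9)
  expect_setequal(vapply(clades(back), paste, "", collapse = ","),
                  vapply(clades(tree), paste, "", collapse = ","))
  # support survives as rounded percentages
  orig <- tree$support[order(tree$support$leafset), ]
  got <- back$support[!is.na(back$support$au), ]
  expect_equal(nrow(got), nrow(orig))
})

test_that("unlabeled leaves are rejected", {
  tree <- cluster_tree(labels = c("A", ""),
                       merge = matrix(c(-1L, -2L), 1), height = 1)
  expect_error(write_newick_annotated(tree, tempfile()), "labelled")
})
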