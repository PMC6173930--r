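Package: xdevo
Title: Cross-Species Developmental Time-Course Transcriptome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing developmental time-course transcriptomes
    between species measured on different platforms (RNA-seq counts versus
    microarray intensities). Implements an intensity-difference screen for
    temporal differential expression, the cross-platform normalisation chain
    (log transform, background correction, sample centering, per-species
    per-gene centering, replicate averaging), correlation-distance
    complete-linkage clustering with multiscale-bootstrap clade support
    (bootstrap probability and approximately unbiased p-values), k-means
    temporal profile clustering, ortholog-based integration with combined
    principal component analysis and loading-based retrieval of
    species-differential genes, and a phase-averaged correlation screen for
    conserved temporal profiles. Ships a synthetic two-species time-course
    generator with planted, labelled structure so every stage can be
    validated against ground truth, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
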