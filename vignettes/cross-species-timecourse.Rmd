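---
title: "Comparing developmental transcriptomes across species and platforms"
author: "xdevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing developmental transcriptomes across species and platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdevo)
```

## The problem

Marsupials are born with immature lungs and complete most of lung
organogenesis after birth, whereas eutherians such as the mouse do the
equivalent work in utero. Comparing the two developmental programs means
comparing a postnatal RNA-seq time course in one species against embryonic
and perinatal microarray time courses in another: different species,
different platforms (counts versus log intensities), different numbers of
stages, and different absolute ages. `xdevo` implements the analysis chain
for exactly this setting: screen each species for temporally differential
genes, align the platforms by a shared normalisation, join the species over
one-to-one orthologs, and then ask which temporal profiles are conserved,
which genes separate the species, and how well-supported the co-clustering
of developmental stages is.

Every stage is also exercised against a synthetic two-species generator
with planted, labelled structure, so the pipeline's operating
characteristics (sensitivity, specificity, calibration, support values)
can be measured rather than assumed.

## The normalisation chain

Cross-platform comparability is obtained exactly as in cross-platform
expression practice: raw values are log2-transformed with a pseudocount
(`log_transform`, default pseudocount 1 on normalised counts), a
per-sample background floor is removed, samples are centered on mean zero
to align the distributions, and finally each gene is centered on its mean
*independently within each species* (`center_genes_by_species`). After the
last step only temporal variation remains; platform- and species-level
location is gone.

Two estimators in this chain are deliberately pinned down so results are
bit-reproducible:

* **Background correction** subtracts each sample's 5th percentile
  (quantile type 7, linear interpolation between order statistics). A
  low-quantile location shift aligns the platform floors of count- and
  intensity-derived log data without distorting within-sample rank order.
  No clipping is applied, because centering follows.
* **Replicate averaging** (`average_replicates`) is the arithmetic mean of
  replicate columns, applied before cross-species integration so each time
  point contributes one column per species.

The chain enforces its own order (`raw -> log -> background ->
center-samples -> center-genes`); applying a step out of order raises an
error rather than silently producing a differently-scaled matrix.

## The intensity-difference screen

Differential expression over a developmental time course is screened
without a count model: a gene's between-group difference is judged against
the *empirical* distribution of differences among genes of similar average
intensity. For each pair of time-point groups and each gene, the
`w = max(50, round(0.01 * n_genes))` genes nearest in average-intensity
rank (a symmetric window, clipped at the ends of the ranking, including
the gene itself) provide the mean and SD of the differences; the gene's
z-score and two-sided normal p-value follow. Per gene, the p-values are
combined by the minimum over group pairs — a gene differential anywhere in
the time course is of interest — and Benjamini–Hochberg adjustment is
applied once, across genes, to the combined statistic, with significance
at adjusted p < 0.05.

Properties worth knowing before relying on the screen:

* The min-p combination is anti-conservative under the global null when
  there are many group pairs (21 pairs for seven stages), so a handful of
  null genes per thousand can pass even in structure-free data. The BH
  step is applied to the combined statistic as a ranking device, exactly
  as specified, not as a calibrated FDR guarantee across pairs.
* With a window of 50 the window SD itself carries ~10% estimation error,
  which widens the z-score distribution of true positives by about 0.4.
  Genes sitting at exactly four within-window SDs are therefore recovered
  at roughly 80%, not near-certainly; the acceptance suite measures this
  honestly.
* The empirical null *includes whatever is differential*. When a large
  fraction of genes share a temporal program (30% in the default synthetic
  study), that program inflates the window SDs for precisely the group
  pairs where it is strongest, and power drops. This self-masking is
  inherent to intensity-difference screening and is the reason the screen
  is best suited to datasets where differential genes are a small
  minority.
* A `vs-rest` mode (each group against the pooled others) is provided
  alongside the default `pairwise` mode, since either grouping is a
  defensible reading of "differential at specific time points".

## Clustering and multiscale-bootstrap support

Samples (or genes) are clustered agglomeratively with correlation distance
`d = 1 - r` and complete linkage. The agglomeration is implemented with
the Lance–Williams maximum update and a deterministic tie rule (the
lowest-index pair merges first), which makes trees invariant to leaf input
order; on tie-free data it agrees with `stats::hclust` to numerical
precision, and the test suite checks both that agreement and an
independent brute-force reference.

Clade support is computed by multiscale bootstrap: for scales
`r in {0.5, ..., 1.4}` (ten scales, always including 1), `n_boot`
replicates resample `round(r * n_features)` features with replacement and
recluster; a clade's bootstrap probability at scale r (BP_r) is the
fraction of replicates containing the identical leaf set. The
approximately unbiased p-value comes from the standard two-parameter
curve: psi_r = qnorm(1 - BP_r) is regressed on (sqrt(r), 1/sqrt(r)) by
weighted least squares with binomial variance weights, giving signed
distance `v` and curvature `c`; then `AU = 1 - pnorm(v - c)` and the
model BP at r = 1 is `1 - pnorm(v + c)`.

Numerical choices: BP values are clipped to
`[1/(n_boot+1), 1 - 1/(n_boot+1)]` before the quantile transform; scales
whose raw BP is exactly 0 or 1 carry no quantile information and are
excluded from the fit; and when fewer than two usable scales remain the
fit is flagged degenerate and AU falls back to the BP at r = 1. The
fallback matters: a clade recovered in *every* replicate at *every* scale
should report AU = 1, whereas a forced constant-psi fit would split the
constant arbitrarily between `v` and `c` and report a meaningless AU near
0.5. Replicate index streams are derived per (seed, scale index,
replicate), so streams are independent across scales and any replicate can
be regenerated in isolation. Items that become constant within a replicate
are dropped for that replicate only. The root clade is trivially supported
and excluded from the support table.

Temporal profile clusters use `kmeans_profiles`: gene profiles are
z-scored (shape, not level), partitioned by Lloyd's algorithm with the
best of `n_restarts` seeded initialisations by within-cluster sum of
squares, and an empty-cluster initialisation is retried from a
farthest-point start. The pipeline default is k = 4, the number of major
temporal patterns distinguished in this setting (late/alveolar rise,
mid/saccular peak, early decline, early peak).

## Cross-species integration and the two centering views

Orthologs are joined strictly one-to-one (`read_ortholog_map` drops every
pair touched by an ambiguous identifier), and the combined matrix carries
both species' samples with their metadata.

PCA is the SVD of the genes-by-samples grid with samples as observations;
the input must already be gene-centered and no further centering is
applied inside. Two centering views serve two different questions:

* **Per-species centering** (the published normalisation) removes all
  species-level location. This is the right view for shared-program
  structure: the first component tracks developmental age across both
  species. But it makes each species' scores sum to exactly zero on every
  component — a species with all-positive scores on some axis is
  *mathematically impossible* in this view — so it cannot exhibit a
  species-separating component.
* **Global centering** (each gene centered across all samples) preserves
  constant species offsets, and it is in this view that a leading
  component separates the species by score sign and genes with large
  absolute loadings on that component are the species-differential
  candidates (`retrieve_pc_loading_genes`, default threshold 0.04 on
  unit-norm loadings, so the threshold has a defined scale).

The pipeline computes both. Components are made deterministic by flipping
each one so its largest-magnitude loading is positive.

## The conservation screen

Each species' time course is collapsed to early / intermediate / late
phase means. The phase map is explicit configuration, not re-derived from
clustering, so the stage is deterministic; the shipped default encodes the
published opossum/mouse grouping (opossum D3/D8/D14 early, D29/D35
intermediate, D63/adult late, with the mouse stages grouped accordingly),
and `default_phase_map` produces the equivalent rank-tercile split (3/2/2
for seven stages) for arbitrary inputs. Pearson correlation over the three
matched phase means classifies each ortholog pair: `conserved_strict`
(r > 0.9), `conserved` (r > 0.8), `not_conserved`, or `undefined` when a
profile has zero variance.

A three-point correlation has blunt geometry: after centering, each
profile is a direction in a plane, r > 0.8 is the angular condition
"angle < arccos(0.8) = 36.9 degrees", and a pure-noise profile lands there
with probability arccos(0.8)/pi = 0.205 *regardless of the noise
magnitude*. A bare r > 0.8 screen therefore runs a ~20% false-positive
rate on genes with no real temporal signal in one species, and its
specificity cannot exceed ~0.8 on such negatives. The published procedure
controls this channel by screening only genes differentially expressed in
*both* species; `ortholog_profile_correlation` takes the two DE result
sets as an optional mask and the pipeline reports its conserved counts on
that masked set. A full-profile correlation mode (all matched time points
rather than three phase means) is available through `phase_average` on
finer phase maps for sensitivity analysis.

## The synthetic study

`simulation_config()` defines the generator defaults as the study design
the package emulates: species A sampled at 7 ordered stages with one
animal each on a count platform, species B at 7 stages with 3 replicate
animals on an intensity platform. Gene classes and their default
fractions: conserved rising / falling / peaked programs (7% / 7% / 6%),
species-A-specific late activation (10%, muscle-like, activating after
stage 4 of 7), species-B-specific elevation in the two earliest postnatal
stages (5%, birth-linked), and flat genes (65%); rounding remainders go to
`flat`. Temporal templates are evaluated on each species' normalised rank
grid — stage alignment, not absolute age — with amplitude `effect_size`
(default 2 on the log2 scale). Conserved-peak positions are drawn
uniformly in the middle half of the course so the maximum is strictly
interior.

Noise: per-observation log2 noise SD 0.3; species A counts are negative
binomial (dispersion 0.02) around `2^(baseline + template)` scaled by
lognormal per-sample library sizes (sigma = 0.2); species B intensities
are lognormal with an additive background of 16; baselines are uniform on
log2 in [5, 10] so the intensity-difference windows are exercised across
the expression range. The magnitudes are configuration, not claims about
any real dataset: the published studies do not state their noise levels,
and these values sit in the range a bulk RNA-seq / microarray practitioner
would call typical.

Species-level offsets are planted on a divergent subset of 50 flat genes
with *fixed* magnitude `species_offset_sd` (default 1) and random sign —
fixed-magnitude planting is the standard convention for effect-size
benchmarks (as with the screen's own "+4 SD" planted differences), and it
keeps "planted" meaningful: Gaussian offsets would leave a quarter of the
planted genes below the detection noise floor by construction. Offsets
live on flat genes so the species-offset program is not confounded with
temporal programs. The ortholog map covers 90% of genes, so recovery is
always evaluated within the mapped subset — an unmapped gene is invisible
to any ortholog-based screen by definition.

What the generator does *not* emulate: read-level sequencing artifacts,
probe-level microarray physics, batch effects beyond the platform offset,
correlated gene modules beyond the planted classes, and genes expressed
near zero. Passing tests therefore demonstrate that the implementation
recovers the structure it models, under realistic noise, at desk scale —
not that the biological conclusions of any particular study are correct.

## Reproducibility machinery

A single global seed drives everything. `substream_seed(seed, label,
index)` expands it into named streams (simulation, k-means, each
bootstrap scale and replicate), so stages can be re-run in isolation with
identical randomness, and `with_seed` restores the caller's RNG state.
All writers use fixed `%.10g` numeric formatting and no timestamps, so
re-running a configuration byte-reproduces every output file. Problem
sizes used throughout the test suite — 1000-gene studies, 2000-gene
null calibrations, bootstrap with 100 replicates in tests and 1000 in the
pipeline default — were chosen so each check completes in seconds to a
couple of minutes while leaving Monte-Carlo margins well inside the
asserted tolerances.

## Known limitations

* The intensity-difference screen loses power as the differential
  fraction grows (self-masking of the empirical null) and its window SD
  estimation noise caps sensitivity for borderline effects; both are
  measured and documented in the acceptance suite rather than hidden.
* Three-point phase correlation cannot be specific against noise-backed
  profiles (the angular null above); use the DE-in-both mask or the
  full-profile mode when specificity matters.
* The additive intensity background compresses apparent fold-changes for
  weakly expressed genes (a signal at half the background level loses
  roughly half of a planted log2 offset), and the per-sample quantile
  shift cannot undo that compression — so loading-based retrieval of
  species-differential genes is least sensitive exactly where microarray
  measurements are least reliable. The generator reproduces this
  deliberately.
* Clade identity is exact leaf-set equality; near-identical clades (one
  leaf swapped) receive no partial credit.
* The one-to-one ortholog rule discards genuinely many-to-many
  orthology; that is a deliberate scope choice, not an inference.
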