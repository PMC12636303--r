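---
title: "Comparing single-nucleus atlases across species and regions"
author: "atlasCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-nucleus atlases across species and regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasCompare)
```

## The problem

Deep single-nucleus atlases of homologous tissue — say, human and mouse
lumbar spinal cord, or human cervical and lumbar segments — raise three
comparative questions. First, which transcriptomic neuron types are
*orthologous*, i.e. recognizable in both datasets after the species- and
chemistry-specific structure is removed? Second, given a matched set of
types, does their *prevalence* differ between the datasets? Third, within
matched types, how *conserved* is the expression of genes that matter for
translation, in particular cell-surface proteins that are candidate drug
targets? atlasCompare implements one coherent, fully testable pipeline for
these questions, together with the surrounding conventions (QC,
normalization, marker detection, signature scoring, spatial gating) and a
synthetic data generator that makes every stage verifiable against planted
ground truth without access to any real dataset.

## Data model

A `CountAtlas` extends `SingleCellExperiment`: raw integer counts
(genes × cells, sparse), gene annotation with a mitochondrial flag derived
from the symbol prefix (`MT-` human, `mt-` mouse; the prefix list is a
parameter because mitochondrial gene sets are a naming convention, not a
biological constant), and cell annotation with donor, sex, region, dataset
and an optional prior type label. Two derived layers exist: `normalized`
(an assay, same shape as counts) and a feature-restricted dense `scaled`
matrix. The scaled layer lives in `metadata()` because it deliberately has
fewer rows than the object; consequently it does **not** follow
subsetting, and every consumer (`findAnchors`) checks that its columns
match the atlas and recomputes otherwise.

## QC and normalization

`filterQC()` applies three rules in a fixed order: genes detected in fewer
than 3 cells are dropped; cells with ≤ 200 detected genes are dropped (the
object-creation filter); then cells are kept only with > 500 detected
genes and < 5% mitochondrial reads (the analysis-stage filter). The
defaults are the conventions for atlas-scale data; all four thresholds are
parameters, and the examples in this package scale them down for toy
matrices. Filtering is idempotent in the regime it is meant for — when QC
removes a small fraction of cells, no retained gene falls back below the
detection threshold. Under aggressive thresholds that remove a large share
of cells, a second application can drop a handful of genes; the function
intentionally does not iterate to a fixed point because the rules are
defined as a single ordered pass.

`logNormalize()` is fixed as library-size scaling to 10,000 counts
followed by `ln(1 + x)`; the procedure is stated only loosely in the
conventions this package follows, and this is the ecosystem default the
rest of the settings imply. Zeros map exactly to zeros, so the sparsity
pattern is preserved. `scaleFeatures()` z-scores per gene with the n−1
standard deviation, sets zero-variance genes to 0, and clips only from
above at +10 — matching the default behavior of the tooling these
conventions come from.

## Variable features and anchors

`selectVariableFeatures()` implements the standardized-variance (vst)
ranking: a loess curve (span 0.3) of log10 variance on log10 mean over all
genes, per-gene standardization by the mean and the curve-predicted
standard deviation, clipping at √n_cells, and ranking by the variance of
the clipped values with ties broken by gene id so the order is total and
reproducible.

`findAnchors()` builds a canonical-correlation embedding from the SVD of
the cross-product of the two scaled feature matrices, keeps `dims`
components (default 10), and L2-normalizes rows. The truncated SVD uses
irlba with a tight tolerance (1e−9): at the default tolerance the left and
right singular vectors of a near-symmetric cross-product (e.g. a dataset
against a copy of itself) differ by ~1e−6, which is enough to scramble
nearest neighbors among near-duplicate cells. Candidate anchors are
mutual nearest neighbors across datasets (k_anchor = 5); anchors whose
partner is not among the k_filter = 200 nearest neighbors in the scaled
feature space are discarded; survivors are scored by shared-neighbor
overlap among k_score = 30 embedding neighbors, min–max rescaled between
the 1st and 90th percentile and clipped to [0, 1]. When the score
quantiles coincide (degenerate small inputs) all scores are set to 1
rather than dividing by zero. Neighbor searches are exact brute-force
scans — at desk scale (thousands of cells) this is both fast and free of
approximation error, and it is what the test suite's O(n²) oracles verify
against.

`integrateExpression()` leaves the reference unchanged and corrects each
query cell by a weighted average of anchor difference vectors (reference
minus query, over the full requested gene set): weights are a Gaussian
kernel on embedding distance to the cell's 100 nearest anchors with
bandwidth equal to the distance to the furthest of them, multiplied by
anchor scores; an all-zero weight vector falls back to uniform weights so
the correction never fails. Two-step designs (integrate regions first,
then species) compose naturally because the corrected output is a valid
input matrix.

## Clustering, labeling, prevalence

`clusterGraph()` takes the top principal components of the corrected
matrix (centered, not re-scaled — corrected values are already on a
comparable footing), builds a shared-nearest-neighbor graph with Jaccard
weights over k = 20 neighborhoods (self-inclusive, pruned below 1/15), and
runs Leiden modularity optimization. Labels are renumbered 0..K−1 by
decreasing size, ties broken by the smallest original community id; with a
fixed seed the labeling is deterministic and invariant (up to renaming) to
cell order. Two presets bundle the conventions: `within_dataset`
(2000 variable features, anchor dims 1:10, 15 PCs, resolution 1) and
`cross_species` (7500-per-dataset anchor features, 30 PCs, resolution 2).

`transferMajorityLabels()` names a joint cluster after a reference type
only when *strictly more than half* of the reference cells in the cluster
carry that prior label; otherwise the cluster keeps a placeholder
(`JC-<k>`). The boundary is tested exhaustively.

`prevalenceBias()` assumes equal-depth inputs (`equalDepthSubsample()`
downsamples the larger dataset once, uniformly without replacement, before
any per-type computation). For each type it reports the percent of pooled
cells belonging to each dataset, the signed deviation from 50, and the
proportion fold ratio. The spread summary is the standard deviation of
*signed* deviations with the n−1 denominator: the phrase it implements is
ambiguous, the signed reading is the natural one, and it is the choice
under which swapping the datasets negates every deviation while leaving
the summary unchanged (a tested property). The absolute-deviation and
n-denominator variants are emitted alongside for transparency. Threefold
enrichment counts fold ≥ 3 in either direction, including the infinite
folds of types absent from one side; the one-direction count is also
reported.

`donorCompositionTest()` normalizes for each donor's total cells, then
compares female and male donor proportion vectors per cluster with a
two-sided Wilcoxon rank-sum test — exact when both sexes have ≤ 10 donors,
normal approximation with continuity correction otherwise, and p = 1 when
all proportions are tied (the zero-variance case where the approximation
is undefined). Raw p is the primary column; a Benjamini–Hochberg column is
appended.

## Signature scores and per-gene follow-up

`moduleScore()` bins all genes into 24 equal-size bins by average
normalized expression (rank-based, stable ties) and, for each signature
gene, samples 25 controls without replacement from its bin; all signature
genes are excluded from control pools to avoid self-cancellation. The
score is the mean signature expression minus the mean over the pooled
controls (duplicates kept, so each signature gene's pool carries equal
weight). The defaults follow the reading of "compared to randomly selected
genes of similar expression level" as 25 controls *per signature gene*;
`ctrl_total = TRUE` implements the alternative reading (25 controls in
total). Scores are seeded and reproducible, invariant to adding a constant
to every gene, and near zero for random sets on a null atlas.
`scoreGroupTest()` is a two-sided Wilcoxon on per-cell scores;
`perGeneGroupDE()` applies the marker-detection fold-change and test
machinery to an explicit gene list without the detection or fold-change
filters.

## Conservation of surface genes

`pseudobulk()` aggregates raw counts per type and divides by the type's
cell count — raw counts, not the normalized layer, because the quantity is
defined on aggregated counts. `variableSurfacePanel()` intersects each
dataset's top-200 standardized-variance ranking with a user-supplied
surface-protein list (the list is an input, not a bundled database: such
lists are versioned external resources) and unions across datasets.
`conservationCorrelations()` computes per-type Spearman ρ over the panel
with average ranks for ties; a constant row yields NA, and types with NA
are dropped and reported rather than silently imputed.
`compareConservation()` reports the Welch two-tailed t-test as primary —
equal variances are not assumable between a within-species and a
cross-species comparison — with the Student variant alongside.

## Spatial gating

`gatePopulation()` selects cells with at least `min_count = 3` transcripts
of *every* marker of a population and of the gate gene (RBFOX3, to
exclude non-neuronal cells); "at least 3" and "more than two" are the same
threshold and the gate gene is held to it as well. Markers listed as
male-only (e.g. the Y-linked USP9Y) are skipped — and may be absent as
columns — in female samples. Gating is conjunctive by default; a
disjunctive mode exists behind a flag. Monotonicity in the threshold and
exact agreement with a per-cell loop are tested.

## The synthetic generator

`simulateAtlas()` draws negative-binomial counts with gene means
`exp(base + ln2·log2FC·marker + mito_boost + surface_jitter)` scaled by a
per-cell lognormal library factor. One shared dispersion (`size`
parameter; variance = μ + μ²/size) is the simplest model with the
overdispersion the analysis assumes, and `size = 1e9` recovers the Poisson
limit used in tests. Defaults describe a plausible desk-scale nucleus
prep: ~2% mitochondrial genes with a modest (+0.5 natural-log) expression
boost so most cells sit near 2% mitochondrial reads with a tail crossing
the 5% QC cut; 10% surface genes; lognormal library factors with σ = 0.3;
donors assigned round-robin (≥ 4 per dataset) alternating F/M so the
sex-composition test has a clean null, with sex-specific clusters planted
by zeroing a type's proportion in one sex's donors. Cross-dataset
divergence is planted as per-dataset lognormal jitter of surface-gene
means; at jitter σ = 0.5 the induced shift is ≈ 0.15 of a gene's
normalized-expression standard deviation — a moderate batch effect.
`simulateOrthologTable()` plants exact quotas of unmapped and one-to-many
genes by construction (a seeded shuffle, then deterministic renaming), so
exclusion counts are integers known in advance.
`simulateSpatialCells()` gives population members Poisson(λ_high = 8)
marker counts and everyone else Poisson(λ_low = 0.2); with the ≥ 3 gate on
two markers plus the gate gene, expected recall is 0.986³ ≈ 0.959 and
precision is essentially 1.

What the generator does *not* emulate: ambient RNA, doublets, dataset-
specific dropout curves, spatial segmentation errors, or donor-specific
gene effects (donor effects are library-size-only by default). Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted structure under clean noise — not robustness to
every artifact of real tissue.

## Problem sizes and numerical choices

The test suite runs the component checks on matrices from 20 × 12 up to a
few hundred cells, and the end-to-end check on two datasets of 3,000 cells
× 2,000 genes with 12 types — a size at which every brute-force oracle is
still exact and the full pipeline completes in a few minutes on one CPU;
the same configuration backs `scripts/acceptance.R`. Integration fixtures
use three types with 20 markers each (types differing in ~4% of genes —
realistic separation for neuron classes; with types differing in only 2%
of genes, anchor purity drops to ~0.88 for this implementation and for the
reference implementation of the same algorithm alike). Statistical
calibration checks use 24 donors so the rank-sum null is effectively
continuous, and 400 random gene sets to average the module-score null.
Tie-breaks are deterministic everywhere: gene-id order in feature
rankings, smallest-community-id in cluster renumbering, first-occurrence
ranks in expression binning.

## Known limitations

- The manual curation steps of real atlas work (doublet cleanup by marker
  co-expression, merging of near-identical clusters) are represented by
  declarative, testable rules, not by a claim to reproduce any particular
  manual decision.
- Harmonization drops excluded genes at intersection time; whether a
  reference gene whose partner was excluded should be dropped earlier is
  a convention choice, recorded in the exclusion report.
- The anchor machinery targets desk-scale data; the exact O(n²) neighbor
  searches would need an approximate-neighbor backend beyond ~50k cells.
- Infinite folds (types absent from one dataset) are counted as
  threefold-enriched; with shallow sampling this can overstate enrichment
  for rare types.
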