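---
title: "Methods: topic models, GRN inference and in silico TF knockouts"
author: "topicgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic models, GRN inference and in silico TF knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`topicgrn` implements an inference chain that links gene-expression
*programs* (topics) in single-cell RNA-seq data to the architecture of the
underlying gene regulatory network (GRN), and then asks how much each
transcription factor (TF) contributes to holding a cell population in its
functional state. The motivating biology is the contrast between
tissue-resident and recruited (monocyte-derived) alveolar macrophages under
inflammatory challenge: resident cells remain close to a homeostatic
program while recruited cells swing hard into an inflammatory program, and
the hypothesis is that a denser TF-TF regulatory core stabilizes the
resident state. Everything here runs on synthetic data with planted ground
truth, so each stage of the chain can be scored against the truth it is
supposed to recover.

# The model chain

## Multinomial topic model

Counts are modeled as `X ~ Poisson(L F')` with non-negative loadings `L`
(cells x K) and factors `F` (genes x K), fitted by multiplicative EM
updates that monotonically increase the Poisson log-likelihood. After
fitting, the factorization is reparametrized to the multinomial
grade-of-membership form: `F` columns become per-topic gene distributions
(summing to 1), `L` rows become per-cell topic proportions (summing to 1),
and per-cell scale is absorbed into size factors. Defaults follow the
fitting schedule of 150 main plus 150 refinement iterations. Because
multiplicative updates can stall in poor local optima, three random
initializations are screened for 25 pilot iterations and the best incumbent
(by log-likelihood) is carried to the full fit; the reported trace is that
of the selected run and is non-decreasing.

Per-topic differential expression uses a grade-of-membership log fold
change: `lfc_jk = log2((F_jk + eps) / (baseline_j + eps))` with
`eps = 1e-8`, where the baseline is the loadings-weighted mean of the
gene's factor values (weights = mean topic proportions over cells). This is
a deliberately simple contrast; it preserves the *ranking* behavior that
the downstream top-N gene lists need, and makes no posterior-uncertainty
claims. Ties in `top_genes()` break by descending factor value, then
lexical gene id, so lists are fully reproducible.

Gene-set enrichment is a plain upper-tail hypergeometric test with
Benjamini-Hochberg adjustment across sets; no pathway database is bundled —
any named gene sets (e.g. read from GMT) can be supplied.

## Gene selection, imputation and GRN inference

Network construction follows the usual single-cell GRN recipe: keep genes
with at least one count, take the top 2,500 most variable genes (variance
of log1p counts-per-10k), union in the declared TF list, project the
normalized expression onto 47 principal components, and KNN-impute each
cell as the mean over its `k = 2.5%`-of-cells nearest neighbors (self
included) in PC space. In the pipeline, imputation runs *within each
population*: the networks are population-specific, and cross-population
neighbors (day-0 cells of the two populations are transcriptomically
similar apart from markers) would average away exactly the
population-specific TF-TF coupling the analysis is after. PCA uses a deterministic sign convention (the
largest-magnitude loading of each component is made positive) so results do
not depend on LAPACK sign whims.

Edges are then fitted per *context* (population, population x timepoint, or
timepoint): for each target gene, a ridge regression (fixed penalty
`lambda = 1` on standardized regressors) of imputed target expression on
its candidate regulators — candidates restricted to a *base GRN* — with 20
bootstrap resamples. The reported coefficient is the bagged mean; an edge
is retained when `|mean| / sd(bag estimates) > 2` and the sign agrees in at
least 80% of resamples. The fixed penalty (rather than per-gene
cross-validation) is a deliberate stability choice at this problem scale;
both the threshold and the penalty are exposed. Bagging operates on cells
sorted by id, so the result is invariant to input cell order.

Eigenvector centrality is computed by power iteration on the undirected
weighted projection of the retained edges (absolute coefficients,
reciprocal edges summed). Eigenvector centrality is ill-behaved on directed
graphs that are not strongly connected, which inferred GRNs rarely are, so
the undirected convention is the default. A small diagonal shift
(`0.1 x max row sum`) is added during iteration; it leaves the leading
eigenvector unchanged and prevents the sign oscillation that pure power
iteration exhibits on bipartite graphs (e.g. stars). Convergence is at
`1e-10` in the max norm or 10,000 iterations; centralities are
max-normalized per context.

Comparing *average TF centrality* across independently fitted networks
has a subtlety: the leading eigenvector of a dense network localizes on
its densest subgraph, so under max-normalization the typical TF in the
*denser* network can score lower relative to its own maximum even though
TFs hold more of the network's centrality mass. The per-network
normalization (max, L2 or sum) is an arbitrary convention and should
cancel out of any cross-network comparison. `centrality_contrast()`
therefore reports, besides the raw mean of max-normalized values, the
ratio of the mean TF centrality to the mean centrality of all nodes in
that network — a statistic invariant to the normalization convention —
and the population contrast is read from the ratio.

## In silico knockouts and perturbation scores

A TF knockout sets the TF's imputed expression to zero: the initial shift
`dX0` is `-x_tf` at the TF coordinate and zero elsewhere. The shift
propagates `n = 3` steps through the retained coefficients
(`dX_{t+1} = dX_t W`), accumulating across steps; after each step simulated
expression is clamped at zero (no negative expression) and the knocked-out
TF is pinned at zero. On a DAG with inactive clamping this equals the
closed form `sum_t dX0 W^t`, which the tests verify exactly.

Gradient fields and projections for both populations live on a single
shared 2D embedding (the first two PCs of the jointly normalized data,
standing in for a study-wide t-SNE); each population contributes its own
cells, fields and networks. A per-population embedding would rescale each
population's occupied region to fill its own bounding box and distort
cross-population comparisons of gradient magnitudes.

The high-dimensional shift is projected onto a 2D embedding the way
single-cell velocity-style tools do: for each cell, the correlation between
its shift vector and the expression difference to each of its
`k_neighbors = 200` nearest expression neighbors (PC space) is mapped
through an exponential kernel (`temperature = 0.05`) into transition
weights, and the cell's 2D arrow is the weighted mean of unit vectors
toward those neighbors minus their unweighted mean. The subtraction removes
embedding-density bias: a cell whose shift correlates with nothing beyond
chance gets a near-zero arrow rather than an arrow toward the local crowd.
With a single neighbor the weighted and unweighted means coincide and the
arrow is exactly zero — at least two effective neighbors are required for a
direction to be expressible.

Topic "trajectories" are gradient fields of the topic loadings over the
same embedding: loadings are smoothed onto a 40 x 40 grid by
Gaussian-kernel averaging (bandwidth = 1/25 of the larger bounding-box
side), nodes with no cell within twice the bandwidth are masked, and the
gradient is taken by central differences (one-sided at mask borders). The
perturbation score of a knockout against a topic is the mean over jointly
occupied grid nodes of the dot product between the smoothed knockout field
and the topic gradient field. The mean (rather than the sum) makes scores
comparable across populations with different cell counts and grid
occupancy. A negative score means the knockout pushes cells *down* that
topic's gradient — away from the program. Each TF gets a score vector
(homeostasis score, inflammation score) whose Euclidean norm summarizes how
destabilizing the knockout is; dot products are computed in the 2D grid
field, and that choice is recorded here rather than hidden.

## Motif scanning and the base GRN

The base GRN — which TF-target pairs regression may consider at all — comes
from motif evidence near transcription start sites. The scanner scores
position-weight matrices (position frequencies with pseudocount 0.01
against a background composition, log2 odds) at every offset on both
strands, reports windows at or above a threshold (default 10, the study
scale's convention), and resolves same-strand overlaps by keeping the
higher score. Peaks map to every gene whose TSS lies within a window of the
peak's closest edge (0-based half-open arithmetic; distance 0 when
overlapping). Two windows are first-class: 3 kb for base-GRN candidate
assignment and 100 kb for the per-topic motif-enrichment contrast; the two
coexist deliberately rather than being reconciled. Each (motif hit in
peak, peak-to-gene) pair becomes a candidate edge via a motif-to-TF map,
deduplicated with provenance.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and the
tests run against them.

* **Populations and time course.** Two populations ("resident-like",
  "recruited-like"), 2,000 cells each by default, split evenly over days 0,
  3, 6 and 15 after challenge.
* **Topics.** Three programs — homeostasis, inflammation, resolution — as
  column-stochastic gene distributions: 30% of probability mass is a
  background shared by *all* topics (so non-program genes, including TFs,
  are not differentially expressed between programs, as is true of
  housekeeping-like genes), 70% concentrates on the topic's own disjoint
  gene block with random texture. TF genes carry 4x background mass,
  reflecting that the analyzed TF list is restricted to expressed TFs;
  this also makes TF expression measurable at realistic depth.
* **Per-cell topic proportions.** Dirichlet draws (concentration 30) around
  population-by-timepoint means. Recruited-like cells swing into
  inflammation at day 3 (mean proportion 0.75) and through resolution at
  day 6 (0.70); resident-like cells shift only mildly (inflammation peaks
  at 0.16 at day 3, homeostasis never below 0.70) and stay predominantly
  homeostatic — the central contrast the
  perturbation analysis should detect. Each phase has a
  dominant-proportion anchor, which is what makes the topic model
  identifiable at K = 3.
* **Regulatory network.** TF activity deviations are standard normal per
  cell (scaled by `tf_activity_sd = 1` on the log-rate scale), coupled one
  step through a population-specific TF-TF weight matrix whose edge
  density is 0.15 (resident-like) versus 0.03 (recruited-like) over
  ordered TF pairs. Every ordinary TF regulates 5 non-TF targets with
  signed weights `±U(0.2, 1) x 0.75`; a designated homeostasis master TF
  (TF01) positively regulates 10 homeostasis-block genes and negatively
  regulates 10 inflammation-block genes in both populations. The weight
  scale 0.75 was chosen once as a moderate regulatory modulation: strong
  enough for regression to rank true edges above decoys, weak enough that
  regulatory variance does not masquerade as a topic.
* **Nuisance noise and depth.** Every gene's log-rate receives
  `N(0, noise_sd = 0.2)`; library sizes are Poisson with mean 2,000; counts
  are multinomial per cell.
* **Markers and decoys.** Eight marker genes per population (4x up in
  their own population, 4x down in the other) make the populations
  separable by clustering, as real marker genes do. Six decoy candidate
  edges per TF — motif present near the gene, regulatory weight zero —
  give the base GRN true negatives, so edge-recovery AUROC measures
  something.
* **Sequences.** One uniform-ACGT contig per gene with a recorded TSS and
  one 200 bp peak; every planted motif is embedded as its exact consensus
  inside the peak (position-frequency matrices use 12 counts for the
  consensus base and 1 for each alternative). Coordinates are 0-based
  half-open throughout; strand is ignored at generation time because the
  scanner searches both strands.

What the generator does **not** emulate: doublets, ambient RNA,
batch/chemistry effects, bursty transcription, feedback from targets to
TFs, chromatin state, or fragment-level ATAC signal. Passing the tests
therefore shows the chain is *internally correct and directionally
sensitive under its own assumptions*, not that it would reach the same
conclusions on arbitrary real data.

# Design choices in genuinely open territory

* **Generative order.** Topic mixture first, regulatory coupling second
  (on the log-rate scale). This keeps both recovery problems well-posed:
  topics remain probability distributions, and regulatory effects remain
  linear in TF activity on the log scale.
* **`noise_sd` vs `tf_activity_sd`.** The nuisance noise and the TF-signal
  scale are separate knobs. Edge-recovery error must *decrease* as
  `noise_sd` shrinks, which forces `noise_sd` to be noise on targets, not
  the source of TF variation; the TF activity scale is its own parameter.
* **Edge-recovery evaluation.** The planted truth is population-specific
  (TF-TF edges differ), so candidates are ranked within each population's
  fitted network and pooled across the two contexts for a single AUROC.
* **K-means feature space** for population annotation: top-50 PCs of
  log1p counts-per-10k, 10 random starts, fixed seed, clustering on cells
  sorted by id (order invariance).
* **Pseudobulk and marker scoring** normalize by counts-per-10k then
  log1p.
* **Grid scores.** 40 x 40 grid, bandwidth 1/25 of the bounding box; the
  acceptance checks verify grid-refinement stability indirectly through
  multi-seed reproduction of the directional contrasts.
* **Resumability.** `run_all()` writes artifacts and a config-hashed
  report; a rerun with an unchanged config returns the saved report. The
  hash covers the full config including the seed.

# Numerical choices and degenerate inputs

* NMF guards divisions with `eps = 1e-100`; all-zero genes keep zero
  factor mass; the log-likelihood trace omits constant terms.
* Zero-variance regulators are dropped per target with a message; empty
  contexts and too-small contexts are errors naming the context.
* Constant knockout shifts (correlation undefined) yield zero arrows with
  a warning; all-zero shifts yield zero arrows silently.
* Graphs with no retained edges yield all-zero centralities with a
  warning; disconnected graphs concentrate centrality on the component
  with the larger leading eigenvalue (documented power-iteration
  behavior, cross-checked against dense eigendecomposition in the tests).
* Contigs shorter than the motif yield zero hits, not errors; ambiguity
  codes skip the affected windows with one warning.
* The binomial edge-count check, the KNN brute-force check, the PWM
  brute-force check, the DAG closed form and the hypergeometric closed
  form are all verified by independent oracles in the test suite.

# Problem sizes used by the tests

Unit tests run on tiny fixtures (~120 cells per population, 120 genes).
The acceptance suite fits the topic model and the edge-recovery AUROC at
the generator's full default scale (2,000 cells per population, 500
genes) and runs the ten-seed directional checks (centrality contrast,
knockout-magnitude contrast, master-TF direction) at a reduced scale of
800 cells per population, 250 genes and 25 TFs — chosen so ten complete
simulate-to-screen chains remain a desk-scale computation while leaving
the per-seed contrasts comfortably resolvable. The acceptance script
(`scripts/acceptance.R`) runs the full default-scale chain once and
reports the quantities it computes.

# Known limitations

* The grade-of-membership LFC is a simple contrast, not a posterior
  estimate; only rankings should be interpreted.
* Post-imputation regression inherits the usual smoothing artifact:
  neighborhood averaging induces weak spurious correlations between any
  two smooth gene fields (effective degrees of freedom roughly
  `n_cells / k`). The generator's signal scales were chosen so true edges
  clear this floor; on real data the same artifact argues for caution
  with weak edges.
* Eigenvector centrality is reported for the undirected projection;
  directed variants differ and are not the default.
* The 2D projection of knockout shifts discards the component of the
  shift orthogonal to the local manifold; scores are comparisons within
  an embedding, not absolute effect sizes.
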