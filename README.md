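# topicgrn

Linking single-cell gene-expression *programs* to gene-regulatory-network
(GRN) architecture, and scoring in silico transcription-factor (TF)
knockouts against those programs.

## The problem

Tissue-resident macrophages (the motivating system is alveolar macrophages
under LPS-induced lung inflammation) hold a homeostatic transcriptional
program even while recruited, monocyte-derived cells in the same tissue
swing into an inflammatory program. One proposed explanation is network
architecture: a denser, more interconnected TF–TF regulatory core
stabilizes the resident state, so perturbing any single TF moves the cell
state less. `topicgrn` implements the full inference chain needed to
interrogate that idea, and a synthetic-data generator with planted ground
truth so every link of the chain can be benchmarked:

1. **Topic model** — multinomial grade-of-membership model fitted by
   Poisson non-negative matrix factorization: counts
   `X ~ Poisson(diag(s) L Fᵀ)` with row-stochastic loadings `L` (per-cell
   topic proportions) and column-stochastic factors `F` (per-topic gene
   distributions). Plus grade-of-membership log fold changes, top-gene
   lists, hypergeometric gene-set enrichment, k-means population
   annotation and pseudobulking.
2. **GRN inference** — highly-variable-gene selection, per-population KNN
   imputation in PC space, bagged ridge regression of each target on its
   base-GRN candidate regulators, eigenvector centrality of the retained
   network (power iteration, undirected weighted projection).
3. **In silico knockout** — set a TF's expression to zero, propagate the
   shift through the network coefficients (`ΔX_{t+1} = ΔX_t W`, 3 steps,
   non-negativity clamped), project the shift onto a 2D embedding via
   correlation-weighted transitions to expression neighbors, and take dot
   products with topic-loading gradient fields on a grid:
   `score(TF, topic) = mean over grid nodes of (perturbation vector ·
   topic gradient)`. Each TF gets a (homeostasis, inflammation) score
   vector; its Euclidean norm measures how destabilizing the knockout is.
4. **Motifs** — PWM log-odds scanning of regulatory sequences on both
   strands, peak-to-TSS window assignment (3 kb / 100 kb), base-GRN
   construction from motif hits, per-topic motif-count contrasts.
5. **Synthetic data** — two populations ("resident-like", dense TF–TF
   core; "recruited-like", sparse core) across a 0/3/6/15-day time
   course, three planted topics (homeostasis, inflammation, resolution),
   signed TF→target effects, marker genes, decoy candidate edges, and
   motif instances planted near topic-gene TSSs — all recorded in a
   ground-truth ledger.

## Worked example

One call runs the whole chain on synthetic data (here 800 cells per
population, 250 genes, 25 TFs; about 20 s):

```r
library(topicgrn)

cfg <- run_config(
  syndata = list(n_cells_per_population = 800, n_genes = 250, n_tfs = 25,
                 library_size_mean = 1500),
  seed = 1)
rep <- run_all(cfg)
cs  <- contrast_summary(rep)

round(rep$topic_recovery_cosine, 3)
#> [1] 0.953
cs$centrality[, c("population", "timepoint", "tf_centrality_ratio")]
#>       population timepoint tf_centrality_ratio
#> 1 recruited-like         0                2.22
#> 2 recruited-like         3                2.22
#> 3 recruited-like         6                2.11
#> 4 recruited-like        15                2.37
#> 5  resident-like         0                3.13
#> 6  resident-like         3                3.37
#> 7  resident-like         6                3.36
#> 8  resident-like        15                3.11
round(cs$magnitude, 4)
#> recruited-like  resident-like
#>         0.0081         0.0042
cs$master
#>       population   tf score_homeostasis score_inflammation magnitude
#> 1 recruited-like TF01          -0.01112            0.01979   0.02270
#> 2  resident-like TF01          -0.00565            0.00657   0.00867
```

Reading the numbers:

* `topic_recovery_cosine` — mean cosine between the fitted topic gene
  distributions and the planted ones after optimal matching; 0.95 means
  the three programs were recovered nearly exactly.
* `tf_centrality_ratio` — mean TF eigenvector centrality relative to the
  network-average node, per population × day. TFs are markedly more
  central in the dense resident-like networks at every timepoint, the
  planted architecture difference.
* `cs$magnitude` — mean knockout score-vector magnitude over all TFs:
  knockouts move the sparse recruited-like population about twice as much
  as the resident-like one.
* `cs$master` — the planted homeostasis master TF: its knockout scores
  negative on the homeostasis gradient and positive on the inflammation
  gradient (pushing cells away from homeostasis, toward inflammation),
  with a magnitude well above the population mean (0.0087 vs 0.0042 in
  resident-like cells).

Per-population edge-recovery AUROCs against the planted edge list are in
`rep$edge_recovery_auroc` (0.96 resident-like / 0.88 recruited-like
above). `run_all(cfg, outdir = "out/")` additionally writes the
centrality and screen tables as TSV and a `report.json`.

The motif route is exercised separately: `generate_regulatory_sequences()`
→ `scan_pwms()` → `assign_peaks_to_genes()` → `build_base_grn()` /
`motif_topic_contrast()`; see the methods vignette
(`vignettes/topicgrn-methods.Rmd`) for the model details and every
tunable parameter.

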