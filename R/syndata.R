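#' Configuration for the synthetic single-cell study
#'
#' Defines the generative conditions for the benchmark: two alveolar
#' macrophage-like populations ("resident-like" and "recruited-like")
#' profiled across an inflammation time course, with a planted
#' grade-of-membership topic structure, a signed TF-to-target regulatory
#' network whose TF-TF interconnectivity differs between the populations
#' (dense in the resident-like population, sparse in the recruited-like
#' one), population marker genes, and motif instances planted near the
#' transcription start sites of topic genes.
#'
#' @param n_cells_per_population Cells per population, split evenly over
#'   `timepoints`.
#' @param n_genes Total genes (transcription factors included).
#' @param n_tfs Number of transcription factors (the first genes).
#' @param n_topics_true Number of planted functional topics.  The default 3
#'   corresponds to homeostasis, inflammation and resolution programs.
#' @param timepoints Labels for the time course (days after challenge).
#' @param library_size_mean Mean per-cell library size; sizes are Poisson.
#' @param tf_tf_density_dense,tf_tf_density_sparse Directed TF-TF edge
#'   probability for the resident-like (dense) and recruited-like (sparse)
#'   populations, over ordered TF pairs.
#' @param edge_weight_scale Multiplier on all planted edge weights.
#' @param tf_activity_sd Standard deviation of per-cell TF activity
#'   deviations on the log-rate scale; this is the signal regression-based
#'   edge recovery relies on.
#' @param noise_sd Additive Gaussian nuisance noise on every gene's
#'   log-rate.
#' @param n_targets_per_tf Non-TF target genes wired to each ordinary TF.
#' @param n_decoys_per_tf Decoy candidate edges (motif present, no
#'   regulatory effect) planted per TF, giving the base GRN true negatives.
#' @param n_marker_genes Marker genes per population.
#' @param topic_concentration Dirichlet concentration of per-cell topic
#'   proportions around the population-by-timepoint mean.
#' @param seed Integer seed; all generator stages derive their streams from
#'   it via [stage_seed()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_per_population = 2000,
                             n_genes = 500,
                             n_tfs = 40,
                             n_topics_true = 3,
                             timepoints = c(0, 3, 6, 15),
                             library_size_mean = 2000,
                             tf_tf_density_dense = 0.15,
                             tf_tf_density_sparse = 0.03,
                             edge_weight_scale = 0.75,
                             tf_activity_sd = 1.0,
                             noise_sd = 0.2,
                             n_targets_per_tf = 5,
                             n_decoys_per_tf = 6,
                             n_marker_genes = 8,
                             topic_concentration = 30,
                             seed = 1L) {
  cfg <- list(n_cells_per_population = n_cells_per_population,
              n_genes = n_genes, n_tfs = n_tfs,
              n_topics_true = n_topics_true, timepoints = timepoints,
              library_size_mean = library_size_mean,
              tf_tf_density_dense = tf_tf_density_dense,
              tf_tf_density_sparse = tf_tf_density_sparse,
              edge_weight_scale = edge_weight_scale,
              tf_activity_sd = tf_activity_sd, noise_sd = noise_sd,
              n_targets_per_tf = n_targets_per_tf,
              n_decoys_per_tf = n_decoys_per_tf,
              n_marker_genes = n_marker_genes,
              topic_concentration = topic_concentration,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_cells_per_population", "n_genes", "n_tfs", "n_topics_true",
              "library_size_mean")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1)
      stop("invalid config: `", f, "` must be a count >= 1", call. = FALSE)
  }
  for (f in c("tf_tf_density_dense", "tf_tf_density_sparse")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config: `", f, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (cfg$tf_tf_density_dense <= cfg$tf_tf_density_sparse)
    stop("invalid config: tf_tf_density_dense must exceed tf_tf_density_sparse",
         call. = FALSE)
  if (cfg$n_tfs >= cfg$n_genes)
    stop("invalid config: n_tfs must be smaller than n_genes", call. = FALSE)
  invisible(cfg)
}

#' Populations used throughout the package
#' @keywords internal
POPULATIONS <- c("resident-like", "recruited-like")

topic_names_for <- function(K) {
  base <- c("homeostasis", "inflammation", "resolution")
  if (K <= 3) base[seq_len(K)] else c(base, paste0("topic", 4:K))
}

## Population-by-timepoint mean topic proportions for the canonical 3-topic
## design: the recruited-like population swings hard into the inflammation
## program at day 3 and through resolution at day 6; the resident-like
## population stays predominantly homeostatic throughout.
mean_props_3topic <- function(timepoints) {
  traj <- list(
    "resident-like"  = rbind(c(0.82, 0.06, 0.12),
                             c(0.70, 0.16, 0.14),
                             c(0.72, 0.08, 0.20),
                             c(0.78, 0.06, 0.16)),
    "recruited-like" = rbind(c(0.70, 0.15, 0.15),
                             c(0.12, 0.75, 0.13),
                             c(0.17, 0.13, 0.70),
                             c(0.55, 0.15, 0.30)))
  lapply(traj, function(m) {
    ## recycle/trim the 4-row design to the requested number of timepoints
    m[((seq_along(timepoints) - 1) %% nrow(m)) + 1, , drop = FALSE]
  })
}

#' Generate the planted ground truth for a synthetic study
#'
#' Builds the unobserved truth the downstream modules are benchmarked
#' against: column-stochastic topic gene distributions, per-cell topic
#' proportions varying by population and timepoint, a signed regulatory
#' edge list whose TF-TF subnetwork density differs between populations,
#' decoy candidate edges, population marker genes, and a planted-motif
#' ledger (one motif per TF near each of its targets, plus contrast motifs
#' planted near the homeostasis and/or inflammation topic gene blocks).
#'
#' A designated homeostasis "master" TF (the first TF) positively regulates
#' a block of homeostasis-topic genes and negatively regulates a block of
#' inflammation-topic genes in both populations.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `ground_truth`.
#' @export
generate_ground_truth <- function(config) {
  validate_synthetic_config(config)
  set.seed(stage_seed(config$seed, "truth"))
  K <- config$n_topics_true
  n_genes <- config$n_genes
  n_tfs <- config$n_tfs
  nm <- config$n_marker_genes

  wid <- max(3, nchar(as.character(n_genes)))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  other_ids <- sprintf("G%0*d", wid, seq(n_tfs + 1, n_genes))
  gene_ids <- c(tf_ids, other_ids)

  ## gene layout: TFs | resident markers | recruited markers | topic blocks
  idx <- n_tfs
  marker_genes <- list()
  for (pop in POPULATIONS) {
    marker_genes[[pop]] <- if (nm > 0) gene_ids[idx + seq_len(nm)] else character(0)
    idx <- idx + nm
  }
  remaining <- seq(idx + 1, n_genes)
  if (length(remaining) < K)
    stop("invalid config: not enough genes left for ", K, " topic blocks",
         call. = FALSE)
  block_size <- length(remaining) %/% K
  topic_names <- topic_names_for(K)
  topic_gene_sets <- lapply(seq_len(K), function(k) {
    gene_ids[remaining[(k - 1) * block_size + seq_len(block_size)]]
  })
  names(topic_gene_sets) <- topic_names

  ## topic gene distributions: 30% background mass shared by all topics
  ## (so non-program genes -- TFs included -- are not differentially
  ## expressed across programs), 70% concentrated on the topic's own
  ## block with random texture
  F_true <- matrix(0, n_genes, K, dimnames = list(gene_ids, topic_names))
  bg <- runif(n_genes, 0.5, 1.5)
  ## TFs are well-expressed (the analyzed TF list is restricted to
  ## expressed TFs), so they carry extra background mass
  bg[seq_len(n_tfs)] <- bg[seq_len(n_tfs)] * 4
  bg <- bg / sum(bg) * 0.3
  for (k in seq_len(K)) {
    blk <- match(topic_gene_sets[[k]], gene_ids)
    boost <- runif(length(blk), 0.5, 1.5)
    boost <- boost / sum(boost) * 0.7
    w <- bg
    w[blk] <- w[blk] + boost
    F_true[, k] <- w / sum(w)
  }

  ## cells and their topic proportions
  n_per <- config$n_cells_per_population
  tps <- config$timepoints
  per_tp <- rep(n_per %/% length(tps), length(tps))
  per_tp[seq_len(n_per %% length(tps))] <- per_tp[seq_len(n_per %% length(tps))] + 1
  cell_meta <- do.call(rbind, lapply(POPULATIONS, function(pop) {
    data.frame(population = pop,
               timepoint = rep(tps, per_tp),
               stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(cell_meta)
  cell_ids <- sprintf("cell%0*d", max(4, nchar(n_cells)), seq_len(n_cells))
  rownames(cell_meta) <- cell_ids

  if (K == 3) {
    mp <- mean_props_3topic(tps)
  } else {
    flat <- matrix(1 / K, length(tps), K)
    mp <- list(flat, flat)
    names(mp) <- POPULATIONS
  }
  props <- matrix(0, n_cells, K, dimnames = list(cell_ids, topic_names))
  for (i in seq_len(n_cells)) {
    pop <- cell_meta$population[i]
    ti <- match(cell_meta$timepoint[i], tps)
    alpha <- mp[[pop]][ti, ] * config$topic_concentration
    props[i, ] <- rdirichlet1(alpha)
  }

  ## regulatory edges ------------------------------------------------------
  ws <- config$edge_weight_scale
  master_tf <- tf_ids[1]
  edges <- list()
  if (K >= 2) {
    n_master <- min(10, block_size)
    homeo_tgt <- topic_gene_sets[[1]][seq_len(n_master)]
    inflam_tgt <- topic_gene_sets[[2]][seq_len(n_master)]
    edges[[length(edges) + 1]] <- data.frame(
      regulator = master_tf, target = homeo_tgt,
      weight = runif(n_master, 0.5, 1) * ws,
      population = "both", type = "master", stringsAsFactors = FALSE)
    edges[[length(edges) + 1]] <- data.frame(
      regulator = master_tf, target = inflam_tgt,
      weight = -runif(n_master, 0.5, 1) * ws,
      population = "both", type = "master", stringsAsFactors = FALSE)
  }
  pool <- setdiff(other_ids, unlist(marker_genes))
  for (tf in setdiff(tf_ids, master_tf)) {
    tgt <- sample(pool, min(config$n_targets_per_tf, length(pool)))
    w <- runif(length(tgt), 0.2, 1) * sample(c(-1, 1), length(tgt), TRUE) * ws
    edges[[length(edges) + 1]] <- data.frame(
      regulator = tf, target = tgt, weight = w,
      population = "both", type = "tf_target", stringsAsFactors = FALSE)
  }
  ## population-specific TF-TF subnetworks over ordered pairs
  dens <- c("resident-like" = config$tf_tf_density_dense,
            "recruited-like" = config$tf_tf_density_sparse)
  for (pop in POPULATIONS) {
    pairs <- expand.grid(regulator = tf_ids, target = tf_ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    keep <- rbinom(nrow(pairs), 1, dens[[pop]]) == 1
    if (any(keep)) {
      sel <- pairs[keep, ]
      w <- runif(nrow(sel), 0.2, 1) * sample(c(-1, 1), nrow(sel), TRUE) * ws
      edges[[length(edges) + 1]] <- data.frame(
        regulator = sel$regulator, target = sel$target, weight = w,
        population = pop, type = "tf_tf", stringsAsFactors = FALSE)
    }
  }
  grn_edges <- do.call(rbind, edges)
  rownames(grn_edges) <- NULL

  ## decoy candidates: the TF's motif is planted near these genes but no
  ## regulatory effect exists, so the base GRN gains true negatives
  decoys <- list()
  for (tf in tf_ids) {
    already <- grn_edges$target[grn_edges$regulator == tf]
    avail <- setdiff(pool, already)
    tgt <- sample(avail, min(config$n_decoys_per_tf, length(avail)))
    if (length(tgt) > 0)
      decoys[[length(decoys) + 1]] <- data.frame(
        regulator = tf, target = tgt, stringsAsFactors = FALSE)
  }
  decoy_edges <- do.call(rbind, decoys)
  rownames(decoy_edges) <- NULL

  ## planted-motif ledger: TF motifs near regulated and decoy genes, plus
  ## topic-contrast motifs near the homeostasis / inflammation blocks
  tf_motif <- function(tf) paste0("M_", tf)
  pm <- rbind(
    data.frame(motif_id = tf_motif(grn_edges$regulator),
               gene_id = grn_edges$target, topic_id = NA_character_,
               stringsAsFactors = FALSE),
    if (!is.null(decoy_edges))
      data.frame(motif_id = tf_motif(decoy_edges$regulator),
                 gene_id = decoy_edges$target, topic_id = NA_character_,
                 stringsAsFactors = FALSE))
  if (K >= 2) {
    n_c <- min(12, block_size)
    homeo_c <- topic_gene_sets[[1]][block_size - seq_len(n_c) + 1]
    inflam_c <- topic_gene_sets[[2]][block_size - seq_len(n_c) + 1]
    pm <- rbind(pm,
      data.frame(motif_id = "M_homeo_only", gene_id = homeo_c,
                 topic_id = topic_names[1], stringsAsFactors = FALSE),
      data.frame(motif_id = "M_inflam_only", gene_id = inflam_c,
                 topic_id = topic_names[2], stringsAsFactors = FALSE),
      data.frame(motif_id = "M_shared", gene_id = c(homeo_c, inflam_c),
                 topic_id = rep(topic_names[1:2], each = n_c),
                 stringsAsFactors = FALSE))
  }
  pm <- unique(pm)
  pm$peak_id <- paste0("peak_", pm$gene_id)
  pm <- pm[, c("motif_id", "peak_id", "gene_id", "topic_id")]
  rownames(pm) <- NULL

  structure(list(config = config,
                 gene_ids = gene_ids, tf_ids = tf_ids,
                 topic_gene_dists = F_true,
                 topic_gene_sets = topic_gene_sets,
                 cell_ids = cell_ids, cell_meta = cell_meta,
                 cell_topic_props = props,
                 grn_edges = grn_edges, decoy_edges = decoy_edges,
                 population_labels = stats::setNames(cell_meta$population, cell_ids),
                 marker_genes = marker_genes,
                 master_tf = master_tf,
                 planted_motifs = pm),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$gene_ids), "genes (", length(x$tf_ids),
      "TFs),", length(x$cell_ids), "cells,",
      ncol(x$topic_gene_dists), "topics,", nrow(x$grn_edges), "edges\n")
  invisible(x)
}

#' Container for a sparse gene-by-cell count matrix
#'
#' @param counts A genes x cells matrix of non-negative integer counts
#'   (coerced to sparse `dgCMatrix`).
#' @param gene_ids,cell_ids Unique identifiers matching the matrix
#'   dimensions.
#' @param cell_meta A data.frame of per-cell metadata (one row per cell;
#'   typically `population` and `timepoint`).
#' @return A list of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, cell_meta) {
  counts <- if (is(counts, "sparseMatrix")) {
    as(as(counts, "CsparseMatrix"), "generalMatrix")
  } else {
    Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- as(counts, "dMatrix")
  stopifnot(nrow(counts) == length(gene_ids),
            ncol(counts) == length(cell_ids),
            nrow(cell_meta) == length(cell_ids))
  if (anyDuplicated(gene_ids) || anyDuplicated(cell_ids))
    stop("duplicate gene or cell identifiers", call. = FALSE)
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(cell_meta) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      round(100 * Matrix::nnzero(x$counts) /
              (nrow(x$counts) * ncol(x$counts)), 1), "% nonzero\n")
  invisible(x)
}

#' Simulate multinomial single-cell counts from the planted truth
#'
#' Each cell's rate vector is the topic mixture
#' `sum_k prop_k * topic_gene_dist_k`.  On the log-rate scale, TF genes
#' then receive their population's TF-TF-coupled activity deviations
#' (`tf_activity_sd` times a standard-normal intrinsic activity propagated
#' one step through the population's TF-TF weights), target genes receive
#' the sum of `weight * activity` over their planted regulators, marker
#' genes are shifted up in their own population and down in the other, and
#' every gene receives `N(0, noise_sd)` nuisance noise.  The rate vector is
#' renormalized to a probability vector and counts are drawn multinomially
#' with a Poisson library size.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param config The same [synthetic_config()] used to build `truth`.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!identical(truth$config$n_genes, config$n_genes) ||
      !identical(truth$config$n_tfs, config$n_tfs))
    stop("truth and config are inconsistent", call. = FALSE)
  set.seed(stage_seed(config$seed, "counts"))

  n_cells <- length(truth$cell_ids)
  n_genes <- length(truth$gene_ids)
  n_tfs <- length(truth$tf_ids)
  F_true <- truth$topic_gene_dists

  rates <- truth$cell_topic_props %*% t(F_true)     # cells x genes
  logr <- log(rates)

  ## TF activities, coupled one step through each population's TF-TF edges
  a <- matrix(rnorm(n_cells * n_tfs), n_cells, n_tfs,
              dimnames = list(truth$cell_ids, truth$tf_ids))
  u <- a
  for (pop in POPULATIONS) {
    ee <- truth$grn_edges[truth$grn_edges$type == "tf_tf" &
                            truth$grn_edges$population == pop, ]
    cells <- truth$cell_meta$population == pop
    if (nrow(ee) > 0 && any(cells)) {
      W_tt <- matrix(0, n_tfs, n_tfs,
                     dimnames = list(truth$tf_ids, truth$tf_ids))
      W_tt[cbind(ee$regulator, ee$target)] <- ee$weight
      u[cells, ] <- a[cells, , drop = FALSE] +
        a[cells, , drop = FALSE] %*% W_tt
    }
  }
  logr[, truth$tf_ids] <- logr[, truth$tf_ids] + config$tf_activity_sd * u

  ## planted TF -> target effects (shared edges; TF-TF handled above)
  ee <- truth$grn_edges[truth$grn_edges$population == "both", ]
  if (nrow(ee) > 0) {
    W_tg <- matrix(0, n_tfs, n_genes,
                   dimnames = list(truth$tf_ids, truth$gene_ids))
    W_tg[cbind(ee$regulator, ee$target)] <- ee$weight
    logr <- logr + u %*% W_tg
  }

  ## population markers: 4-fold up in own population, 4-fold down in other
  for (pop in POPULATIONS) {
    mk <- truth$marker_genes[[pop]]
    if (length(mk) > 0) {
      own <- truth$cell_meta$population == pop
      logr[own, mk] <- logr[own, mk] + log(4)
      logr[!own, mk] <- logr[!own, mk] - log(4)
    }
  }

  if (config$noise_sd > 0)
    logr <- logr + matrix(rnorm(n_cells * n_genes, 0, config$noise_sd),
                          n_cells, n_genes)

  p <- exp(logr)
  bad <- which(!is.finite(colSums(p)))
  if (length(bad) > 0)
    stop("non-finite rate for gene ", truth$gene_ids[bad[1]], call. = FALSE)
  p <- p / rowSums(p)

  lib <- rpois(n_cells, config$library_size_mean)
  counts <- matrix(0L, n_genes, n_cells)
  for (i in seq_len(n_cells)) {
    counts[, i] <- rmultinom(1, lib[i], p[i, ])
  }
  count_matrix(counts, truth$gene_ids, truth$cell_ids, truth$cell_meta)
}
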