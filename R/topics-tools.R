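#' Grade-of-membership log fold changes per topic
#'
#' For gene `j` and topic `k`, `lfc = log2((F[j,k] + eps) / (baseline_j +
#' eps))`, where `baseline_j` is the loadings-weighted average of gene
#' `j`'s factor values across topics (weights = mean topic proportions
#' over cells).  Genes with zero mass in every topic get `NA`.
#'
#' @param fit A [fit_topic_model()] result.
#' @param topic Topic index, or `NULL` for all topics.
#' @param eps Pseudocount guarding the ratio.
#' @return A data.frame of class `topic_lfc` with columns `gene`, `topic`,
#'   `lfc`, `f` (the factor value) and `baseline`.
#' @export
gom_lfc <- function(fit, topic = NULL, eps = 1e-8) {
  stopifnot(inherits(fit, "topic_fit"))
  ks <- topic %||% seq_len(fit$K)
  stopifnot(all(ks >= 1), all(ks <= fit$K))
  w <- colMeans(fit$L)
  baseline <- as.numeric(fit$F %*% w)
  out <- do.call(rbind, lapply(ks, function(k) {
    lfc <- log2((fit$F[, k] + eps) / (baseline + eps))
    lfc[rowSums(fit$F) == 0] <- NA_real_
    data.frame(gene = rownames(fit$F), topic = k, lfc = lfc,
               f = fit$F[, k], baseline = baseline,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("topic_lfc", "data.frame")
  out
}

#' Top genes of a topic by log fold change
#'
#' Sorted by descending LFC; ties broken by descending factor value, then
#' lexical gene id, so the ordering is fully deterministic.
#'
#' @param lfc A [gom_lfc()] table.
#' @param topic Topic index.
#' @param n Number of genes to return (truncated to the gene count).
#' @return Character vector of gene ids.
#' @export
top_genes <- function(lfc, topic, n = 1000) {
  stopifnot(n >= 1)
  x <- lfc[lfc$topic == topic & !is.na(lfc$lfc), ]
  ord <- order(-x$lfc, -x$f, x$gene)
  head(x$gene[ord], n)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each named gene set, within a stated universe; Benjamini-Hochberg
#' adjustment across sets.  Sets are intersected with the universe before
#' testing.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector, the gene universe.
#' @return A data.frame of class `enrichment_table` with columns `set`,
#'   `overlap`, `set_size`, `universe_size`, `p_value`, `p_adjusted`.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(s, query))
    ## P(overlap >= k) drawing q from N with |s| successes
    p <- phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Annotate cell populations by clustering and marker scoring
#'
#' K-means on the top principal components of log1p counts-per-10k
#' expression; each cluster is scored by the mean normalized expression of
#' each marker set, the best-scoring cluster per marker set receives that
#' set's label, and all remaining clusters are labeled `"other"`.
#'
#' @param counts A [count_matrix()].
#' @param marker_sets Named list of two (or more) disjoint marker gene
#'   sets; names become the population labels.
#' @param k_clusters Number of k-means clusters.
#' @param n_pcs Principal components used as the clustering space.
#' @param seed Seed for the k-means initialization.
#' @return Named character vector of per-cell labels (names = cell ids).
#' @export
annotate_populations <- function(counts, marker_sets, k_clusters = 5,
                                 n_pcs = 50, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"), length(marker_sets) >= 1)
  missing <- lapply(marker_sets, setdiff, y = counts$gene_ids)
  if (any(lengths(missing) > 0))
    stop("marker genes absent from the count matrix: ",
         paste(unlist(missing), collapse = ", "), call. = FALSE)
  n_cells <- length(counts$cell_ids)
  if (n_cells < k_clusters)
    stop("fewer cells than clusters", call. = FALSE)
  norm <- normalize_log_cp(counts$counts)      # cells x genes
  pcs <- pca_scores(norm, min(n_pcs, ncol(norm), n_cells - 1))
  set.seed(seed)
  ## cluster on sorted cell ids so labels are invariant to cell order
  ord <- order(counts$cell_ids)
  km <- kmeans(pcs[ord, , drop = FALSE], centers = k_clusters,
               nstart = 10, iter.max = 100)
  cl <- integer(n_cells)
  cl[ord] <- km$cluster
  labels <- rep("other", n_cells)
  scores <- sapply(marker_sets, function(mk) {
    ms <- rowMeans(norm[, mk, drop = FALSE])
    tapply(ms, factor(cl, levels = seq_len(k_clusters)), mean)
  })
  scores <- matrix(scores, nrow = k_clusters,
                   dimnames = list(NULL, names(marker_sets)))
  for (nm in names(marker_sets)) {
    labels[cl == which.max(scores[, nm])] <- nm
  }
  stats::setNames(labels, counts$cell_ids)
}

#' Pseudobulk expression by metadata group
#'
#' Per group, the mean of log1p counts-per-10k normalized expression per
#' gene.  Empty groups are dropped with a warning.
#'
#' @param counts A [count_matrix()].
#' @param group_by Character vector of `cell_meta` column names.
#' @return A groups x genes matrix; row names are the group keys joined
#'   with `"|"`.
#' @export
pseudobulk <- function(counts, group_by) {
  stopifnot(inherits(counts, "count_matrix"))
  missing <- setdiff(group_by, colnames(counts$cell_meta))
  if (length(missing) > 0)
    stop("unknown metadata keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- interaction(counts$cell_meta[, group_by, drop = FALSE],
                     sep = "|", drop = FALSE)
  empty <- setdiff(levels(key), unique(as.character(key)))
  if (length(empty) > 0)
    warning("dropping empty groups: ", paste(empty, collapse = ", "))
  norm <- normalize_log_cp(counts$counts)
  out <- rowsum(norm, group = as.character(key)) /
    as.vector(table(as.character(key)))
  colnames(out) <- counts$gene_ids
  out
}

## PCA scores with a deterministic sign convention: within each component
## the loading with the largest magnitude is made positive.
pca_scores <- function(x, n_pcs) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(pc$x, 2, flip, "*")
}
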