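#' Select genes for network construction
#'
#' Keeps genes with at least one count, ranks them by the variance of
#' their log1p counts-per-10k expression, takes the top `n_hvg` highly
#' variable genes, and unions in the supplied TF list (TFs that fail the
#' expression filter are excluded and reported via message).
#'
#' @param counts A [count_matrix()].
#' @param n_hvg Number of highly variable genes.
#' @param tf_list Character vector of TF gene ids to force-include.
#' @return Character vector: HVGs in rank order followed by the appended
#'   TFs in sorted order.
#' @export
select_genes <- function(counts, n_hvg = 2500, tf_list = character(0)) {
  stopifnot(inherits(counts, "count_matrix"))
  if (n_hvg < 1) stop("n_hvg must be >= 1", call. = FALSE)
  expressed <- counts$gene_ids[Matrix::rowSums(counts$counts) > 0]
  dropped_tfs <- setdiff(tf_list, expressed)
  if (length(dropped_tfs) > 0)
    message("excluding unexpressed TFs: ", paste(dropped_tfs, collapse = ", "))
  norm <- normalize_log_cp(counts$counts)      # cells x genes
  v <- apply(norm[, expressed, drop = FALSE], 2, var)
  hvg <- expressed[order(-v, expressed)][seq_len(min(n_hvg, length(expressed)))]
  c(hvg, sort(setdiff(intersect(tf_list, expressed), hvg)))
}

#' KNN imputation of expression in principal-component space
#'
#' Log1p counts-per-10k expression over the selected genes is projected
#' onto the top principal components; each cell's imputed profile is the
#' mean normalized expression over its `k` nearest cells (self included)
#' in PC space, with `k = max(1, round(k_frac * n_cells))`.
#'
#' @param counts A [count_matrix()].
#' @param genes Genes to impute (e.g. from [select_genes()]).
#' @param n_pcs Number of principal components (clamped to the data).
#' @param k_frac Neighborhood size as a fraction of the cell count
#'   (default 2.5%).
#' @return A list of class `knn_imputed` with `x` (cells x genes imputed
#'   matrix), `norm` (the un-imputed normalized matrix), `pcs` (cells x
#'   n_pcs scores), `neighbors` (cells x k index matrix) and `k`.
#' @export
knn_impute <- function(counts, genes = NULL, n_pcs = 47, k_frac = 0.025) {
  stopifnot(inherits(counts, "count_matrix"))
  if (k_frac <= 0 || k_frac > 1) stop("k_frac must be in (0, 1]", call. = FALSE)
  genes <- genes %||% counts$gene_ids
  norm <- normalize_log_cp(counts$counts)[, genes, drop = FALSE]
  n <- nrow(norm)
  k <- max(1L, as.integer(round(k_frac * n)))
  if (k > n) {
    warning("k exceeds the number of cells; clamping")
    k <- n
  }
  n_pcs <- min(n_pcs, ncol(norm), n - 1)
  pcs <- pca_scores(norm, n_pcs)
  nn <- knn_indices(pcs, k)
  imputed <- matrix(0, n, ncol(norm), dimnames = dimnames(norm))
  for (i in seq_len(n))
    imputed[i, ] <- colMeans(norm[nn[i, ], , drop = FALSE])
  structure(list(x = imputed, norm = norm, pcs = pcs, neighbors = nn, k = k),
            class = "knn_imputed")
}

## k nearest rows (self included) by Euclidean distance; deterministic
## tie-break by index order.
knn_indices <- function(pcs, k) {
  n <- nrow(pcs)
  sq <- rowSums(pcs^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pcs)
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    nn[i, ] <- order(d2[i, ])[seq_len(k)]
  }
  nn
}

#' Fit a context-specific GRN by bagged ridge regression
#'
#' For every target gene with candidate regulators in the base GRN, the
#' imputed target expression is regressed (ridge, fixed penalty on
#' standardized regressors) on the imputed expression of its candidate
#' regulators over the context's cells, with bagging: `bags` bootstrap
#' resamples, coefficient = bagged mean.  An edge is retained when
#' `|mean| / sd(bag estimates)` exceeds `retain_z` and the coefficient
#' sign is stable in at least `sign_frac` of the resamples.  Edges outside
#' the base GRN never appear; zero-variance regulators are dropped per
#' target.
#'
#' @param imputed A [knn_impute()] result (or a plain cells x genes
#'   matrix).
#' @param base Base GRN: data.frame with columns `regulator`, `target`.
#' @param context_mask Logical or integer subset of cells defining the
#'   context; `NULL` uses all cells.
#' @param context_label Label stored on the result.
#' @param lambda Ridge penalty on standardized regressors.
#' @param bags Number of bootstrap resamples.
#' @param retain_z Retention threshold on `|mean| / sd(bags)`.
#' @param sign_frac Minimum fraction of resamples agreeing with the
#'   coefficient sign.
#' @param min_cells Minimum context size.
#' @param seed Bagging seed (fanned out per target; resampling is done on
#'   cells sorted by id, so cell order does not affect the result).
#' @return A list of class `inferred_grn` with `context`, `edges`
#'   (regulator, target, coef, se, sign_frac, retained) and `genes` (the
#'   fitted-gene list).
#' @export
fit_grn <- function(imputed, base, context_mask = NULL,
                    context_label = "all", lambda = 1, bags = 20,
                    retain_z = 2, sign_frac = 0.8, min_cells = 50,
                    seed = 1L) {
  x <- if (inherits(imputed, "knn_imputed")) imputed$x else imputed
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (anyDuplicated(base[, c("regulator", "target")]))
    base <- base[!duplicated(base[, c("regulator", "target")]), ]
  cells <- seq_len(nrow(x))
  if (!is.null(context_mask)) cells <- cells[context_mask]
  if (length(cells) == 0)
    stop("empty context: ", context_label, call. = FALSE)
  if (length(cells) < min_cells)
    stop("context ", context_label, " has fewer than ", min_cells, " cells",
         call. = FALSE)
  xc <- x[cells, , drop = FALSE]
  ## sort by cell id so bagging is invariant to the input cell order
  if (!is.null(rownames(xc))) xc <- xc[order(rownames(xc)), , drop = FALSE]
  n <- nrow(xc)
  genes <- colnames(xc)
  base <- base[base$target %in% genes & base$regulator %in% genes, ]
  targets <- sort(unique(base$target))

  res <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    tgt <- targets[ti]
    regs <- sort(unique(base$regulator[base$target == tgt]))
    regs <- setdiff(regs, tgt)
    Z <- xc[, regs, drop = FALSE]
    sds <- apply(Z, 2, sd)
    if (any(sds == 0)) {
      message("dropping zero-variance regulators for ", tgt, ": ",
              paste(regs[sds == 0], collapse = ", "))
      regs <- regs[sds > 0]
      Z <- Z[, regs, drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (length(regs) == 0) next
    Z <- scale(Z)
    y <- xc[, tgt] - mean(xc[, tgt])
    p <- ncol(Z)
    set.seed(stage_seed(seed, paste0("bag_", context_label, "_", tgt)))
    betas <- matrix(0, bags, p)
    for (b in seq_len(bags)) {
      idx <- sample.int(n, n, replace = TRUE)
      Zb <- Z[idx, , drop = FALSE]
      betas[b, ] <- solve(crossprod(Zb) + diag(lambda, p),
                          crossprod(Zb, y[idx]))
    }
    cf <- colMeans(betas)
    se <- apply(betas, 2, sd)
    sf <- colMeans(sweep(sign(betas), 2, sign(cf), "=="))
    res[[ti]] <- data.frame(regulator = regs, target = tgt, coef = cf,
                            se = se, sign_frac = sf,
                            retained = abs(cf) / pmax(se, 1e-12) > retain_z &
                              sf >= sign_frac,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  edges <- do.call(rbind, res)
  if (is.null(edges))
    edges <- data.frame(regulator = character(0), target = character(0),
                        coef = numeric(0), se = numeric(0),
                        sign_frac = numeric(0), retained = logical(0))
  structure(list(context = context_label, edges = edges, genes = genes),
            class = "inferred_grn")
}

#' @export
print.inferred_grn <- function(x, ...) {
  cat("inferred_grn [", x$context, "]: ", nrow(x$edges), " candidate edges, ",
      sum(x$edges$retained), " retained, ", length(x$genes),
      " fitted genes\n", sep = "")
  invisible(x)
}

#' Eigenvector centrality of an inferred GRN
#'
#' Power iteration on the undirected weighted projection of the retained
#' edges (weights = absolute coefficients; reciprocal edges sum).
#' Convergence when the L-infinity change of the unit-norm iterate falls
#' below `tol` or after `max_iter` iterations; centralities are
#' max-normalized so the most central node scores 1.
#'
#' @param grn An [fit_grn()] result, or a data.frame of edges with
#'   columns `regulator`, `target`, `coef` (and optional `retained`).
#' @param tol,max_iter Power-iteration controls.
#' @return A data.frame of class `centrality_table` with columns `node`,
#'   `centrality`; the attribute `context` carries the GRN's context.
#' @export
eigenvector_centrality <- function(grn, tol = 1e-10, max_iter = 10000) {
  edges <- if (inherits(grn, "inferred_grn")) grn$edges else grn
  if ("retained" %in% colnames(edges)) edges <- edges[edges$retained, ]
  ctx <- if (inherits(grn, "inferred_grn")) grn$context else "all"
  if (nrow(edges) == 0) {
    warning("no retained edges; all centralities zero")
    nodes <- if (inherits(grn, "inferred_grn")) grn$genes else character(0)
    out <- data.frame(node = nodes, centrality = rep(0, length(nodes)))
    class(out) <- c("centrality_table", "data.frame")
    attr(out, "context") <- ctx
    return(out)
  }
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w <- abs(edges$coef)
  for (i in seq_len(nrow(edges))) {
    r <- edges$regulator[i]; t <- edges$target[i]
    A[r, t] <- A[r, t] + w[i]
    A[t, r] <- A[t, r] + w[i]
  }
  ## small diagonal shift: preserves eigenvectors, prevents the sign
  ## oscillation power iteration suffers on bipartite graphs
  shift <- 0.1 * max(rowSums(A))
  v <- rep(1 / sqrt(length(nodes)), length(nodes))
  for (it in seq_len(max_iter)) {
    v2 <- as.numeric(A %*% v) + shift * v
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) break
    v2 <- v2 / nrm
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      break
    }
    v <- v2
  }
  v <- abs(v)
  v <- v / max(v)
  out <- data.frame(node = nodes, centrality = v, row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "context") <- ctx
  out
}

#' Mean TF centrality per context
#'
#' Reports, per context, the mean centrality over TFs both as the raw
#' mean of the max-normalized values (`mean_tf_centrality`) and relative
#' to the mean centrality of all nodes in that network
#' (`tf_centrality_ratio`).  The ratio is invariant to the per-network
#' normalization (max, L2 or sum), which makes it the comparable
#' statistic across independently fitted and normalized networks; the
#' raw mean additionally reflects how localized each network's leading
#' eigenvector happens to be.
#'
#' @param tables Named list of [eigenvector_centrality()] tables, keyed
#'   `"population|timepoint"` (any `"a|b"` key works).
#' @param tf_list TF gene ids.
#' @return Data.frame with `population`, `timepoint`,
#'   `mean_tf_centrality`, `tf_centrality_ratio` and `n_tfs`; contexts
#'   whose network contains no TF get `NA` with a warning.
#' @export
centrality_contrast <- function(tables, tf_list) {
  rows <- lapply(names(tables), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tab <- tables[[key]]
    tfs <- intersect(tab$node, tf_list)
    if (length(tfs) == 0 || all(tab$centrality == 0)) {
      warning("context ", key, " has no TFs in its network")
      m <- NA_real_
      r <- NA_real_
    } else {
      m <- mean(tab$centrality[match(tfs, tab$node)])
      r <- m / mean(tab$centrality)
    }
    data.frame(population = parts[1],
               timepoint = if (length(parts) > 1) parts[2] else NA,
               mean_tf_centrality = m, tf_centrality_ratio = r,
               n_tfs = length(tfs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
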