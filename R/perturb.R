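#' Simulate an in silico TF knockout with GRN signal propagation
#'
#' The knockout sets the TF's imputed expression to zero in every cell:
#' the initial shift `dX0` has only the TF entry set to `-x_tf`.  The
#' shift is then propagated `n_propagation` times through the retained
#' network coefficients (`dX_{t+1} = dX_t %*% W`, where
#' `W[regulator, target]` is the retained coefficient); after each step
#' the cumulative simulated expression is clamped at zero (expression
#' cannot go negative) and the knocked-out TF is pinned at zero.  The
#' returned shift is the cumulative sum over steps.
#'
#' @param imputed A [knn_impute()] result or cells x genes matrix.
#' @param grn An [fit_grn()] result.
#' @param tf TF gene id to knock out.
#' @param n_propagation Number of propagation steps (>= 1).
#' @return A list of class `ko_shift` with `tf`, `delta` (cells x genes)
#'   and `n_propagation`.
#' @export
simulate_ko <- function(imputed, grn, tf, n_propagation = 3) {
  x <- if (inherits(imputed, "knn_imputed")) imputed$x else imputed
  stopifnot(inherits(grn, "inferred_grn"), n_propagation >= 1)
  genes <- intersect(colnames(x), grn$genes)
  x <- x[, genes, drop = FALSE]
  if (!tf %in% genes) {
    avail <- sort(unique(grn$edges$regulator[grn$edges$retained]))
    stop("TF ", tf, " is not in the network; available regulators: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  ee <- grn$edges[grn$edges$retained, ]
  ee <- ee[ee$regulator %in% genes & ee$target %in% genes, ]
  W <- Matrix::sparseMatrix(i = match(ee$regulator, genes),
                            j = match(ee$target, genes),
                            x = ee$coef,
                            dims = c(length(genes), length(genes)))
  delta0 <- matrix(0, nrow(x), length(genes), dimnames = dimnames(x))
  delta0[, tf] <- -x[, tf]
  cum <- delta0
  cur <- delta0
  for (t in seq_len(n_propagation)) {
    cur <- as.matrix(cur %*% W)
    cum <- cum + cur
    ## clamp: simulated expression stays non-negative; KO gene pinned at 0
    cum <- pmax(x + cum, 0) - x
    cum[, tf] <- -x[, tf]
  }
  structure(list(tf = tf, delta = cum, n_propagation = n_propagation),
            class = "ko_shift")
}

#' Project a knockout expression shift onto a 2D embedding
#'
#' For each cell `i`, the Pearson correlation between its shift vector
#' `dX_i` and the expression difference `X_j - X_i` is computed for each
#' of its `k_neighbors` nearest expression neighbors (in the imputation's
#' PC space).  Correlations are mapped to transition weights by an
#' exponential kernel (`exp(cor / temperature)`, normalized), and the 2D
#' shift is the weighted mean of the unit embedding-space vectors toward
#' the neighbors minus their unweighted mean (removing embedding-density
#' bias).  Cells with an all-zero shift get zero vectors; a constant
#' nonzero shift has undefined correlation and also yields a zero vector
#' with a warning.
#'
#' @param shift A [simulate_ko()] result.
#' @param imputed The [knn_impute()] result the shift was computed from.
#' @param embedding Cells x 2 matrix (any 2D embedding).
#' @param k_neighbors Number of expression neighbors (>= 2; clamped to
#'   n - 1).
#' @param temperature Exponential-kernel temperature on correlations.
#' @param neighbors Optional precomputed cells x k neighbor index matrix
#'   (excluding self), e.g. shared across TFs in a screen.
#' @param cache Optional [projection_cache()] shared across TFs in a
#'   screen (built on the fly otherwise).
#' @return A list of class `embedding_field` with `vectors` (cells x 2)
#'   and `embedding`.
#' @export
project_shift <- function(shift, imputed, embedding, k_neighbors = 200,
                          temperature = 0.05, neighbors = NULL,
                          cache = NULL) {
  stopifnot(inherits(shift, "ko_shift"), k_neighbors >= 2)
  x <- if (inherits(imputed, "knn_imputed")) imputed$x else imputed
  emb <- as.matrix(embedding)
  stopifnot(ncol(emb) == 2, nrow(emb) == nrow(x))
  genes <- colnames(shift$delta)
  x <- x[, genes, drop = FALSE]
  n <- nrow(x)
  k <- min(k_neighbors, n - 1)
  if (is.null(cache)) {
    if (is.null(neighbors)) {
      pcs <- if (inherits(imputed, "knn_imputed")) imputed$pcs else x
      neighbors <- strip_self(knn_indices(pcs, k + 1), k)
    }
    cache <- projection_cache(x, emb, neighbors)
  }
  nb <- cache$neighbors
  k <- ncol(nb)
  G <- ncol(x)

  delta <- shift$delta
  dc <- delta - rowMeans(delta)
  dn <- sqrt(rowSums(dc^2))
  active <- rowSums(delta != 0) > 0
  const <- active & dn == 0
  live <- active & dn > 0

  vec <- matrix(0, n, 2, dimnames = list(rownames(x), c("v1", "v2")))
  if (any(live)) {
    ## numerator of cor(dX_i, X_j - X_i): centering over genes drops out,
    ## so one matmul gives <X_j, dc_i> for every (i, j) pair at once
    N <- x %*% t(dc)                      # N[j, i] = <X_j, dc_i>
    idx <- cbind(as.vector(nb), rep(seq_len(n), k))
    num <- matrix(N[idx], n, k) - diag(N)
    cc <- num / (cache$vn * dn)
    cc[cache$vn == 0] <- 0
    P <- exp(cc / temperature)
    P <- P / rowSums(P)
    vx <- rowSums(P * cache$ux) - cache$ubar[, 1]
    vy <- rowSums(P * cache$uy) - cache$ubar[, 2]
    vec[live, 1] <- vx[live]
    vec[live, 2] <- vy[live]
  }
  if (any(const))
    warning("constant nonzero shift in some cells; correlation undefined, ",
            "zero vectors assigned")
  structure(list(vectors = vec, embedding = emb), class = "embedding_field")
}

#' Precomputed geometry for [project_shift()]
#'
#' Stores, per cell, the centered-difference norms to its expression
#' neighbors and the unit embedding vectors toward them, so a TF screen
#' pays the neighbor geometry once rather than per knockout.
#'
#' @param x Cells x genes imputed matrix.
#' @param embedding Cells x 2 embedding.
#' @param neighbors Cells x k neighbor index matrix (excluding self).
#' @return A list of class `projection_cache`.
#' @export
projection_cache <- function(x, embedding, neighbors) {
  n <- nrow(x)
  k <- ncol(neighbors)
  G <- ncol(x)
  emb <- as.matrix(embedding)
  gram <- tcrossprod(x)
  sq <- diag(gram)
  m <- rowMeans(x)
  gv <- matrix(gram[cbind(rep(seq_len(n), k), as.vector(neighbors))], n, k)
  sqn <- matrix(sq[neighbors], n, k)
  mn <- matrix(m[neighbors], n, k)
  ## |centered (X_j - X_i)|^2 = |X_j - X_i|^2 - G * mean(X_j - X_i)^2
  vn2 <- sq + sqn - 2 * gv - G * (mn - m)^2
  vn <- sqrt(pmax(vn2, 0))
  vn[vn < 1e-12] <- 0
  ex <- matrix(emb[neighbors, 1], n, k) - emb[, 1]
  ey <- matrix(emb[neighbors, 2], n, k) - emb[, 2]
  un <- sqrt(ex^2 + ey^2)
  un[un < 1e-12] <- 1e-12
  ux <- ex / un
  uy <- ey / un
  structure(list(neighbors = neighbors, vn = vn, ux = ux, uy = uy,
                 ubar = cbind(rowMeans(ux), rowMeans(uy))),
            class = "projection_cache")
}

strip_self <- function(nn, k) {
  t(vapply(seq_len(nrow(nn)), function(i) {
    row <- nn[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
}

#' Grid geometry over an embedding bounding box
#' @keywords internal
grid_geometry <- function(embedding, grid_size, bandwidth = NULL) {
  emb <- as.matrix(embedding)
  rx <- range(emb[, 1]); ry <- range(emb[, 2])
  if (is.null(bandwidth))
    bandwidth <- max(diff(rx), diff(ry)) / 25
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  list(xs = seq(rx[1], rx[2], length.out = grid_size),
       ys = seq(ry[1], ry[2], length.out = grid_size),
       bandwidth = bandwidth, grid_size = grid_size)
}

## Gaussian-kernel smoothing of per-cell values onto the grid.
## values: cells x p matrix.  Returns list(values = G x G x p array slices
## as list, mask = G x G occupancy).
smooth_to_grid <- function(embedding, values, geom) {
  emb <- as.matrix(embedding)
  values <- as.matrix(values)
  G <- geom$grid_size
  h <- geom$bandwidth
  dx2 <- outer(geom$xs, emb[, 1], "-")^2      # G x n
  dy2 <- outer(geom$ys, emb[, 2], "-")^2
  out <- lapply(seq_len(ncol(values)), function(j) matrix(0, G, G))
  mask <- matrix(FALSE, G, G)
  for (gy in seq_len(G)) {
    d2 <- t(dx2) + dy2[gy, ]                  # n x G (x index)
    w <- exp(-d2 / (2 * h^2))
    near <- colSums(d2 <= (2 * h)^2) > 0
    mask[, gy] <- near
    sw <- colSums(w)
    for (j in seq_len(ncol(values))) {
      v <- colSums(w * values[, j]) / pmax(sw, 1e-300)
      v[!near] <- 0
      out[[j]][, gy] <- v
    }
  }
  list(values = out, mask = mask)
}

#' Topic-loading gradient field on a 2D embedding grid
#'
#' The topic's per-cell loading is smoothed onto a regular grid over the
#' embedding bounding box by Gaussian-kernel weighted averaging; grid
#' nodes with no cell within twice the bandwidth are masked.  The 2D
#' gradient is computed by central finite differences on occupied nodes
#' (one-sided at mask borders, zero where no occupied neighbor exists).
#'
#' @param fit A [fit_topic_model()] result, or a numeric vector of
#'   per-cell loadings.
#' @param topic Topic index (ignored when `fit` is a vector).
#' @param embedding Cells x 2 matrix.
#' @param grid_size Nodes per grid side.
#' @param bandwidth Gaussian kernel bandwidth; default 1/25 of the larger
#'   bounding-box side.
#' @return A list of class `topic_gradient` with `topic`, `xs`, `ys`,
#'   `value`, `gx`, `gy` (grid matrices, x-index by y-index), `mask` and
#'   `geom`.
#' @export
topic_gradient <- function(fit, topic = 1, embedding, grid_size = 40,
                           bandwidth = NULL) {
  z <- if (inherits(fit, "topic_fit")) {
    stopifnot(topic >= 1, topic <= fit$K)
    fit$L[, topic]
  } else as.numeric(fit)
  emb <- as.matrix(embedding)
  stopifnot(length(z) == nrow(emb))
  geom <- grid_geometry(emb, grid_size, bandwidth)
  sm <- smooth_to_grid(emb, matrix(z, ncol = 1), geom)
  value <- sm$values[[1]]
  mask <- sm$mask
  g <- grid_gradient(value, mask, geom$xs, geom$ys)
  structure(list(topic = topic, xs = geom$xs, ys = geom$ys, value = value,
                 gx = g$gx, gy = g$gy, mask = mask, geom = geom),
            class = "topic_gradient")
}

## Finite-difference gradient respecting the occupancy mask.
grid_gradient <- function(value, mask, xs, ys) {
  G <- nrow(value)
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  gx <- matrix(0, G, G)
  gy <- matrix(0, G, G)
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (!mask[i, j]) next
      lo <- i > 1 && mask[i - 1, j]
      hi <- i < G && mask[i + 1, j]
      gx[i, j] <- if (lo && hi) (value[i + 1, j] - value[i - 1, j]) / (2 * dx)
      else if (hi) (value[i + 1, j] - value[i, j]) / dx
      else if (lo) (value[i, j] - value[i - 1, j]) / dx
      else 0
      lo <- j > 1 && mask[i, j - 1]
      hi <- j < G && mask[i, j + 1]
      gy[i, j] <- if (lo && hi) (value[i, j + 1] - value[i, j - 1]) / (2 * dy)
      else if (hi) (value[i, j + 1] - value[i, j]) / dy
      else if (lo) (value[i, j] - value[i, j - 1]) / dy
      else 0
    }
  }
  list(gx = gx, gy = gy)
}

#' Dot-product perturbation score of a knockout field against a topic
#' gradient
#'
#' The per-cell 2D shift vectors are smoothed onto the gradient's grid
#' (same kernel and occupancy rule); the score is the mean over jointly
#' occupied nodes of the dot product between the perturbation vector and
#' the topic gradient vector.  A negative score means the knockout moves
#' cells down the topic's gradient, away from that functional state.
#'
#' @param field An [project_shift()] result.
#' @param grad A [topic_gradient()] result computed on the same
#'   embedding.
#' @return A single signed numeric score.
#' @export
perturbation_score <- function(field, grad) {
  stopifnot(inherits(field, "embedding_field"),
            inherits(grad, "topic_gradient"))
  sm <- smooth_to_grid(field$embedding, field$vectors, grad$geom)
  joint <- sm$mask & grad$mask
  if (!any(joint))
    stop("geometry mismatch: occupancy masks are disjoint", call. = FALSE)
  vx <- sm$values[[1]]; vy <- sm$values[[2]]
  sum((vx * grad$gx + vy * grad$gy)[joint]) / sum(joint)
}

#' Screen every TF in a network by in silico knockout
#'
#' For each TF with retained outgoing edges: simulate the knockout,
#' project the expression shift onto the embedding, and score it against
#' the homeostasis and inflammation topic gradients.  The score vector's
#' magnitude (Euclidean norm of the two components) is the per-TF measure
#' of how destabilizing the knockout is.
#'
#' @param imputed A [knn_impute()] result for the context's cells.
#' @param grn The context's [fit_grn()] result.
#' @param fit The [fit_topic_model()] result (loadings for the context's
#'   cells).
#' @param embedding Cells x 2 matrix for the context's cells.
#' @param topics Length-2 integer vector: (homeostasis topic index,
#'   inflammation topic index).
#' @param tf_list TFs to screen; default all regulators with retained
#'   edges.
#' @param k_neighbors,temperature Passed to [project_shift()].
#' @param grid_size,bandwidth Passed to [topic_gradient()].
#' @param n_propagation Passed to [simulate_ko()].
#' @return A data.frame of class `tf_screen` with columns `tf`,
#'   `score_homeostasis`, `score_inflammation`, `magnitude`.
#' @export
tf_screen <- function(imputed, grn, fit, embedding, topics = c(1, 2),
                      tf_list = NULL, k_neighbors = 200,
                      temperature = 0.05, grid_size = 40,
                      bandwidth = NULL, n_propagation = 3) {
  stopifnot(length(topics) == 2)
  regs <- sort(unique(grn$edges$regulator[grn$edges$retained]))
  tfs <- if (is.null(tf_list)) regs else intersect(tf_list, regs)
  emb <- as.matrix(embedding)
  L <- if (inherits(fit, "topic_fit")) fit$L else as.matrix(fit)
  grad_h <- topic_gradient(L[, topics[1]], embedding = emb,
                           grid_size = grid_size, bandwidth = bandwidth)
  grad_i <- topic_gradient(L[, topics[2]], embedding = emb,
                           grid_size = grid_size, bandwidth = bandwidth)
  x <- if (inherits(imputed, "knn_imputed")) imputed$x else imputed
  n <- nrow(x)
  k <- min(k_neighbors, n - 1)
  pcs <- if (inherits(imputed, "knn_imputed")) imputed$pcs else x
  neighbors <- strip_self(knn_indices(pcs, k + 1), k)
  xg <- x[, intersect(colnames(x), grn$genes), drop = FALSE]
  cache <- projection_cache(xg, emb, neighbors)
  rows <- lapply(tfs, function(tf) {
    shift <- simulate_ko(imputed, grn, tf, n_propagation = n_propagation)
    field <- project_shift(shift, imputed, emb, k_neighbors = k,
                           temperature = temperature, cache = cache)
    sh <- perturbation_score(field, grad_h)
    si <- perturbation_score(field, grad_i)
    data.frame(tf = tf, score_homeostasis = sh, score_inflammation = si,
               magnitude = sqrt(sh^2 + si^2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), score_homeostasis = numeric(0),
                      score_inflammation = numeric(0), magnitude = numeric(0))
  class(out) <- c("tf_screen", "data.frame")
  out
}
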