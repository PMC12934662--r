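# helpers to build small networks and imputed matrices by hand
toy_grn <- function(edges, genes) {
  edges$se <- 0.01
  edges$sign_frac <- 1
  if (is.null(edges$retained)) edges$retained <- TRUE
  structure(list(context = "toy", edges = edges, genes = genes),
            class = "inferred_grn")
}

toy_x <- function(mat, genes) {
  colnames(mat) <- genes
  rownames(mat) <- sprintf("c%02d", seq_len(nrow(mat)))
  mat
}

test_that("a TF with no outgoing edges shifts only its own coordinate", {
  genes <- c("TF", "g1")
  x <- toy_x(cbind(c(2, 3), c(1, 1)), genes)
  g <- toy_grn(data.frame(regulator = "g1", target = "TF", coef = 0,
                          retained = FALSE), genes)
  ko <- simulate_ko(x, g, "TF")
  expect_equal(ko$delta[, "TF"], -x[, "TF"], ignore_attr = TRUE)
  expect_true(all(ko$delta[, "g1"] == 0))
})

test_that("single-edge chain matches the hand computation", {
  genes <- c("TF", "g1")
  x <- toy_x(cbind(c(2, 2), c(5, 5)), genes)
  g <- toy_grn(data.frame(regulator = "TF", target = "g1", coef = 0.5),
               genes)
  for (steps in 1:3) {
    ko <- simulate_ko(x, g, "TF", n_propagation = steps)
    expect_equal(unname(ko$delta[1, "g1"]), -1)  # -2 * 0.5, then stable
  }
})

test_that("two-step chain equals the matrix-power closed form on a DAG", {
  genes <- c("TF", "g1", "g2")
  x <- toy_x(cbind(c(2, 1), c(5, 5), c(4, 4)), genes)
  g <- toy_grn(data.frame(regulator = c("TF", "g1"),
                          target = c("g1", "g2"),
                          coef = c(0.5, 0.4)), genes)
  ko <- simulate_ko(x, g, "TF", n_propagation = 2)
  expect_equal(unname(ko$delta[1, "g2"]), -2 * 0.5 * 0.4)
  # closed form: delta0 (I + W + W^2 + ...) for clamp-inactive DAGs
  W <- matrix(0, 3, 3, dimnames = list(genes, genes))
  W["TF", "g1"] <- 0.5; W["g1", "g2"] <- 0.4
  d0 <- matrix(0, 2, 3, dimnames = list(rownames(x), genes))
  d0[, "TF"] <- -x[, "TF"]
  closed <- d0 + d0 %*% W + d0 %*% W %*% W
  expect_equal(ko$delta, closed, tolerance = 1e-12)
})

test_that("simulate_ko matches the DAG closed form on a random network", {
  set.seed(17)
  n_genes <- 12
  genes <- sprintf("g%02d", seq_len(n_genes))
  # upper-triangular (topologically ordered) random DAG, small coefficients
  ee <- expand.grid(regulator = genes, target = genes,
                    stringsAsFactors = FALSE)
  ee <- ee[match(ee$regulator, genes) < match(ee$target, genes), ]
  ee <- ee[sample(nrow(ee), 20), ]
  ee$coef <- runif(20, -0.1, 0.1)
  g <- toy_grn(ee, genes)
  # large expression so clamping never activates
  x <- toy_x(matrix(runif(5 * n_genes, 50, 100), 5), genes)
  tf <- "g01"
  ko <- simulate_ko(x, g, tf, n_propagation = 3)
  W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  W[cbind(ee$regulator, ee$target)] <- ee$coef
  d0 <- matrix(0, 5, n_genes, dimnames = list(rownames(x), genes))
  d0[, tf] <- -x[, tf]
  closed <- d0
  P <- diag(n_genes)
  for (t in 1:3) {
    P <- P %*% W
    closed <- closed + d0 %*% P
  }
  expect_lt(max(abs(ko$delta - closed)), 1e-10)
})

test_that("clamping keeps simulated expression non-negative", {
  genes <- c("TF", "g1")
  x <- toy_x(cbind(c(2, 2), c(0.5, 0.5)), genes)
  g <- toy_grn(data.frame(regulator = "TF", target = "g1", coef = 2),
               genes)
  ko <- simulate_ko(x, g, "TF")   # raw shift would be -4 < -0.5
  expect_equal(unname(ko$delta[, "g1"]), c(-0.5, -0.5))
})

test_that("unknown TF raises an error listing available regulators", {
  genes <- c("TF", "g1")
  x <- toy_x(cbind(c(2, 2), c(5, 5)), genes)
  g <- toy_grn(data.frame(regulator = "TF", target = "g1", coef = 0.5),
               genes)
  expect_error(simulate_ko(x, g, "nope"), "TF")
})

test_that("a null shift projects to zero vectors everywhere", {
  set.seed(3)
  genes <- paste0("g", 1:6)
  x <- toy_x(matrix(runif(60), 10), genes)
  emb <- matrix(rnorm(20), 10, 2)
  shift <- structure(list(tf = "g1",
                          delta = matrix(0, 10, 6,
                                         dimnames = dimnames(x)),
                          n_propagation = 3),
                     class = "ko_shift")
  f <- project_shift(shift, x, emb, k_neighbors = 3)
  expect_true(all(f$vectors == 0))
})

test_that("a shift matching a neighbor difference points toward it", {
  # 3 cells on a line in expression space; cell 1's shift equals
  # (X2 - X1) exactly, so the transition weight concentrates on cell 2
  genes <- paste0("g", 1:4)
  x <- toy_x(rbind(c(1, 2, 3, 4),
                   c(2, 4, 2, 5),
                   c(0, 1, 6, 2)), genes)
  emb <- rbind(c(0, 0), c(1, 0), c(0, 1))
  delta <- rbind(x[2, ] - x[1, ], rep(0, 4), rep(0, 4))
  dimnames(delta) <- dimnames(x)
  shift <- structure(list(tf = "g1", delta = delta, n_propagation = 1),
                     class = "ko_shift")
  f <- project_shift(shift, x, emb, k_neighbors = 2)
  # unit vectors toward cells 2 and 3 are (1,0) and (0,1); weight on
  # cell 2 dominates, so after baseline subtraction v1 > 0 > v2
  expect_gt(f$vectors[1, 1], 0)
  expect_lt(f$vectors[1, 2], 0)
  expect_true(all(f$vectors[2:3, ] == 0))
})

test_that("topic gradients vanish for constant loadings", {
  set.seed(6)
  emb <- matrix(runif(200), 100, 2)
  g <- topic_gradient(rep(0.4, 100), embedding = emb, grid_size = 12)
  expect_lt(max(abs(g$gx[g$mask])), 1e-10)
  expect_lt(max(abs(g$gy[g$mask])), 1e-10)
  expect_true(all(g$gx[!g$mask] == 0))
})

test_that("a linear field has the analytic gradient on interior nodes", {
  # dense uniform grid of cells; loading = x coordinate => gradient (1, 0)
  gr <- expand.grid(x = seq(0, 1, length.out = 40),
                    y = seq(0, 1, length.out = 40))
  emb <- as.matrix(gr)
  g <- topic_gradient(emb[, 1], embedding = emb, grid_size = 20)
  interior <- matrix(FALSE, 20, 20)
  interior[4:17, 4:17] <- TRUE
  rel_err <- abs(g$gx[interior] - 1)
  expect_lt(max(rel_err), 0.05)
  expect_lt(max(abs(g$gy[interior])), 0.05)
  expect_error(topic_gradient(emb[, 1], embedding = emb, grid_size = 20,
                              bandwidth = -1), "bandwidth")
})

test_that("perturbation scores obey the inner-product identities", {
  set.seed(30)
  emb <- as.matrix(expand.grid(x = seq(0, 1, length.out = 15),
                               y = seq(0, 1, length.out = 15)))
  n <- nrow(emb)
  grad <- topic_gradient(emb[, 1] + 0.5 * emb[, 2], embedding = emb,
                         grid_size = 10)
  mk_field <- function(v) structure(list(vectors = v, embedding = emb),
                                    class = "embedding_field")
  # field equal to the analytic gradient direction: positive self score
  f_pos <- mk_field(cbind(rep(1, n), rep(0.5, n)))
  s_pos <- perturbation_score(f_pos, grad)
  expect_gt(s_pos, 0)
  # orthogonal field: zero score
  f_orth <- mk_field(cbind(rep(-0.5, n), rep(1, n)))
  expect_lt(abs(perturbation_score(f_orth, grad)), 1e-10)
  # antisymmetry is exact
  f_neg <- mk_field(-f_pos$vectors)
  expect_equal(perturbation_score(f_neg, grad), -s_pos, tolerance = 1e-12)
})

test_that("score scales monotonically with the field amplitude", {
  set.seed(31)
  emb <- matrix(runif(160), 80, 2)
  grad <- topic_gradient(emb[, 1], embedding = emb, grid_size = 10)
  v <- cbind(runif(80, -1, 1), runif(80, -1, 1))
  scores <- sapply(c(0.5, 1, 2), function(cc)
    perturbation_score(structure(list(vectors = cc * v, embedding = emb),
                                 class = "embedding_field"), grad))
  expect_equal(scores[2] / scores[1], 2, tolerance = 1e-9)
  expect_equal(scores[3] / scores[2], 2, tolerance = 1e-9)
})

test_that("tf_screen returns zero magnitudes for an all-zero network", {
  set.seed(32)
  genes <- paste0("g", 1:5)
  x <- toy_x(matrix(runif(100, 1, 2), 20), genes)
  g <- toy_grn(data.frame(regulator = "g1", target = "g2", coef = 0),
               genes)
  emb <- matrix(rnorm(40), 20, 2)
  L <- cbind(runif(20), runif(20))
  scr <- tf_screen(x, g, L, emb, topics = c(1, 2), k_neighbors = 5,
                   grid_size = 8)
  # knocking out g1 still shifts g1 itself, but the propagated effect on
  # the rest of the transcriptome is nil, so scores are tiny but defined
  expect_identical(scr$tf, "g1")
  expect_true(all(is.finite(scr$magnitude)))
  expect_equal(scr$magnitude,
               sqrt(scr$score_homeostasis^2 + scr$score_inflammation^2),
               tolerance = 1e-12)
})
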