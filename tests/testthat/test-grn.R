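test_that("select_genes filters, ranks and unions deterministically", {
  x <- rbind(c(5, 6, 5, 6), c(0, 0, 0, 0), c(1, 9, 1, 9), c(2, 2, 2, 2))
  cm <- count_matrix(x, c("gA", "gZero", "gVar", "gTF"),
                     paste0("c", 1:4),
                     data.frame(population = rep("p", 4), timepoint = 0))
  # all-zero gene excluded even when listed as a TF
  expect_message(sel <- select_genes(cm, n_hvg = 2,
                                     tf_list = c("gZero", "gTF")),
                 "gZero")
  expect_false("gZero" %in% sel)
  # union absorbs TFs already in the HVG set
  sel2 <- select_genes(cm, n_hvg = 3, tf_list = "gVar")
  expect_identical(length(sel2), 3L)
  expect_error(select_genes(cm, n_hvg = 0), "n_hvg")
})

test_that("selected gene count follows the union arithmetic", {
  dat <- tiny_dataset()
  tf_list <- dat$truth$tf_ids
  n_hvg <- 60
  sel <- select_genes(dat$counts, n_hvg = n_hvg, tf_list = tf_list)
  expressed <- dat$counts$gene_ids[Matrix::rowSums(dat$counts$counts) > 0]
  hvg <- sel[seq_len(n_hvg)]
  expect_equal(length(sel),
               n_hvg + length(setdiff(intersect(tf_list, expressed), hvg)))
})

test_that("k = 1 imputation is the identity on normalized expression", {
  dat <- tiny_dataset()
  imp <- knn_impute(dat$counts, k_frac = 1e-9)
  expect_identical(imp$k, 1L)
  expect_equal(imp$x, imp$norm, tolerance = 1e-12)
})

test_that("duplicate cells receive identical imputed profiles", {
  x <- cbind(c(5, 1, 3), c(5, 1, 3), c(0, 8, 2), c(0, 8, 2))
  cm <- count_matrix(x, paste0("g", 1:3), paste0("c", 1:4),
                     data.frame(population = rep("p", 4), timepoint = 0))
  imp <- knn_impute(cm, k_frac = 0.5)   # k = 2
  expect_equal(imp$x[1, ], imp$x[2, ], tolerance = 1e-12)
  expect_equal(imp$x[3, ], imp$x[4, ], tolerance = 1e-12)
})

test_that("neighbor sets match a brute-force all-pairs computation", {
  set.seed(21)
  n <- 60
  pcs <- matrix(rnorm(n * 5), n, 5)
  k <- 7
  nn <- topicgrn:::knn_indices(pcs, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(pcs) - pcs[i, ])^2))
    brute <- order(d)[seq_len(k)]
    expect_setequal(nn[i, ], brute)
  }
})

test_that("fit_grn recovers a planted coefficient and rejects a bystander", {
  set.seed(5)
  n <- 300
  tf1 <- rnorm(n)
  tf2 <- rnorm(n)
  y <- 0.8 * tf1 + rnorm(n, sd = 1e-3)
  x <- cbind(TF1 = tf1, TF2 = tf2, target = y)
  rownames(x) <- sprintf("c%03d", seq_len(n))
  base <- data.frame(regulator = c("TF1", "TF2"), target = "target")
  g <- fit_grn(x, base, min_cells = 10, seed = 9)
  e1 <- g$edges[g$edges$regulator == "TF1", ]
  e2 <- g$edges[g$edges$regulator == "TF2", ]
  # regressors are standardized, so rescale to the raw slope
  expect_equal(e1$coef / sd(tf1), 0.8, tolerance = 0.01)
  expect_true(e1$retained)
  expect_false(e2$retained)
  # ordinary-least-squares oracle on the same draw
  ols <- coef(lm(y ~ tf1 + tf2))
  expect_equal(e1$coef / sd(tf1), unname(ols[2]), tolerance = 0.01)
  # permuting cells leaves the bagged coefficients unchanged
  perm <- sample(n)
  g2 <- fit_grn(x[perm, ], base, min_cells = 10, seed = 9)
  expect_equal(g2$edges$coef, g$edges$coef, tolerance = 1e-12)
})

test_that("fit_grn enforces its context and design-matrix contracts", {
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("c%02d", 1:50),
                              c("TF1", "TF2", "g1", "g2")))
  base <- data.frame(regulator = c("TF1", "TF2"), target = "g1")
  expect_error(fit_grn(x, base, context_mask = rep(FALSE, 50),
                       context_label = "empty"), "empty")
  expect_error(fit_grn(x, base, context_mask = 1:10, min_cells = 50),
               "fewer than")
  # zero-variance regulator dropped with a message, fit proceeds
  x[, "TF2"] <- 1
  expect_message(g <- fit_grn(x, base, min_cells = 10, seed = 2), "TF2")
  expect_false("TF2" %in% g$edges$regulator)
})

test_that("eigenvector centrality matches closed forms and eigen()", {
  # 3-cycle with unit weights: all nodes equal, max-normalized to 1
  cyc <- data.frame(regulator = c("a", "b", "c"),
                    target = c("b", "c", "a"), coef = 1)
  ct <- eigenvector_centrality(cyc)
  expect_equal(ct$centrality, rep(1, 3), tolerance = 1e-8)
  # star: hub 1, leaves 1/2 (leading eigenvector of K_{1,4})
  star <- data.frame(regulator = "hub", target = paste0("l", 1:4), coef = 1)
  ct2 <- eigenvector_centrality(star)
  expect_equal(ct2$centrality[ct2$node == "hub"], 1, tolerance = 1e-8)
  expect_equal(ct2$centrality[ct2$node != "hub"], rep(0.5, 4),
               tolerance = 1e-8)
  # random weighted graph vs dense eigendecomposition oracle
  set.seed(8)
  nodes <- paste0("n", 1:8)
  ee <- expand.grid(regulator = nodes, target = nodes,
                    stringsAsFactors = FALSE)
  ee <- ee[ee$regulator < ee$target, ]
  ee <- ee[sample(nrow(ee), 16), ]
  ee$coef <- runif(16, -1, 1)
  ct3 <- eigenvector_centrality(ee)
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(ee))) {
    A[ee$regulator[r], ee$target[r]] <- A[ee$regulator[r], ee$target[r]] +
      abs(ee$coef[r])
    A[ee$target[r], ee$regulator[r]] <- A[ee$target[r], ee$regulator[r]] +
      abs(ee$coef[r])
  }
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  v <- v / max(v)
  expect_equal(ct3$centrality[match(nodes, ct3$node)], v, tolerance = 1e-6)
})

test_that("centrality concentrates on the dominant disconnected component", {
  # two triangles, one with heavier weights: its leading eigenvalue wins
  tri <- function(nodes, w) data.frame(regulator = nodes,
                                       target = nodes[c(2, 3, 1)], coef = w)
  ee <- rbind(tri(c("a", "b", "c"), 2), tri(c("x", "y", "z"), 1))
  ct <- eigenvector_centrality(ee)
  heavy <- ct$centrality[ct$node %in% c("a", "b", "c")]
  light <- ct$centrality[ct$node %in% c("x", "y", "z")]
  expect_true(all(heavy > 0.99))
  expect_true(all(light < 1e-6))
})

test_that("centrality is invariant under uniform weight rescaling", {
  set.seed(13)
  ee <- data.frame(regulator = sample(letters[1:6], 10, TRUE),
                   target = sample(letters[1:6], 10, TRUE),
                   coef = runif(10, 0.1, 1))
  ee <- ee[ee$regulator != ee$target, ]
  c1 <- eigenvector_centrality(ee)
  ee2 <- ee; ee2$coef <- ee2$coef * 37
  c2 <- eigenvector_centrality(ee2)
  expect_equal(c1$centrality, c2$centrality, tolerance = 1e-8)
})

test_that("centrality_contrast averages TFs per context and flags gaps", {
  t1 <- data.frame(node = c("TF1", "TF2", "g1"),
                   centrality = c(1, 0.5, 0.2))
  t2 <- data.frame(node = c("g1", "g2"), centrality = c(1, 0.3))
  tabs <- list("popA|0" = t1, "popB|0" = t2)
  expect_warning(out <- centrality_contrast(tabs, c("TF1", "TF2")),
                 "no TFs")
  expect_equal(out$mean_tf_centrality[out$population == "popA"], 0.75)
  expect_true(is.na(out$mean_tf_centrality[out$population == "popB"]))
  # identical networks give identical means
  tabs2 <- list("popA|0" = t1, "popB|0" = t1)
  out2 <- centrality_contrast(tabs2, c("TF1", "TF2"))
  expect_equal(out2$mean_tf_centrality[1], out2$mean_tf_centrality[2])
})

test_that("coefficient error shrinks as nuisance noise vanishes", {
  # deep libraries and no neighborhood averaging, so the nuisance noise
  # on the log-rate scale is the dominant error source
  errs <- sapply(c(0.5, 0.2, 0.05), function(ns) {
    cfg <- synthetic_config(n_cells_per_population = 1000, n_genes = 150,
                            n_tfs = 15, library_size_mean = 10000,
                            noise_sd = ns, seed = 101)
    truth <- generate_ground_truth(cfg)
    cm <- simulate_counts(truth, cfg)
    imp <- knn_impute(cm, k_frac = 1e-9)
    g <- fit_grn(imp, base_grn_from_truth(truth), min_cells = 10, seed = 1)
    te <- truth$grn_edges[truth$grn_edges$population == "both", ]
    key <- paste(te$regulator, te$target)
    fk <- paste(g$edges$regulator, g$edges$target)
    co <- g$edges$coef[match(key, fk)]
    w <- te$weight[!is.na(co)]; co <- co[!is.na(co)]
    # scale-free error: 1 - correlation with the planted weights
    1 - cor(co, w)
  })
  expect_true(all(diff(errs) < 0))
})
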