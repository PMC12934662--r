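#' Fit a multinomial topic model by Poisson non-negative matrix factorization
#'
#' Factorizes the counts as `X ~ Poisson(L F')` (cells x topics, genes x
#' topics) by multiplicative EM updates that maximize the Poisson
#' log-likelihood, then reparametrizes to the multinomial
#' grade-of-membership form: loadings `L` row-stochastic (per-cell topic
#' proportions) and factors `F` column-stochastic (per-topic gene
#' distributions), absorbing the scale factors.  Fitting runs
#' `n_iter_main` iterations followed by `n_iter_refine` further iterations
#' from the incumbent solution; the log-likelihood trace is monotone
#' non-decreasing up to floating-point slack.
#'
#' Genes with all-zero counts are retained and end with zero factor mass.
#'
#' Multiplicative EM updates can stall in local optima, so `n_starts`
#' random initializations are run for `n_iter_pilot` iterations each and
#' the best (highest log-likelihood) incumbent is carried through the full
#' fit -- the usual select-the-best-converged-model practice.
#'
#' @param counts A [count_matrix()] or a genes x cells matrix.
#' @param K Number of topics, `1 <= K <= min(genes, cells)`.
#' @param n_iter_main,n_iter_refine Iteration counts for the main fit and
#'   the refinement continuation (defaults 150 + 150).
#' @param n_starts Number of random initializations screened.
#' @param n_iter_pilot Pilot iterations per screened initialization.
#' @param seed Seed for the random initialization (start `s` uses
#'   `seed + s - 1`).
#' @return A list of class `topic_fit` with elements `L` (cells x K,
#'   rows sum to 1), `F` (genes x K, columns sum to 1), `K`,
#'   `loglik_trace` (one entry per iteration, constant terms dropped),
#'   `size_factors` (per-cell Poisson scale absorbed by the
#'   reparametrization) and `seed`.
#' @export
fit_topic_model <- function(counts, K, n_iter_main = 150,
                            n_iter_refine = 150, n_starts = 3,
                            n_iter_pilot = 25, seed = 1L) {
  X <- if (inherits(counts, "count_matrix")) counts$counts else counts
  X <- as.matrix(X)
  if (length(X) == 0 || sum(X) == 0) stop("counts are empty", call. = FALSE)
  if (K < 1 || K > min(dim(X)))
    stop("invalid K: must satisfy 1 <= K <= min(genes, cells)", call. = FALSE)
  Xt <- t(X)                                     # cells x genes
  n <- nrow(Xt); m <- ncol(Xt)
  eps <- 1e-100
  nz <- which(Xt > 0)
  xnz <- Xt[nz]

  init <- function(s) {
    set.seed(s)
    list(L = matrix(runif(n * K, 0.5, 1.5), n, K) *
           (sum(Xt) / (n * sqrt(m)))^0.5,
         F = matrix(runif(m * K, 0.5, 1.5), m, K) *
           (sum(Xt) / (m * sqrt(n)))^0.5,
         trace = numeric(0))
  }
  run <- function(st, n_iter) {
    L <- st$L; F <- st$F; trace <- st$trace
    for (it in seq_len(n_iter)) {
      M <- L %*% t(F)
      R <- Xt / (M + eps)
      L <- L * (R %*% F) / rep(colSums(F) + eps, each = n)
      M <- L %*% t(F)
      R <- Xt / (M + eps)
      F <- F * (t(R) %*% L) / rep(colSums(L) + eps, each = m)
      M <- L %*% t(F)
      trace[length(trace) + 1] <- sum(xnz * log(M[nz])) - sum(M)
    }
    list(L = L, F = F, trace = trace)
  }

  ## screen random starts with a short pilot, keep the best incumbent
  n_starts <- max(1, n_starts)
  pilots <- lapply(seq_len(n_starts), function(s)
    run(init(seed + s - 1), n_iter_pilot))
  best <- which.max(vapply(pilots, function(p) p$trace[length(p$trace)],
                           numeric(1)))
  st <- pilots[[best]]
  st <- run(st, max(0, n_iter_main - n_iter_pilot))
  st <- run(st, n_iter_refine)
  L <- st$L; F <- st$F; trace <- st$trace

  ## reparametrize to the multinomial grade-of-membership form
  s <- colSums(F)
  Fm <- sweep(F, 2, pmax(s, eps), "/")
  Lm <- sweep(L, 2, s, "*")
  size <- rowSums(Lm)
  Lm <- Lm / pmax(size, eps)
  dimnames(Lm) <- list(colnames(X), paste0("k", seq_len(K)))
  dimnames(Fm) <- list(rownames(X), paste0("k", seq_len(K)))
  structure(list(L = Lm, F = Fm, K = K, loglik_trace = trace,
                 size_factors = size, seed = seed),
            class = "topic_fit")
}

#' @export
print.topic_fit <- function(x, ...) {
  cat("topic_fit: K =", x$K, "|", nrow(x$L), "cells x", nrow(x$F),
      "genes |", length(x$loglik_trace), "iterations\n")
  invisible(x)
}

#' Match fitted topics to reference gene distributions
#'
#' One-to-one assignment of fitted topics to reference topics maximizing
#' the mean cosine similarity of the gene distributions (exhaustive over
#' permutations; intended for small K).
#'
#' @param fit A [fit_topic_model()] result.
#' @param reference A genes x K matrix of reference topic gene
#'   distributions (rows aligned with `fit$F`).
#' @return List with `perm` (fitted topic index assigned to each reference
#'   topic) and `cosine` (per-reference-topic cosine similarity).
#' @export
match_fitted_topics <- function(fit, reference) {
  stopifnot(inherits(fit, "topic_fit"))
  ref <- as.matrix(reference)
  common <- intersect(rownames(fit$F), rownames(ref))
  if (length(common) > 0) {
    est <- fit$F[common, , drop = FALSE]
    ref <- ref[common, , drop = FALSE]
  } else est <- fit$F
  match_topics(est, ref)
}
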