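#' @importFrom methods as is
#' @importFrom stats cor kmeans p.adjust phyper prcomp rgamma rmultinom rnorm
#'   rpois runif sd var rbinom
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-local random seed from a global seed
#'
#' A single global seed is fanned out to the pipeline stages through a
#' counter-free scheme based on the stage name, so that reordering or
#' skipping stages does not perturb the random stream any other stage sees.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2003 + h * 17 + 1) %% .Machine$integer.max
}

## counts: genes x cells (sparse or dense).  Returns cells x genes dense
## matrix of log1p counts-per-`scale` -- the normalization used everywhere
## downstream (marker scoring, pseudobulk, HVG selection, imputation).
normalize_log_cp <- function(counts, scale = 1e4) {
  x <- as.matrix(counts)
  libs <- colSums(x)
  libs[libs == 0] <- 1
  log1p(t(x) / libs * scale)
}

## Rank-based (Mann-Whitney) AUROC of `scores` for binary `labels`.
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

## Best one-to-one matching of columns of `est` to columns of `truth` by
## cosine similarity, by exhaustive permutation (K is small here).  Returns
## the permutation and the per-topic cosines.
match_topics <- function(est, truth) {
  K <- ncol(truth)
  stopifnot(ncol(est) >= K, K <= 7)
  perms <- permutations_of(seq_len(ncol(est)))
  best <- NULL
  best_mean <- -Inf
  for (p in perms) {
    p <- p[seq_len(K)]
    cs <- vapply(seq_len(K), function(k) cosine_sim(est[, p[k]], truth[, k]),
                 numeric(1))
    if (mean(cs) > best_mean) {
      best_mean <- mean(cs)
      best <- list(perm = p, cosine = cs)
    }
  }
  best
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

## Dirichlet draw (vector alpha), one sample.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}
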