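consensus_pwm <- function(cons, id = "m1") {
  bases <- c("A", "C", "G", "T")
  L <- nchar(cons)
  counts <- matrix(1, 4, L, dimnames = list(bases, NULL))
  counts[cbind(match(strsplit(cons, "")[[1]], bases), seq_len(L))] <- 12
  pwm(counts, id = id)
}

test_that("pwm normalizes frequencies and derives log-odds", {
  p <- consensus_pwm("ACGTACGT")
  expect_lt(max(abs(colSums(p$freq) - 1)), 1e-6)
  expect_identical(p$consensus, "ACGTACGT")
  expect_equal(p$max_score, sum(apply(p$log_odds, 2, max)), tolerance = 1e-12)
})

test_that("the consensus scores maximally and substitutions score less", {
  p <- consensus_pwm("ACGTTGCA")
  hits <- scan_pwm(c(s = "ACGTTGCA"), p, threshold = -Inf)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, p$max_score, tolerance = 1e-12)
  for (sub in c("CCGTTGCA", "ACGTTGCT", "ACGATGCA")) {
    h <- scan_pwm(c(s = sub), p, threshold = -Inf)
    expect_lt(max(h$score[h$strand == "+"]), p$max_score)
  }
  # a threshold above the maximum yields no hits
  none <- scan_pwm(c(s = "ACGTTGCA"), p, threshold = p$max_score + 1)
  expect_identical(nrow(none), 0L)
})

test_that("a planted site is the top hit and matches brute-force scoring", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  cons <- "TTGACGCA"
  p <- consensus_pwm(cons)
  bg <- sample(bases, 1000, replace = TRUE)
  pos0 <- 400L                                  # 0-based planting position
  bg[pos0 + 1:8] <- strsplit(cons, "")[[1]]
  s <- paste(bg, collapse = "")
  hits <- scan_pwm(stats::setNames(s, "ctg"), p, threshold = -Inf)
  top <- hits[which.max(hits$score), ]
  expect_identical(top$start, pos0)
  expect_identical(top$strand, "+")
  # brute-force all-offset oracle, written directly from the definition
  codes <- match(bg, bases)
  brute <- sapply(seq_len(1000 - 8 + 1), function(o)
    sum(p$log_odds[cbind(codes[o:(o + 7)], 1:8)]))
  expect_equal(top$score, max(brute), tolerance = 1e-12)
  expect_identical(top$start, which.max(brute) - 1L)
})

test_that("scanning respects strand symmetry", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  p <- consensus_pwm("GATAAGGC")
  h1 <- scan_pwm(c(x = s), p, threshold = 2)
  h2 <- scan_pwm(c(x = rc), p, threshold = 2)
  expect_identical(nrow(h1), nrow(h2))
  # strand labels swap and the score multiset is preserved exactly
  expect_identical(sum(h1$strand == "+"), sum(h2$strand == "-"))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
  # a planted site mirrors exactly: [a, b) -> [L - b, L - a)
  bg <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  bg[101:108] <- strsplit("GATAAGGC", "")[[1]]
  s3 <- paste(bg, collapse = "")
  rc3 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s3)))
  p1 <- scan_pwm(c(x = s3), p, threshold = p$max_score - 1e-9)
  p2 <- scan_pwm(c(x = rc3), p, threshold = p$max_score - 1e-9)
  expect_identical(p1$start, 100L)
  expect_identical(p1$strand, "+")
  expect_identical(p2$start, 300L - p1$end)
  expect_identical(p2$end, 300L - p1$start)
  expect_identical(p2$strand, "-")
})

test_that("prepending background shifts hit coordinates exactly", {
  set.seed(43)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  p <- consensus_pwm("CCGGTTAA")
  h1 <- scan_pwm(c(x = s), p, threshold = 0)
  prefix <- "ACGTACGTACGT"
  h2 <- scan_pwm(c(x = paste0(prefix, s)), p, threshold = 0)
  h2_in <- h2[h2$start >= nchar(prefix), ]
  expect_equal(h2_in$start - nchar(prefix), h1$start)
  expect_equal(h2_in$score, h1$score, tolerance = 1e-12)
})

test_that("peak-to-gene assignment respects the window boundary exactly", {
  tss <- data.frame(contig = "c1", start = 1000, end = 1001, name = "gA")
  near <- data.frame(contig = "c1", start = 0, end = 900, name = "p_near")
  exact <- data.frame(contig = "c1", start = 0, end = 900 - 1,
                      name = "p_exact")   # edge 101 bp away
  over <- data.frame(contig = "c1", start = 990, end = 1010, name = "p_over")
  m <- assign_peaks_to_genes(rbind(near, over), tss, window_bp = 100)
  expect_setequal(m$peak, c("p_near", "p_over"))
  expect_identical(m$distance[m$peak == "p_over"], 0L)
  expect_identical(m$distance[m$peak == "p_near"], 100L)
  # one base beyond the window: excluded
  m2 <- assign_peaks_to_genes(exact, tss, window_bp = 100)
  expect_identical(nrow(m2), 0L)
  expect_error(assign_peaks_to_genes(
    data.frame(contig = "c1", start = 10, end = 10, name = "bad"),
    tss, 100), "malformed")
})

test_that("base GRN construction deduplicates and maps provenance", {
  peaks <- data.frame(contig = c("c1", "c2"), start = 0, end = 100,
                      name = c("p1", "p2"))
  tss <- data.frame(contig = c("c1", "c1", "c2"),
                    start = c(150, 180, 150), end = c(151, 181, 151),
                    name = c("gA", "gB", "gC"))
  map <- assign_peaks_to_genes(peaks, tss, window_bp = 200)
  hits <- data.frame(motif = "M_TF1", contig = "c1", start = 10, end = 18,
                     strand = "+", score = 12)
  grn <- build_base_grn(hits, peaks, map, c(M_TF1 = "TF1"))
  # one hit in a peak near two genes yields two candidate edges
  expect_identical(nrow(grn), 2L)
  expect_setequal(grn$target, c("gA", "gB"))
  # duplicating the hit changes nothing
  grn2 <- build_base_grn(rbind(hits, hits), peaks, map, c(M_TF1 = "TF1"))
  expect_identical(grn, grn2)
  # unmapped motifs are dropped
  expect_message(
    grn3 <- build_base_grn(
      data.frame(motif = "M_x", contig = "c1", start = 10, end = 18,
                 strand = "+", score = 12),
      peaks, map, c(M_TF1 = "TF1")),
    "without a TF mapping")
  expect_identical(nrow(grn3), 0L)
  # zero hits give an empty base GRN
  empty <- build_base_grn(hits[0, ], peaks, map, c(M_TF1 = "TF1"))
  expect_identical(nrow(empty), 0L)
})

test_that("the synthetic one-contig design maps peaks only to their gene", {
  dat <- tiny_dataset()
  rs <- generate_regulatory_sequences(dat$truth, dat$cfg)
  m <- assign_peaks_to_genes(rs$peaks, rs$tss, window_bp = 3000)
  expect_identical(nrow(m), nrow(rs$peaks))
  expect_identical(m$gene, sub("^peak_", "", m$peak))
})

test_that("motif-derived candidates cover the planted edges", {
  dat <- tiny_dataset()
  rs <- generate_regulatory_sequences(dat$truth, dat$cfg)
  hits <- scan_pwms(rs$sequences, rs$pwms, threshold = 10)
  m <- assign_peaks_to_genes(rs$peaks, rs$tss, window_bp = 3000)
  base <- build_base_grn(hits, rs$peaks, m, rs$motif_to_tf)
  planted <- unique(paste(dat$truth$grn_edges$regulator,
                          dat$truth$grn_edges$target))
  got <- paste(base$regulator, base$target)
  expect_gte(mean(planted %in% got), 0.9)
})

test_that("motif-topic contrast counts reflect the planting design", {
  dat <- tiny_dataset()
  # noise-free regime: long motifs scanned at an exact-match threshold,
  # so chance consensus occurrences in the background are absent
  rs <- generate_regulatory_sequences(dat$truth, dat$cfg, motif_length = 14)
  contrast_pwms <- rs$pwms[c("M_homeo_only", "M_inflam_only", "M_shared")]
  thr <- min(vapply(contrast_pwms, function(p) p$max_score, numeric(1))) - 1e-9
  hits <- scan_pwms(rs$sequences, contrast_pwms, threshold = thr)
  map <- assign_peaks_to_genes(rs$peaks, rs$tss, window_bp = 100000)
  sets <- list(homeostasis = dat$truth$topic_gene_sets$homeostasis,
               inflammation = dat$truth$topic_gene_sets$inflammation)
  ct <- motif_topic_contrast(hits, rs$peaks, map, sets)
  h_only <- ct[ct$motif == "M_homeo_only", ]
  i_only <- ct[ct$motif == "M_inflam_only", ]
  shared <- ct[ct$motif == "M_shared", ]
  expect_identical(h_only$n_inflammation, 0)
  expect_identical(i_only$n_homeostasis, 0)
  expect_gt(h_only$n_homeostasis, 0)
  expect_gt(i_only$n_inflammation, 0)
  # the shared motif has the largest minimum count across the two sets
  min_counts <- pmin(ct$n_homeostasis, ct$n_inflammation)
  expect_identical(ct$motif[which.max(min_counts)], "M_shared")
  # zero-hit motifs simply do not appear
  none <- motif_topic_contrast(hits[0, ], rs$peaks, map, sets)
  expect_identical(nrow(none), 0L)
})
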