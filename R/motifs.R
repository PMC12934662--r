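#' Position-weight matrix from a position-frequency table
#'
#' Frequencies are computed from the counts with a pseudocount per cell
#' and renormalized per position; the log-odds matrix is
#' `log2(freq / background)`.
#'
#' @param counts 4 x L numeric matrix of base counts (rows A, C, G, T).
#' @param id Motif identifier.
#' @param background Length-4 background base composition.
#' @param pseudocount Added to every frequency cell before normalization.
#' @return A list of class `pwm` with `id`, `counts`, `freq`, `log_odds`,
#'   `length`, `background`, `consensus` and `max_score`.
#' @export
pwm <- function(counts, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 4,
            length(background) == 4, all(background > 0))
  bases <- c("A", "C", "G", "T")
  rownames(counts) <- bases
  background <- background / sum(background)
  freq <- sweep(counts, 2, colSums(counts), "/")
  freq <- freq + pseudocount
  freq <- sweep(freq, 2, colSums(freq), "/")
  lo <- log2(freq / background)
  structure(list(id = id, counts = counts, freq = freq, log_odds = lo,
                 length = ncol(counts), background = background,
                 consensus = paste(bases[apply(freq, 2, which.max)],
                                   collapse = ""),
                 max_score = sum(apply(lo, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$id, ": length ", x$length, ", consensus ", x$consensus,
      ", max score ", round(x$max_score, 2), "\n", sep = "")
  invisible(x)
}

#' Estimate background base composition from sequences
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character
#'   vector.
#' @return Length-4 frequency vector (A, C, G, T).
#' @export
background_composition <- function(sequences) {
  seqs <- as_dna_character(sequences)
  tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                      levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab)
  f / sum(f)
}

as_dna_character <- function(sequences) {
  if (is(sequences, "XStringSet")) {
    stats::setNames(as.character(sequences), names(sequences))
  } else {
    stopifnot(is.character(sequences), !is.null(names(sequences)))
    toupper(sequences)
  }
}

#' Scan sequences with a PWM on both strands
#'
#' At every offset on both strands the log-odds score
#' `sum_positions log2(p_base / q_base)` is computed; windows scoring at
#' least `threshold` are reported.  Windows containing ambiguity codes
#' are skipped with a warning.  Overlapping hits on the same strand of
#' the same contig are resolved by keeping the higher-scoring hit
#' (greedy, ties to the earlier offset).  Coordinates are 0-based
#' half-open on the forward strand.
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character
#'   vector of contigs.
#' @param pwm A [pwm()] object.
#' @param threshold Minimum log-odds score (default 10).
#' @return Data.frame with columns `motif`, `contig`, `start`, `end`,
#'   `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = 10) {
  stopifnot(inherits(pwm, "pwm"))
  seqs <- as_dna_character(sequences)
  L <- pwm$length
  lo_fwd <- pwm$log_odds
  lo_rev <- lo_fwd[4:1, L:1]                   # reverse complement scan
  hits <- list()
  ambig_warned <- FALSE
  for (ctg in names(seqs)) {
    s <- strsplit(seqs[[ctg]], "")[[1]]
    code <- match(s, c("A", "C", "G", "T"))
    n <- length(code)
    if (n < L) next
    has_ambig <- anyNA(code)
    if (has_ambig && !ambig_warned) {
      warning("skipping windows containing ambiguity codes")
      ambig_warned <- TRUE
    }
    n_off <- n - L + 1
    sc_f <- numeric(n_off)
    sc_r <- numeric(n_off)
    ok <- rep(TRUE, n_off)
    for (j in seq_len(L)) {
      cj <- code[j:(j + n_off - 1)]
      bad <- is.na(cj)
      if (any(bad)) {
        ok <- ok & !bad
        cj[bad] <- 1L
      }
      sc_f <- sc_f + lo_fwd[cbind(cj, j)]
      sc_r <- sc_r + lo_rev[cbind(cj, j)]
    }
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sc_f else sc_r
      pass <- which(ok & sc >= threshold)
      if (length(pass) == 0) next
      ## greedy overlap resolution: best score first, earlier offset ties
      pass <- pass[order(-sc[pass], pass)]
      kept <- integer(0)
      for (p in pass) {
        if (all(abs(p - kept) >= L)) kept <- c(kept, p)
      }
      kept <- sort(kept)
      hits[[length(hits) + 1]] <- data.frame(
        motif = pwm$id, contig = ctg, start = kept - 1L,
        end = kept - 1L + L, strand = strand, score = sc[kept],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(motif = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Scan sequences with several PWMs
#'
#' @inheritParams scan_pwm
#' @param pwms List of [pwm()] objects.
#' @return Row-bound [scan_pwm()] results.
#' @export
scan_pwms <- function(sequences, pwms, threshold = 10) {
  do.call(rbind, lapply(pwms, function(p)
    scan_pwm(sequences, p, threshold = threshold)))
}

#' Assign peaks to genes by TSS window
#'
#' A peak maps to every gene whose TSS lies within `window_bp` of the
#' peak's closest edge (distance 0 when they overlap); multi-mapping is
#' allowed.  All arithmetic is 0-based half-open.
#'
#' @param peaks Data.frame with `contig`, `start`, `end`, `name`.
#' @param tss Data.frame with `contig`, `start`, `end`, `name` (gene id).
#' @param window_bp Window size in bp (3000 for base-GRN candidate
#'   assignment, 100000 for the topic-contrast analysis).
#' @return Data.frame of class `peak_gene_map` with columns `peak`,
#'   `gene`, `distance`, `window`.
#' @export
assign_peaks_to_genes <- function(peaks, tss, window_bp) {
  check_bed <- function(x, what) {
    bad <- which(x$start >= x$end)
    if (length(bad) > 0)
      stop("malformed ", what, " interval (start >= end) at line ", bad[1],
           call. = FALSE)
  }
  check_bed(peaks, "peak")
  check_bed(tss, "tss")
  gp <- GenomicRanges::GRanges(peaks$contig,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  gt <- GenomicRanges::GRanges(tss$contig,
                               IRanges::IRanges(tss$start + 1, tss$end))
  ov <- GenomicRanges::findOverlaps(gp, gt, maxgap = window_bp)
  d <- GenomicRanges::distance(gp[S4Vectors::queryHits(ov)],
                               gt[S4Vectors::subjectHits(ov)])
  keep <- !is.na(d) & d <= window_bp
  out <- data.frame(peak = peaks$name[S4Vectors::queryHits(ov)[keep]],
                    gene = tss$name[S4Vectors::subjectHits(ov)[keep]],
                    distance = as.integer(d[keep]),
                    window = rep(window_bp, sum(keep)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_gene_map", "data.frame")
  out
}

#' Build a base GRN from motif hits and a peak-to-gene map
#'
#' Each (motif hit inside a peak, peak-to-gene assignment) pair yields a
#' candidate edge (TF, gene), deduplicated with provenance retained.
#' Hits outside every peak, and motifs without a TF mapping, are dropped
#' with a message.
#'
#' @param hits [scan_pwm()]/[scan_pwms()] output.
#' @param peaks Peak intervals (`contig`, `start`, `end`, `name`), used
#'   to place hits into peaks by overlap.
#' @param map An [assign_peaks_to_genes()] result.
#' @param motif_to_tf Named character vector mapping motif id to TF gene
#'   id (`NA` entries are dropped).
#' @return A data.frame of class `base_grn` with columns `regulator`,
#'   `target`, `motif`, `peak`.
#' @export
build_base_grn <- function(hits, peaks, map, motif_to_tf) {
  if (nrow(hits) > 0) {
    gh <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start + 1, hits$end))
    gp <- GenomicRanges::GRanges(peaks$contig,
                                 IRanges::IRanges(peaks$start + 1, peaks$end))
    ov <- GenomicRanges::findOverlaps(gh, gp, type = "within")
    n_out <- nrow(hits) - length(unique(S4Vectors::queryHits(ov)))
    if (n_out > 0)
      message(n_out, " hits fall outside every peak and were dropped")
    hp <- data.frame(motif = hits$motif[S4Vectors::queryHits(ov)],
                     peak = peaks$name[S4Vectors::subjectHits(ov)],
                     stringsAsFactors = FALSE)
  } else {
    hp <- data.frame(motif = character(0), peak = character(0))
  }
  hp$tf <- unname(motif_to_tf[hp$motif])
  n_unmapped <- sum(is.na(hp$tf))
  if (n_unmapped > 0)
    message(n_unmapped, " hits from motifs without a TF mapping were dropped")
  hp <- hp[!is.na(hp$tf), ]
  m <- merge(hp, as.data.frame(map)[, c("peak", "gene")], by = "peak")
  out <- unique(data.frame(regulator = m$tf, target = m$gene,
                           motif = m$motif, peak = m$peak,
                           stringsAsFactors = FALSE))
  out <- out[order(out$regulator, out$target, out$motif), ]
  rownames(out) <- NULL
  class(out) <- c("base_grn", "data.frame")
  out
}

#' Per-motif counts near two topic gene sets
#'
#' For each motif, counts the distinct (hit, gene) assignments whose gene
#' belongs to each of the two topic gene sets (typically homeostasis and
#' inflammation top genes, with a wide TSS window).  Overlap between the
#' two sets is allowed but reported via message.
#'
#' @param hits [scan_pwm()]/[scan_pwms()] output.
#' @param peaks Peak intervals used to place hits into peaks.
#' @param map An [assign_peaks_to_genes()] result (typically at a
#'   100 kb window).
#' @param topic_gene_sets Named list of two gene-id vectors.
#' @return Data.frame with `motif`, one count column per topic set, and
#'   `total`, sorted by descending total.
#' @export
motif_topic_contrast <- function(hits, peaks, map, topic_gene_sets) {
  stopifnot(length(topic_gene_sets) == 2)
  ov <- intersect(topic_gene_sets[[1]], topic_gene_sets[[2]])
  if (length(ov) > 0)
    message("topic gene sets share ", length(ov), " genes")
  if (nrow(hits) > 0) {
    gh <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start + 1, hits$end))
    gp <- GenomicRanges::GRanges(peaks$contig,
                                 IRanges::IRanges(peaks$start + 1, peaks$end))
    ovl <- GenomicRanges::findOverlaps(gh, gp, type = "within")
    hp <- data.frame(hit = S4Vectors::queryHits(ovl),
                     motif = hits$motif[S4Vectors::queryHits(ovl)],
                     peak = peaks$name[S4Vectors::subjectHits(ovl)],
                     stringsAsFactors = FALSE)
    m <- merge(hp, as.data.frame(map)[, c("peak", "gene")], by = "peak")
  } else {
    m <- data.frame(hit = integer(0), motif = character(0),
                    gene = character(0))
  }
  motifs <- sort(unique(hits$motif))
  nm <- names(topic_gene_sets)
  rows <- lapply(motifs, function(mo) {
    mm <- unique(m[m$motif == mo, c("hit", "gene")])
    counts <- vapply(topic_gene_sets, function(gs)
      sum(mm$gene %in% gs), numeric(1))
    out <- data.frame(motif = mo, stringsAsFactors = FALSE)
    out[[paste0("n_", nm[1])]] <- counts[1]
    out[[paste0("n_", nm[2])]] <- counts[2]
    out$total <- sum(counts)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif = character(0))
    out[[paste0("n_", nm[1])]] <- numeric(0)
    out[[paste0("n_", nm[2])]] <- numeric(0)
    out$total <- numeric(0)
  }
  out <- out[order(-out$total, out$motif), ]
  rownames(out) <- NULL
  out
}
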