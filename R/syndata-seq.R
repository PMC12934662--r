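#' Generate synthetic regulatory sequences with planted motif instances
#'
#' Builds one synthetic contig per gene neighborhood: i.i.d. uniform-ACGT
#' background, a recorded TSS, one accessibility peak downstream of the
#' TSS, and every motif the ground-truth ledger plants for that gene
#' embedded (as its exact consensus) inside the peak.  All coordinates are
#' 0-based half-open, BED convention; strand is ignored at generation time
#' (the scanner searches both strands).
#'
#' @param truth A [generate_ground_truth()] result.
#' @param config The matching [synthetic_config()].
#' @param contig_length Length of each per-gene contig (bp).
#' @param peak_width Width of the planted peak (bp).
#' @param peak_offset Distance from the TSS to the peak start (bp); must
#'   keep the peak within the contig.
#' @param motif_length Length of each motif consensus (bp).
#' @return A list of class `regulatory_sequences` with elements
#'   `sequences` (a [Biostrings::DNAStringSet]), `peaks`, `tss`
#'   (data.frames with `contig`, `start`, `end`, `name`), `pwms` (a list of
#'   [pwm()] position-frequency models, one per motif), `motif_to_tf`
#'   (named character; `NA` for topic-contrast motifs), and `planted`
#'   (the realized motif ledger with coordinates).
#' @export
generate_regulatory_sequences <- function(truth, config,
                                          contig_length = 1500,
                                          peak_width = 200,
                                          peak_offset = 120,
                                          motif_length = 8) {
  stopifnot(inherits(truth, "ground_truth"))
  if (peak_width > contig_length)
    stop("peak longer than contig", call. = FALSE)
  set.seed(stage_seed(config$seed, "sequences"))

  bases <- c("A", "C", "G", "T")
  motif_ids <- sort(unique(truth$planted_motifs$motif_id))
  consensus <- vapply(motif_ids, function(m)
    paste(sample(bases, motif_length, replace = TRUE), collapse = ""),
    character(1))

  ## position-frequency matrices: 12 counts for the consensus base, 1 for
  ## each alternative -- a sharp but not degenerate motif
  pwms <- lapply(motif_ids, function(m) {
    cons <- strsplit(consensus[[m]], "")[[1]]
    counts <- matrix(1, 4, motif_length, dimnames = list(bases, NULL))
    counts[cbind(match(cons, bases), seq_len(motif_length))] <- 12
    pwm(counts, id = m)
  })
  names(pwms) <- motif_ids

  tss_pos <- contig_length %/% 3
  peak_start <- tss_pos + peak_offset
  peak_end <- peak_start + peak_width
  if (peak_end > contig_length)
    stop("peak longer than contig", call. = FALSE)

  planted <- truth$planted_motifs
  seqs <- character(length(truth$gene_ids))
  planted$start <- NA_integer_
  planted$end <- NA_integer_
  planted$contig <- paste0("contig_", planted$gene_id)
  for (gi in seq_along(truth$gene_ids)) {
    g <- truth$gene_ids[gi]
    s <- sample(bases, contig_length, replace = TRUE)
    rows <- which(planted$gene_id == g)
    if (length(rows) > 0) {
      slots <- peak_start + 4 + (seq_along(rows) - 1) * (motif_length + 3)
      if (any(slots + motif_length > peak_end))
        stop("too many motifs planted in the peak of gene ", g, call. = FALSE)
      for (j in seq_along(rows)) {
        cons <- strsplit(consensus[[planted$motif_id[rows[j]]]], "")[[1]]
        s[slots[j] + seq_len(motif_length)] <- cons  # 0-based start slots[j]
        planted$start[rows[j]] <- slots[j]
        planted$end[rows[j]] <- slots[j] + motif_length
      }
    }
    seqs[gi] <- paste(s, collapse = "")
  }
  contigs <- paste0("contig_", truth$gene_ids)
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, contigs))

  peaks <- data.frame(contig = contigs, start = peak_start, end = peak_end,
                      name = paste0("peak_", truth$gene_ids),
                      stringsAsFactors = FALSE)
  tss <- data.frame(contig = contigs, start = tss_pos, end = tss_pos + 1,
                    name = truth$gene_ids, stringsAsFactors = FALSE)

  motif_to_tf <- stats::setNames(sub("^M_", "", motif_ids), motif_ids)
  motif_to_tf[!motif_to_tf %in% truth$tf_ids] <- NA_character_

  structure(list(sequences = sequences, peaks = peaks, tss = tss,
                 pwms = pwms, motif_to_tf = motif_to_tf,
                 consensus = consensus, planted = planted),
            class = "regulatory_sequences")
}
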