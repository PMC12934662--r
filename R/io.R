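#' Write a count matrix as a 10x-style MTX bundle
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv`, `barcodes.tsv` and
#' `cell_meta.tsv` into `dir`.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(cbind(cell_id = x$cell_ids, x$cell_meta),
              file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from a 10x-style MTX bundle
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `cell_meta.tsv`.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    mm <- read.delim(meta_path, stringsAsFactors = FALSE)
    rownames(mm) <- mm$cell_id
    mm[cells, setdiff(colnames(mm), "cell_id"), drop = FALSE]
  } else {
    data.frame(row.names = cells)
  }
  count_matrix(m, genes, cells, meta)
}

#' Write BED intervals (0-based half-open)
#'
#' @param x Data.frame with columns `contig`, `start`, `end` and optional
#'   `name`, `score`, `strand`.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    colnames(x))
  write.table(x[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals (0-based half-open)
#'
#' @param path BED file (3-6 columns).
#' @return Data.frame with `contig`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.  Malformed intervals raise an error naming
#'   the offending line.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  nm <- c("contig", "start", "end", "name", "score", "strand")
  colnames(x) <- nm[seq_len(ncol(x))]
  bad <- which(x$start >= x$end)
  if (length(bad) > 0)
    stop("malformed interval (start >= end) at line ", bad[1], call. = FALSE)
  x
}

#' Write position-frequency matrices as a 4-row TSV per motif
#'
#' Each motif block is `>motif_id` followed by four tab-separated rows
#' (A, C, G, T counts per position), JASPAR-like.
#'
#' @param pwms A list of [pwm()] objects.
#' @param path Output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in seq_len(4))
      writeLines(paste(p$counts[b, ], collapse = "\t"), con)
  }
  invisible(path)
}

#' Read position-frequency matrices written by [write_pwms()]
#'
#' @param path Input file.
#' @inheritParams pwm
#' @return A named list of [pwm()] objects.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  out <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>", "", lines[starts[i]])
    rows <- lines[starts[i] + 1:4]
    counts <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\t")[[1]])))
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(counts, id = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>genes...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, character(1), 1))
}

#' Write the ground-truth ledger as plain-text files
#'
#' Writes the planted truth (topic gene distributions, per-cell topic
#' proportions, edge list, decoys, marker genes, planted motifs) as TSV
#' plus a JSON index, so downstream evaluation never needs the R object.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param dir Output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(cbind(gene_id = rownames(truth$topic_gene_dists),
           as.data.frame(truth$topic_gene_dists)), "topic_gene_dists.tsv")
  wt(cbind(cell_id = rownames(truth$cell_topic_props),
           as.data.frame(truth$cell_topic_props), truth$cell_meta),
     "cell_topic_props.tsv")
  wt(truth$grn_edges, "grn_edges.tsv")
  if (!is.null(truth$decoy_edges)) wt(truth$decoy_edges, "decoy_edges.tsv")
  wt(truth$planted_motifs, "planted_motifs.tsv")
  jsonlite::write_json(list(master_tf = truth$master_tf,
                            tf_ids = truth$tf_ids,
                            marker_genes = truth$marker_genes,
                            topic_gene_sets = truth$topic_gene_sets),
                       file.path(dir, "truth_index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write generated regulatory sequences as FASTA + BED + PWM TSV
#'
#' Writes `contigs.fa`, `peaks.bed`, `tss.bed`, `pwms.tsv` and the
#' realized planting ledger `planted_motifs.tsv` into `dir`.
#'
#' @param rs A [generate_regulatory_sequences()] result.
#' @param dir Output directory.
#' @export
write_regulatory_sequences <- function(rs, dir) {
  stopifnot(inherits(rs, "regulatory_sequences"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(rs$sequences, file.path(dir, "contigs.fa"))
  write_bed(rs$peaks, file.path(dir, "peaks.bed"))
  write_bed(rs$tss, file.path(dir, "tss.bed"))
  write_pwms(rs$pwms, file.path(dir, "pwms.tsv"))
  write.table(rs$planted, file.path(dir, "planted_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an inferred GRN edge table as TSV
#'
#' @param grn An [fit_grn()] result.
#' @param path Output file.
#' @export
write_grn <- function(grn, path) {
  stopifnot(inherits(grn, "inferred_grn"))
  write.table(cbind(context = grn$context, grn$edges), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6 (name = motif id, score = log-odds)
#'
#' @param hits A [scan_pwm()]/[scan_pwms()] hit table.
#' @param path Output file.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(contig = hits$contig, start = hits$start,
                    end = hits$end, name = hits$motif,
                    score = hits$score, strand = hits$strand)
  write_bed(bed, path)
}

#' Export a topic gradient field as JSON
#'
#' Grid coordinates, smoothed values, gradient components and the
#' occupancy mask, in a quiver-plot-ready layout.
#'
#' @param grad A [topic_gradient()] result.
#' @param path Output file.
#' @export
export_gradient_json <- function(grad, path) {
  stopifnot(inherits(grad, "topic_gradient"))
  jsonlite::write_json(list(topic = grad$topic, xs = grad$xs, ys = grad$ys,
                            value = grad$value, gx = grad$gx, gy = grad$gy,
                            mask = grad$mask),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
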