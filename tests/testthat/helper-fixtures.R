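# Small generator configurations used across the unit tests.  Sizes are
# deliberately tiny; the acceptance tests use larger, study-scale settings.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells_per_population = 120, n_genes = 120, n_tfs = 12,
         library_size_mean = 800, n_targets_per_tf = 3,
         n_decoys_per_tf = 3, seed = 101),
    list(...))
  do.call(synthetic_config, args)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells_per_population = 400, n_genes = 200, n_tfs = 20,
         library_size_mean = 1200, seed = 202),
    list(...))
  do.call(synthetic_config, args)
}

tiny_dataset <- function(cfg = tiny_config()) {
  truth <- generate_ground_truth(cfg)
  counts <- simulate_counts(truth, cfg)
  list(cfg = cfg, truth = truth, counts = counts)
}

# deterministic toy count matrix: two disjoint gene blocks expressed in two
# disjoint cell groups
block_counts <- function() {
  x <- rbind(c(9, 7, 8, 0, 0, 0, 0, 0),
             c(6, 9, 7, 0, 0, 0, 0, 0),
             c(8, 6, 9, 1, 0, 0, 0, 0),
             c(0, 0, 0, 9, 8, 7, 9, 6),
             c(0, 0, 1, 6, 9, 8, 7, 9),
             c(0, 0, 0, 8, 7, 9, 6, 8))
  count_matrix(x, paste0("g", 1:6), paste0("c", 1:8),
               data.frame(population = rep(c("A", "B"), each = 4),
                          timepoint = 0))
}
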