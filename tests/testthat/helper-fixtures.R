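# Small-scale configurations used across tests (fast variants of the default
# study conditions; the acceptance tests use the full-scale defaults).

tiny_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    n_cells_per_type = c(basal = 20L, L1 = 20L, L2 = 20L, IM = 20L),
    n_peaks = 400L, n_genes = 80L,
    program_peaks_per_type = 20L), list(...))
  do.call(sim_config, args)
}

# motif table with every amplification switched off (the null condition)
null_motif_specs <- function() {
  specs <- default_motif_specs()
  specs$amplification <- rep(1, nrow(specs))
  specs$target_type <- rep(NA_character_, nrow(specs))
  specs
}

# peaks-x-B identity background map wrapped as a valid background_sets object
identity_backgrounds <- function(n_peaks, B = 5L) {
  structure(list(map = matrix(rep(seq_len(n_peaks), B), n_peaks, B),
                 neighbors = matrix(seq_len(n_peaks), n_peaks, 1L),
                 k = 1L, B = B, seed = 0L),
            class = "background_sets")
}

# per-iteration random permutation background (measure-preserving maps)
permutation_backgrounds <- function(n_peaks, B = 5L, seed = 1L) {
  set.seed(seed)
  map <- vapply(seq_len(B), function(b) sample.int(n_peaks),
                integer(n_peaks))
  structure(list(map = map, neighbors = NULL, k = n_peaks, B = B,
                 seed = seed),
            class = "background_sets")
}

random_count_matrix <- function(n_peaks, n_cells, seed = 1L, lambda = 2) {
  set.seed(seed)
  X <- matrix(rpois(n_peaks * n_cells, lambda), n_peaks, n_cells,
              dimnames = list(sprintf("p%03d", seq_len(n_peaks)),
                              sprintf("c%03d", seq_len(n_cells))))
  X
}
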