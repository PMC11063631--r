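## End-to-end convenience wrapper: raw session -> binned -> embedded ->
## clustered -> trial matrix.

#' Run the full manifold pipeline on one session
#'
#' Preprocesses (outlier exclusion, binning, z-scoring), embeds with the
#' two-round Laplacian-eigenmaps reduction, optimizes the clustering
#' configuration, derives deterministic consensus labels, and builds the
#' trial cluster-sequence matrix.
#'
#' @param session a `pm_session`.
#' @param dims,k_frac passed to [two_round_reduce()].
#' @param k_grid,grid_reps passed to [optimize_config()].
#' @param consensus_reps passed to [consensus_labels()].
#' @param seed master RNG seed for the stochastic stages.
#' @param per_run_zscore passed to [preprocess_session()].
#' @return list with `binned`, `embedding`, `config`, `clustering`,
#'   `trial_matrix`.
#' @export
run_pipeline <- function(session, dims = c(20L, 6L),
                         k_frac = c(0.075, 0.025), k_grid = 2:20,
                         grid_reps = 20L, consensus_reps = 500L, seed = 1L,
                         per_run_zscore = FALSE) {
  bs <- preprocess_session(session, per_run_zscore = per_run_zscore)
  emb <- two_round_reduce(bs$z, dims = dims, k_frac = k_frac)
  cfg <- optimize_config(emb, k_grid = k_grid, reps = grid_reps, seed = seed)
  clus <- consensus_labels(emb, cfg, reps = consensus_reps, seed = seed)
  tm <- build_trial_matrix(clus, bs$trials)
  list(binned = bs, embedding = emb, config = cfg, clustering = clus,
       trial_matrix = tm)
}
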