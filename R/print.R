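## Compact print methods for the main result objects.

#' @export
print.pm_dim <- function(x, ...) {
  cat(sprintf("Intrinsic dimension estimate: %.3f (n_used = %d)\n",
              x$d_hat, x$n_used))
  invisible(x)
}

#' @export
print.pm_dim_profile <- function(x, ...) {
  cat(sprintf("Intrinsic dimension (plateau): %.3f\n", x$d_hat))
  print(x$profile)
  invisible(x)
}

#' @export
print.pm_embedding <- function(x, ...) {
  cat(sprintf("Manifold embedding: %d bins x %d dims (rounds: %s)\n",
              nrow(x$coords), ncol(x$coords),
              paste(vapply(x$stage_params, function(s)
                sprintf("K=%d->%dd", s$K, s$out_dim), ""), collapse = ", ")))
  invisible(x)
}

#' @export
print.pm_cluster_config <- function(x, ...) {
  cat(sprintf("Clustering configuration: K* = %d, central cloud = %d bins\n",
              x$optimum$K, x$optimum$n_excluded))
  invisible(x)
}

#' @export
print.pm_clustering <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1L, seq_len(x$K_star))))
  cat(sprintf("Manifold clustering: %d clusters + central cloud (%d bins)\n",
              x$K_star, x$n_excluded))
  print(tab)
  invisible(x)
}

#' @export
print.pm_decoding <- function(x, ...) {
  cat(sprintf("Cross-dataset decoding (overall accuracy %.3f, p = %.3f):\n",
              x$overall, x$p_overall))
  print(data.frame(accuracy = round(x$accuracy, 3), p = round(x$p, 3)))
  invisible(x)
}

#' @export
print.pm_topo_comparison <- function(x, ...) {
  cat(sprintf(
    "Topological comparison: mean Wasserstein %.4f, p = %.3f (%d perms)\n",
    x$distance, x$p_value, x$n_perm))
  cat("(low p: lifespan distributions are unusually similar)\n")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic session config: %d neurons, %d trials/class, noise %.2f z, seed %d\n",
    x$n_neurons, x$n_trials_per_class, x$noise_sd, x$seed))
  invisible(x)
}
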