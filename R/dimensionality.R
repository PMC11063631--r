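## Intrinsic-dimension estimation from two-nearest-neighbor distance ratios.

#' Estimate intrinsic dimensionality from nearest-neighbor ratios
#'
#' For every point the ratio \eqn{\mu = r_2 / r_1} of second-nearest to
#' nearest Euclidean neighbor distance is computed. On a d-dimensional
#' manifold sampled densely enough, \eqn{\mu} follows a Pareto law with
#' shape d, so d is recovered as the slope of \eqn{-\log(1 - F(\mu))}
#' against \eqn{\log \mu} (regression through the origin), where F is the
#' empirical percentile (rank / (n + 1)). The top `discard_top_frac` of
#' ratio values is excluded before the fit to guard against boundary and
#' noise effects.
#'
#' @param points T x D point matrix (rows = observations).
#' @param discard_top_frac fraction of the largest ratios discarded
#'   (default 0.04).
#' @return a `pm_dim` object: `d_hat`, per-point `mu`, percentile `F`,
#'   `n_used`, and the regression sums in `fit`.
#' @export
estimate_dimension <- function(points, discard_top_frac = 0.04) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 50) stop("need at least 50 points")
  nn <- .knn_brute(points, 2L)
  r1 <- nn$dist[, 1]; r2 <- nn$dist[, 2]
  if (any(r1 == 0))
    stop("duplicate points (zero nearest-neighbor distance): ",
         paste(head(which(r1 == 0), 10L), collapse = ", "))
  mu <- r2 / r1
  Fq <- rank(mu, ties.method = "first") / (n + 1)
  keep <- order(mu)[seq_len(n - floor(discard_top_frac * n))]
  x <- log(mu[keep]); y <- -log(1 - Fq[keep])
  d_hat <- sum(x * y) / sum(x * x)
  structure(list(d_hat = d_hat, mu = mu, F = Fq, n_used = length(keep),
                 fit = list(sxy = sum(x * y), sxx = sum(x * x))),
            class = "pm_dim")
}

#' Iterative dimension estimation with spectral denoising
#'
#' Estimates the intrinsic dimension of a binned activity matrix directly
#' and after Laplacian-eigenmaps reduction to each dimension in
#' `intermediate_dims`. Because the estimate is invariant to the embedding
#' dimension, successive reductions should agree once noise has been
#' stripped; the reported estimate is taken at the plateau — the smallest
#' intermediate dimension whose estimate lies within 1 of the preceding
#' stage (falling back to the last stage if none qualifies).
#'
#' @param z neuron x bin matrix (time bins are the points).
#' @param intermediate_dims descending reduction dimensions, all below the
#'   neuron count.
#' @param k_frac kNN-graph neighbor fraction used for the reductions.
#' @param discard_top_frac passed to [estimate_dimension()].
#' @return a `pm_dim_profile` object: `d_hat` (plateau estimate),
#'   `plateau_dim`, and `profile` (data.frame of stage estimates, with the
#'   raw-data stage tagged `dim = NA`).
#' @export
estimate_dimension_iterative <- function(z, intermediate_dims = c(20L, 10L, 6L),
                                         k_frac = 0.075,
                                         discard_top_frac = 0.04) {
  dims <- as.integer(intermediate_dims)
  if (is.unsorted(rev(dims), strictly = TRUE))
    stop("intermediate_dims must be strictly descending")
  if (any(dims >= nrow(z))) stop("intermediate dims must be < n_neurons")
  pts <- t(z)
  Tt <- nrow(pts)
  K <- max(2L, round(k_frac * Tt))
  est <- numeric(length(dims) + 1L)
  est[1] <- estimate_dimension(pts, discard_top_frac)$d_hat
  ## eigenmaps at the different output dims share the same graph, so the
  ## lower-dimensional reductions are truncations of the largest one
  red <- laplacian_eigenmaps(pts, K, max(dims))
  for (i in seq_along(dims)) {
    ri <- red[, seq_len(dims[i]), drop = FALSE]
    ## bins with identical graph neighborhoods can land on identical
    ## coordinates; the ratio is undefined there, so drop exact duplicates
    ri <- ri[!duplicated(ri), , drop = FALSE]
    est[i + 1L] <- estimate_dimension(ri, discard_top_frac)$d_hat
  }
  plateau <- length(est)
  for (i in 2:length(est)) {
    if (abs(est[i] - est[i - 1L]) <= 1) { plateau <- i; break }
  }
  structure(list(d_hat = est[plateau],
                 plateau_dim = if (plateau == 1L) NA_integer_ else
                   dims[plateau - 1L],
                 profile = data.frame(dim = c(NA_integer_, dims),
                                      d_hat = est)),
            class = "pm_dim_profile")
}

#' Neuron-subsampling control for dimension estimates
#'
#' Repeatedly subsamples each session's neurons to a common count and
#' re-estimates the dimension, verifying that estimates are not driven by
#' neuron number.
#'
#' @param zs list of neuron x bin matrices.
#' @param n_target neurons per subsample (>= 3, at most the smallest
#'   session).
#' @param reps subsample repetitions per session.
#' @param seed RNG seed.
#' @return data.frame with one row per session: `mean`, `sd`, and a list
#'   column `estimates`.
#' @export
subsample_control <- function(zs, n_target, reps = 10L, seed = 1L) {
  if (n_target < 3L) stop("n_target must be >= 3")
  if (n_target > min(vapply(zs, nrow, 1L)))
    stop("n_target exceeds the smallest session's neuron count")
  res <- lapply(seq_along(zs), function(s) {
    ests <- vapply(seq_len(reps), function(r) {
      idx <- with_seed(derive_seed(seed, s * 1000L + r),
                       sample(nrow(zs[[s]]), n_target))
      estimate_dimension(t(zs[[s]][idx, , drop = FALSE]))$d_hat
    }, numeric(1))
    ests
  })
  out <- data.frame(session = seq_along(zs),
                    mean = vapply(res, mean, numeric(1)),
                    sd = vapply(res, sd, numeric(1)))
  out$estimates <- res
  out
}
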