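## Manifold clustering: central-point-cloud exclusion, (n_excluded, K) grid
## optimization, and deterministic consensus labels.

#' Order time bins by distance to the embedding centroid
#'
#' Ascending Euclidean distance to the coordinate centroid; ties broken by
#' bin index. The prefix of this order is the central point cloud.
#'
#' @param coords T x m embedding coordinates (or a `pm_embedding`).
#' @return integer permutation of `1:T`.
#' @export
central_cloud_order <- function(coords) {
  if (inherits(coords, "pm_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty embedding")
  ctr <- colMeans(coords)
  d2 <- rowSums(sweep(coords, 2L, ctr)^2)
  order(d2, seq_len(nrow(coords)))
}

#' Default geometric exclusion grid
#'
#' Central-cloud candidate sizes: a geometric progression from 40 up to
#' half the time points, in 12 steps.
#'
#' @param n_bins number of time bins T.
#' @param from,steps grid start and length.
#' @return increasing integer vector.
#' @export
exclusion_grid <- function(n_bins, from = 40L, steps = 12L) {
  to <- max(from + 1L, n_bins %/% 2L)
  unique(round(exp(seq(log(from), log(to), length.out = steps))))
}

#' Optimize the (central-cloud size, K) clustering configuration
#'
#' For every grid cell, runs `reps` K-means repetitions on the bins outside
#' the candidate central cloud and records the mean squared distance of
#' points to their centroids (MSE). Both grid axes and the MSE are scaled
#' to [0, 1]; the optimum is the valid cell closest to the origin of the
#' resulting 3-D system (small cloud, few clusters, low error).
#'
#' @param coords embedding coordinates (or `pm_embedding`).
#' @param excluded_grid candidate central-cloud sizes; default
#'   [exclusion_grid()].
#' @param k_grid K-means K values (default 2:20).
#' @param reps K-means repetitions per cell.
#' @param seed master RNG seed.
#' @return a `pm_cluster_config`: `optimum` (`n_excluded`, `K`),
#'   `mse_grid`, `scaled_distance`, grids, `reps`, `seed`.
#' @export
optimize_config <- function(coords, excluded_grid = NULL, k_grid = 2:20,
                            reps = 20L, seed = 1L) {
  if (inherits(coords, "pm_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  Tt <- nrow(coords)
  if (is.null(excluded_grid)) excluded_grid <- exclusion_grid(Tt)
  excluded_grid <- sort(unique(as.integer(excluded_grid)))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (!length(excluded_grid) || !length(k_grid)) stop("empty grid")
  if (max(excluded_grid) >= Tt) stop("cannot exclude all time points")
  ord <- central_cloud_order(coords)
  mse <- matrix(NA_real_, length(excluded_grid), length(k_grid),
                dimnames = list(excluded_grid, k_grid))
  for (e in seq_along(excluded_grid)) {
    pts <- coords[-ord[seq_len(excluded_grid[e])], , drop = FALSE]
    n_distinct <- nrow(unique(pts))
    for (k in seq_along(k_grid)) {
      K <- k_grid[k]
      if (nrow(pts) <= K) next   # invalid cell
      if (n_distinct == 1L) {    # degenerate: zero error at any K
        mse[e, k] <- 0
        next
      }
      if (n_distinct < K) next   # cannot form K distinct clusters
      v <- vapply(seq_len(reps), function(r) {
        km <- tryCatch(
          with_seed(derive_seed(seed, e * 100000L + k * 1000L + r),
                    kmeans(pts, centers = K, iter.max = 50L)),
          error = function(err) NULL)
        if (is.null(km)) NA_real_ else km$tot.withinss / nrow(pts)
      }, numeric(1))
      if (any(is.finite(v))) mse[e, k] <- mean(v, na.rm = TRUE)
    }
  }
  valid <- is.finite(mse)
  if (!any(valid)) stop("no valid grid cell")
  sx <- scale01(excluded_grid); sy <- scale01(k_grid)
  sz <- mse
  sz[valid] <- scale01(mse[valid])
  d <- sqrt(outer(sx^2, sy^2, "+") + sz^2)
  d[!valid] <- Inf
  ## deterministic tie rule: smallest scaled coordinates first
  best <- which(d == min(d), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(optimum = list(n_excluded = excluded_grid[best[1]],
                                K = k_grid[best[2]]),
                 mse_grid = mse, scaled_distance = d,
                 excluded_grid = excluded_grid, k_grid = k_grid,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "pm_cluster_config")
}

#' Deterministic consensus cluster labels
#'
#' Removes the optimal central point cloud, runs 500 seeded K-means
#' repetitions at the optimal K on the remaining bins, and reduces the
#' 500 x T' label matrix to one deterministic partition by hierarchically
#' clustering the bins on their co-association (fraction of repetitions
#' sharing a label — invariant to each repetition's arbitrary label
#' permutation) and cutting at K*. Central-cloud bins get the sentinel
#' label -1; clusters are numbered 1..K* by first appearance in time.
#'
#' @param coords embedding coordinates (or `pm_embedding`).
#' @param config a `pm_cluster_config` from [optimize_config()].
#' @param reps consensus K-means repetitions (default 500).
#' @param seed master RNG seed.
#' @param linkage hierarchical linkage: `"ward"` (ward.D2, default) or
#'   `"complete"`.
#' @param keep_rep_matrix retain the reps x T' label matrix.
#' @return a `pm_clustering`: `labels` (length T, values -1 or 1..K*),
#'   `K_star`, `n_excluded`, `central_idx`, optionally `rep_matrix`.
#' @export
consensus_labels <- function(coords, config, reps = 500L, seed = 1L,
                             linkage = c("ward", "complete"),
                             keep_rep_matrix = FALSE) {
  linkage <- match.arg(linkage)
  if (inherits(coords, "pm_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(inherits(config, "pm_cluster_config"))
  n_exc <- config$optimum$n_excluded
  K <- config$optimum$K
  ord <- central_cloud_order(coords)
  central <- ord[seq_len(n_exc)]
  keep <- setdiff(seq_len(nrow(coords)), central)
  pts <- coords[keep, , drop = FALSE]
  rep_mat <- matrix(0L, reps, nrow(pts))
  for (r in seq_len(reps)) {
    rep_mat[r, ] <- with_seed(derive_seed(seed, 555000L + r),
                              kmeans(pts, centers = K,
                                     iter.max = 50L)$cluster)
  }
  co <- .coassoc_matrix(rep_mat)
  hc <- hclust(as.dist(1 - co),
               method = if (linkage == "ward") "ward.D2" else "complete")
  grp <- cutree(hc, k = K)
  ## stable numbering: clusters 1..K* in order of first appearance
  remap <- integer(K)
  remap[unique(grp)] <- seq_len(K)
  grp <- remap[grp]
  labels <- integer(nrow(coords))
  labels[central] <- -1L
  labels[keep] <- grp
  structure(list(labels = labels, K_star = K, n_excluded = n_exc,
                 central_idx = central,
                 rep_matrix = if (keep_rep_matrix) rep_mat else NULL),
            class = "pm_clustering")
}
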