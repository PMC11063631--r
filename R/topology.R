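## Topological shape of the embedded manifold: Vietoris-Rips persistence on
## K-means-condensed landmarks, compared by 1-D Wasserstein distance on
## lifespan distributions with a permutation test.

#' Condense an embedding to K-means landmark sets
#'
#' Rips persistence on every time bin is infeasible, so the embedded points
#' are condensed to the centroids of K-means clustering (K = 80). Because
#' K-means is stochastic, the condensation is repeated (20 times by
#' default) with per-repetition seeds derived from `seed`.
#'
#' @param coords T x m embedding coordinates (or a `pm_embedding`).
#' @param k landmark count (must be < T).
#' @param reps number of K-means repetitions.
#' @param seed master RNG seed.
#' @return list of `reps` landmark matrices (k x m).
#' @export
condense_landmarks <- function(coords, k = 80L, reps = 20L, seed = 1L) {
  if (inherits(coords, "pm_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) <= k) stop("need more points than landmarks")
  lapply(seq_len(reps), function(r) {
    with_seed(derive_seed(seed, r),
              kmeans(coords, centers = k, iter.max = 100L)$centers)
  })
}

#' Rips persistence lifespans in degrees 0 and 1
#'
#' Computes Vietoris-Rips persistent homology of a point set and returns
#' the lifespan (death minus birth radius) of every finite feature:
#' connected components (degree 0, born at radius 0) and holes (degree 1).
#' The single never-dying component is excluded — it exists for every point
#' set and carries no comparative information.
#'
#' @param points landmark matrix (>= 3 points, pairwise distinct).
#' @return list with numeric vectors `h0` and `h1` (lifespans) and matrix
#'   `h1_diagram` (birth, death).
#' @export
compute_lifespans <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  D <- as.matrix(dist(points))
  if (any(D[upper.tri(D)] == 0)) stop("degenerate input: duplicate points")
  ph <- .rips_ph01(D)
  list(h0 = ph$h0_deaths,
       h1 = ph$h1_death - ph$h1_birth,
       h1_diagram = cbind(birth = ph$h1_birth, death = ph$h1_death))
}

#' Lifespan distributions over landmark repetitions
#'
#' @param landmarks list of landmark matrices from [condense_landmarks()].
#' @return a `pm_lifespans` object: per-degree lists of per-repetition
#'   lifespan vectors.
#' @export
lifespan_distributions <- function(landmarks) {
  per <- lapply(landmarks, compute_lifespans)
  structure(list(h0 = lapply(per, `[[`, "h0"),
                 h1 = lapply(per, `[[`, "h1"),
                 landmark_k = nrow(landmarks[[1]])),
            class = "pm_lifespans")
}

#' Topological similarity: mean Wasserstein distance between lifespans
#'
#' The distance between two datasets' lifespan distributions for one
#' homology degree, averaged over all pairings of their clustering
#' repetitions (20 x 20 by default).
#'
#' @param a,b `pm_lifespans` objects.
#' @param degree 0 (components) or 1 (holes).
#' @return non-negative scalar.
#' @export
wasserstein_similarity <- function(a, b, degree = 0L) {
  la <- lifespan_reps(a, degree); lb <- lifespan_reps(b, degree)
  if (!all(lengths(la)) || !all(lengths(lb)))
    stop("empty lifespan distribution for degree ", degree)
  mean(vapply(la, function(x)
    vapply(lb, function(y) wasserstein1d(x, y), numeric(1)),
    numeric(length(lb))))
}

lifespan_reps <- function(x, degree) {
  stopifnot(inherits(x, "pm_lifespans"), degree %in% c(0L, 1L))
  if (degree == 0L) x$h0 else x$h1
}

#' Permutation test for topological similarity
#'
#' For each clustering repetition, the two lifespan samples are pooled and
#' re-split at their original sizes `n_perm` times; the repetition's p-value
#' is the fraction of permuted Wasserstein distances strictly below the
#' observed one, and the reported p averages over repetitions. Note the
#' direction: a LOW p says the observed distance is unusually small, i.e.
#' it is evidence of topological similarity.
#'
#' @param a,b `pm_lifespans` objects with equally many repetitions.
#' @param degree homology degree (0 or 1).
#' @param n_perm permutations per repetition (default 200).
#' @param seed RNG seed.
#' @return a `pm_topo_comparison`: `distance` (mean over paired reps),
#'   `p_value`, `p_per_rep`, `n_perm`.
#' @export
permutation_test <- function(a, b, degree = 0L, n_perm = 200L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  la <- lifespan_reps(a, degree); lb <- lifespan_reps(b, degree)
  stopifnot(length(la) == length(lb))
  p_rep <- numeric(length(la))
  d_rep <- numeric(length(la))
  for (r in seq_along(la)) {
    x <- la[[r]]; y <- lb[[r]]
    pool <- c(x, y)
    if (length(pool) < 4L) stop("need >= 4 pooled lifespans")
    d_obs <- wasserstein1d(x, y)
    d_rep[r] <- d_obs
    perm <- with_seed(derive_seed(seed, r), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pool), length(x))
        wasserstein1d(pool[idx], pool[-idx])
      }, numeric(1))
    })
    p_rep[r] <- mean(perm < d_obs)
  }
  structure(list(distance = mean(d_rep), p_value = mean(p_rep),
                 p_per_rep = p_rep, n_perm = as.integer(n_perm)),
            class = "pm_topo_comparison")
}
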