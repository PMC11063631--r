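## Shared fixtures, built in code at test time.

## Small go/no-go session (fast to generate).
small_session <- function(seed = 1L, n_per_class = 6L, n_neurons = 40L,
                          free = TRUE, ...) {
  sim_config(n_neurons = n_neurons, n_trials_per_class = n_per_class,
             free_epoch = if (free)
               list(enabled = TRUE, n_bins = 150, bout_rate_hz = 6.5,
                    bout_len_s = c(2, 5), gap_s = c(2, 8)) else
                 list(enabled = FALSE),
             seed = seed, ...)
}

## Ground-truth per-bin labels in clustering convention (-1 = central).
gt_labels <- function(gt) {
  ifelse(gt$state_sequence == 0L, -1L, gt$state_sequence)
}

## Linear-latent population matrix: N neurons driven by a d-dimensional
## iid latent, plus isotropic noise.
latent_matrix <- function(d, n_neurons, n_bins, noise_sd, seed) {
  set.seed(seed)
  W <- matrix(rnorm(n_neurons * d), n_neurons, d)
  W %*% matrix(rnorm(d * n_bins), d, n_bins) +
    matrix(rnorm(n_neurons * n_bins, 0, noise_sd), n_neurons, n_bins)
}

## Mean silhouette width of labeled points (Euclidean), computed directly.
mean_silhouette <- function(points, labels) {
  D <- as.matrix(dist(points))
  levs <- unique(labels)
  s <- vapply(seq_along(labels), function(i) {
    a <- mean(D[i, labels == labels[i] & seq_along(labels) != i])
    b <- min(vapply(setdiff(levs, labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

## Plug-in mutual information by direct double summation (oracle).
mi_brute <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    pij <- tab[i, j] / n
    out <- out + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  out
}

## Adjusted Rand index between two labelings (via mclust if present).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
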