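## Internal helpers shared across modules.

## Derive a reproducible 32-bit sub-seed from a master seed and a salt.
## Keeps every derived seed in [0, 2^31 - 2] so set.seed() is safe.
derive_seed <- function(seed, salt) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + (salt %% m)) %% m)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

scale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Exact 1-D Wasserstein (earth mover's) distance between samples
#'
#' Computes the order-1 Wasserstein distance between the empirical
#' distributions of two numeric samples, as the integral of the absolute
#' difference of their empirical CDFs. For equal-size samples this reduces
#' to the mean absolute difference of the sorted values.
#'
#' @param a,b numeric vectors (need not be the same length).
#' @return a non-negative scalar.
#' @examples
#' wasserstein1d(c(1, 2, 3), c(2, 3, 4)) # 1
#' @export
wasserstein1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  a <- sort(a); b <- sort(b)
  if (length(a) == length(b)) return(mean(abs(a - b)))
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1L) return(0)
  ## CDF difference is piecewise constant between consecutive grid values
  Fa <- findInterval(grid, a) / length(a)
  Fb <- findInterval(grid, b) / length(b)
  ng <- length(grid)
  sum(abs(Fa[-ng] - Fb[-ng]) * diff(grid))
}
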