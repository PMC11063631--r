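## Two-round Laplacian-eigenmaps reduction of binned population activity.

#' Mutual k-nearest-neighbor adjacency
#'
#' Binary adjacency of the mutual kNN graph: points i and j are connected
#' iff each falls within the K nearest neighbors of the other. Neighbor
#' ties are broken by point index.
#'
#' @param points T x D matrix.
#' @param K neighbor count, `1 <= K < T`.
#' @return sparse symmetric 0/1 Matrix with zero diagonal.
#' @export
knn_adjacency <- function(points, K) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (K < 1 || K >= n) stop("K must be in [1, T - 1]")
  idx <- .knn_brute(points, as.integer(K))$idx
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), K), j = as.vector(idx),
                            x = 1, dims = c(n, n))
  W <- A * Matrix::t(A)          # mutual: both directions present
  W@x[] <- 1
  W
}

## Add MST edges of the Euclidean distance matrix between components of W.
## Returns list(W, n_added).
repair_connectivity <- function(W, points) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no == 1L) return(list(W = W, n_added = 0L, components = comp$no))
  tr <- vegan::spantree(dist(points))
  from <- 2:nrow(points); to <- tr$kid
  add <- comp$membership[from] != comp$membership[to]
  if (any(add)) {
    W <- W + Matrix::sparseMatrix(i = c(from[add], to[add]),
                                  j = c(to[add], from[add]),
                                  x = 1, dims = dim(W))
    W@x[] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp2 <- igraph::components(g)
  if (comp2$no > 1L)
    stop("graph disconnected after MST repair; component sizes: ",
         paste(comp2$csize, collapse = ", "))
  list(W = W, n_added = sum(add), components = comp$no)
}

#' Laplacian-eigenmaps embedding
#'
#' Builds the mutual-kNN graph, forms the graph Laplacian `L = D - W`, and
#' solves the generalized eigenproblem `L f = lambda D f`. The leading
#' (constant) eigenvector is dropped; the next `out_dim` eigenvectors, in
#' ascending eigenvalue order, map point i to `(f1(i), ..., fm(i))`.
#' Eigenvectors are D-orthonormal; each column's sign is fixed so its
#' largest-magnitude entry is positive. If the mutual-kNN graph is
#' disconnected it is repaired by adding the minimum-spanning-tree edges of
#' the Euclidean distance matrix that join components.
#'
#' @param points T x D matrix.
#' @param K mutual-kNN neighbor count.
#' @param out_dim embedding dimension m (`< T - 1`).
#' @param dense_cutoff below this T a dense symmetric eigensolver is used;
#'   above it, ARPACK (both deterministic).
#' @return T x m coordinate matrix with attributes `eigenvalues`,
#'   `n_edges`, `n_repaired`.
#' @export
laplacian_eigenmaps <- function(points, K, out_dim, dense_cutoff = 1500L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (out_dim >= n - 1L) stop("out_dim must be < T - 1")
  W <- knn_adjacency(points, K)
  rep_ <- repair_connectivity(W, points)
  W <- rep_$W
  deg <- Matrix::rowSums(W)
  dm <- 1 / sqrt(deg)
  ## normalized adjacency S = D^-1/2 W D^-1/2; eigenvalues mu = 1 - lambda,
  ## so the smallest generalized eigenvalues of L are the largest of S.
  S <- Matrix::Diagonal(x = dm) %*% W %*% Matrix::Diagonal(x = dm)
  nev <- out_dim + 1L
  if (n <= dense_cutoff) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    vals <- es$values[seq_len(nev)]
    vecs <- es$vectors[, seq_len(nev), drop = FALSE]
  } else {
    Sc <- methods::as(S, "CsparseMatrix")
    res <- igraph::arpack(function(x, extra) as.numeric(Sc %*% x),
                          sym = TRUE,
                          options = list(n = n, nev = nev,
                                         ncv = min(n, max(4L * nev, 40L)),
                                         which = "LA", maxiter = 5000,
                                         start = sin(seq_len(n))))
    ord <- order(res$values, decreasing = TRUE)
    vals <- res$values[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }
  f <- vecs * dm                        # f = D^-1/2 u; f' D f = I
  f <- f[, -1L, drop = FALSE]           # drop constant leading eigenvector
  ## canonical sign: largest-magnitude entry positive (first index on ties)
  for (j in seq_len(ncol(f))) {
    i <- which.max(abs(f[, j]))
    if (f[i, j] < 0) f[, j] <- -f[, j]
  }
  structure(f, eigenvalues = 1 - vals[-1L],
            n_edges = length(W@x) / 2, n_repaired = rep_$n_added)
}

#' Two-round spectral reduction to manifold coordinates
#'
#' Round 1 reduces the T time bins (points in neuron space) to 20
#' dimensions with `K = round(0.075 T)` mutual neighbors; round 2 reduces
#' those 20-dimensional points to the final 6 dimensions (the mean
#' estimated intrinsic dimension) with `K = round(0.025 T)`.
#'
#' @param z neuron x bin z-scored matrix (or a `pm_binned`).
#' @param dims output dimensions of the two rounds.
#' @param k_frac neighbor fractions of the two rounds.
#' @return a `pm_embedding` object: `coords` (T x m), `stage_params`,
#'   `graph` summaries.
#' @export
two_round_reduce <- function(z, dims = c(20L, 6L), k_frac = c(0.075, 0.025)) {
  if (inherits(z, "pm_binned")) z <- z$z
  pts <- t(as.matrix(z))
  Tt <- nrow(pts)
  if (Tt < 200L) stop("need at least 200 time bins")
  stages <- list(); coords <- pts
  for (r in 1:2) {
    K <- max(2L, round(k_frac[r] * Tt))
    coords <- laplacian_eigenmaps(coords, K, as.integer(dims[r]))
    stages[[r]] <- list(round = r, K = K, out_dim = as.integer(dims[r]),
                        n_edges = attr(coords, "n_edges"),
                        n_repaired = attr(coords, "n_repaired"))
  }
  structure(list(coords = `attributes<-`(coords, list(dim = dim(coords))),
                 stage_params = stages,
                 graph = list(n_edges = stages[[2]]$n_edges,
                              connected = TRUE)),
            class = "pm_embedding")
}
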