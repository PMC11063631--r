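## Trial-aligned cluster sequences, cosine trial similarity, transition-
## matrix label translation, and cross-dataset trial-outcome decoding.

#' Build the trial-by-bin cluster-label matrix
#'
#' One row per trial: the sequence of manifold cluster labels (sentinel -1
#' for the central point cloud) over the 20 bins (~10 s) from cue onset.
#' Trials whose window overruns the session end are dropped with a warning.
#'
#' @param clustering a `pm_clustering` (or integer label vector).
#' @param trials trial table with columns `cue_bin` and `class` (a
#'   `pm_binned$trials`).
#' @param n_bins sequence length (default 20).
#' @return a `pm_trial_matrix`: `sequences` (M x n_bins), `classes`,
#'   `cue_bins`.
#' @export
build_trial_matrix <- function(clustering, trials, n_bins = 20L) {
  labels <- if (inherits(clustering, "pm_clustering")) clustering$labels else
    clustering
  Tt <- length(labels)
  ok <- trials$cue_bin + n_bins - 1L <= Tt
  if (!any(ok)) stop("no usable trials (all overrun the session end)")
  if (any(!ok)) warning(sum(!ok), " trial(s) dropped at session end")
  tr <- trials[ok, , drop = FALSE]
  seqs <- t(vapply(tr$cue_bin,
                   function(cb) labels[cb:(cb + n_bins - 1L)],
                   integer(n_bins)))
  structure(list(sequences = seqs, classes = tr$class,
                 cue_bins = tr$cue_bin),
            class = "pm_trial_matrix")
}

#' Cosine similarity between two trial label sequences
#'
#' Treats the label sequences (sentinel -1, clusters 1..K) as numeric
#' vectors: `dot(a, b) / (|a| |b|)`.
#'
#' @param a,b equal-length numeric vectors with no zero entries.
#' @return similarity in [-1, 1].
#' @export
trial_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm trial sequence")
  sum(a * b) / (na * nb)
}

#' All pairwise trial similarities
#'
#' @param tm a `pm_trial_matrix` (or bare M x n matrix).
#' @return list with the full symmetric `matrix` and `pooled`, the
#'   off-diagonal lower-triangle values.
#' @export
pairwise_trial_similarity <- function(tm) {
  R <- if (inherits(tm, "pm_trial_matrix")) tm$sequences else tm
  if (nrow(R) < 2L) stop("need at least 2 trials")
  nrm <- sqrt(rowSums(R^2))
  if (any(nrm == 0)) stop("zero-norm trial sequence")
  Rn <- R / nrm
  S <- tcrossprod(Rn)
  list(matrix = S, pooled = S[lower.tri(S)])
}

#' Cluster-label transition probability matrix
#'
#' Row-stochastic transition matrix over all labels (sentinel plus clusters
#' 1..K*), counted over consecutive bins; transitions across run boundaries
#' are excluded. Self-transitions (dwell) are counted by default — dwell
#' structure is part of what identifies a cluster across datasets. Rows are
#' given a reproducible leaf order by Ward hierarchical clustering of the
#' row profiles; dendrogram branch flips are canonicalized by mean leaf
#' dwell probability (subtree minimum) so the order is invariant to label
#' permutation.
#'
#' @param clustering a `pm_clustering` (or label vector).
#' @param run_bins optional matrix of half-open bin intervals `[start, end)`
#'   (rows = runs); transitions across boundaries are dropped.
#' @param include_self count self-transitions (default TRUE).
#' @return a `pm_transition`: `P` ((K*+1) x (K*+1)), `order` (label ids in
#'   leaf order), `dwell`, `counts`.
#' @export
transition_matrix <- function(clustering, run_bins = NULL,
                              include_self = TRUE) {
  labels <- if (inherits(clustering, "pm_clustering")) clustering$labels else
    clustering
  Tt <- length(labels)
  lev <- sort(unique(labels))
  K <- max(labels)
  expect <- c(-1L, seq_len(K))
  missing <- setdiff(expect, lev)
  if (length(missing))
    stop("label(s) with zero occupancy: ", paste(missing, collapse = ", "),
         "; dataset excluded")
  from <- seq_len(Tt - 1L)
  if (!is.null(run_bins))
    from <- from[!(from + 1L) %in% run_bins[, 1]]   # no cross-run pairs
  f <- factor(labels[from], levels = expect)
  t2 <- factor(labels[from + 1L], levels = expect)
  counts <- table(f, t2)
  dwell <- diag(counts) / pmax(rowSums(counts), 1L)
  cmat <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  if (!include_self) diag(cmat) <- 0
  rs <- rowSums(cmat)
  if (any(rs == 0)) stop("label with no outgoing transitions")
  P <- cmat / rs
  hc <- hclust(dist(P), method = "ward.D2")
  dend <- reorder(as.dendrogram(hc), dwell, agglo.FUN = min)
  ord <- expect[order.dendrogram(dend)]
  structure(list(P = P, order = ord, dwell = dwell, counts = counts),
            class = "pm_transition")
}

#' Translate cluster labels between datasets
#'
#' Aligns two datasets' transition matrices by their hierarchical leaf
#' orders: the k-th label in `other`'s order maps to the k-th label in
#' `ref`'s order.
#'
#' @param ref,other `pm_transition` objects with equal label counts.
#' @return named integer vector: `mapping[as.character(l)]` is the ref
#'   label for other-label `l`; a bijection.
#' @export
translate_labels <- function(ref, other) {
  stopifnot(inherits(ref, "pm_transition"), inherits(other, "pm_transition"))
  if (length(ref$order) != length(other$order))
    stop("label sets differ in size")
  setNames(ref$order, as.character(other$order))
}

#' Apply a label mapping to a trial matrix
#'
#' @param tm a `pm_trial_matrix`.
#' @param mapping named vector from [translate_labels()].
#' @return the relabeled `pm_trial_matrix`.
#' @export
apply_label_mapping <- function(tm, mapping) {
  stopifnot(inherits(tm, "pm_trial_matrix"))
  s <- tm$sequences
  out <- s
  out[] <- mapping[as.character(s)]
  if (anyNA(out)) stop("mapping does not cover all labels")
  tm$sequences <- out
  tm
}

#' Decode trial outcomes across datasets
#'
#' Each trial in `ref` is assigned the class maximizing the summed cosine
#' trial similarity to the training trials of that class in `other`
#' (translate `other`'s labels first via [apply_label_mapping()]). The
#' shuffle null permutes trial classes in both datasets `n_perm` times;
#' p-values are the fraction of null accuracies at or above the observed.
#'
#' @param ref a `pm_trial_matrix` to decode (test set).
#' @param other the training `pm_trial_matrix` (labels already translated).
#' @param n_perm class shuffles for the null (default 200).
#' @param seed RNG seed.
#' @return a `pm_decoding`: `predicted`, per-class `accuracy`, `overall`,
#'   per-class `p`, `p_overall`, null matrices.
#' @export
decode_across <- function(ref, other, n_perm = 200L, seed = 1L) {
  stopifnot(inherits(ref, "pm_trial_matrix"),
            inherits(other, "pm_trial_matrix"))
  Rr <- ref$sequences; Ro <- other$sequences
  nr <- sqrt(rowSums(Rr^2)); no <- sqrt(rowSums(Ro^2))
  if (any(nr == 0) || any(no == 0)) stop("zero-norm trial sequence")
  sims <- tcrossprod(Rr / nr, Ro / no)      # M_ref x M_other
  class_levels <- sort(unique(c(ref$classes, other$classes)))
  absent <- setdiff(unique(ref$classes), unique(other$classes))
  if (length(absent))
    warning("class(es) absent in training set skipped: ",
            paste(absent, collapse = ", "))
  run <- function(train_classes, true_classes) {
    ind <- outer(class_levels, train_classes, "==") * 1
    scores <- sims %*% t(ind)               # M_ref x n_class
    pred <- class_levels[max.col(scores, ties.method = "first")]
    acc <- vapply(class_levels, function(cl) {
      idx <- true_classes == cl
      if (!any(idx)) NA_real_ else mean(pred[idx] == cl)
    }, numeric(1))
    list(pred = pred, acc = acc, overall = mean(pred == true_classes))
  }
  obs <- run(other$classes, ref$classes)
  null_acc <- matrix(NA_real_, n_perm, length(class_levels),
                     dimnames = list(NULL, class_levels))
  null_overall <- numeric(n_perm)
  with_seed(derive_seed(seed, 99L), {
    for (i in seq_len(n_perm)) {
      sh <- run(sample(other$classes), sample(ref$classes))
      null_acc[i, ] <- sh$acc
      null_overall[i] <- sh$overall
    }
  })
  p <- vapply(seq_along(class_levels), function(j) {
    if (is.na(obs$acc[j])) return(NA_real_)
    mean(null_acc[, j] >= obs$acc[j], na.rm = TRUE)
  }, numeric(1))
  structure(list(predicted = obs$pred,
                 accuracy = setNames(obs$acc, class_levels),
                 overall = obs$overall,
                 p = setNames(p, class_levels),
                 p_overall = mean(null_overall >= obs$overall),
                 null_accuracy = null_acc, null_overall = null_overall,
                 n_perm = as.integer(n_perm)),
            class = "pm_decoding")
}

#' Thirsty-quenched linear activity axis
#'
#' The population-vector difference between mean ongoing activity in the
#' thirsty and quenched states. Projections are scaled so the thirsty
#' anchor pattern maps to 1 and the quenched anchor to 0.
#'
#' @param z neuron x bin z-scored matrix.
#' @param thirsty_bins,quenched_bins bin indices defining the two anchor
#'   states.
#' @return a `pm_state_axis`: `axis`, `project(x)` for a neuron vector or
#'   matrix, anchor means.
#' @export
state_axis <- function(z, thirsty_bins, quenched_bins) {
  if (!length(thirsty_bins) || !length(quenched_bins))
    stop("undefined anchor-state bins")
  xt <- rowMeans(z[, thirsty_bins, drop = FALSE])
  xq <- rowMeans(z[, quenched_bins, drop = FALSE])
  axis <- xt - xq
  denom <- sum((xt - xq) * axis)
  if (denom == 0) stop("degenerate axis: anchors coincide")
  project <- function(x) {
    x <- as.matrix(x)
    as.numeric(crossprod(x - xq, axis)) / denom
  }
  structure(list(axis = axis, project = project, thirsty = xt,
                 quenched = xq),
            class = "pm_state_axis")
}

#' Per-trial baseline feature sequences
#'
#' Replaces each trial's 20-bin cluster sequence by a scalar sequence:
#' mean population activity per bin (`"mean_activity"`), or the per-bin
#' projection onto the thirsty-quenched axis (`"state_axis"`).
#'
#' @param z neuron x bin matrix.
#' @param trials trial table (`cue_bin`, `class`).
#' @param mode `"mean_activity"` or `"state_axis"`.
#' @param axis a `pm_state_axis` (required for `"state_axis"`).
#' @param n_bins sequence length (default 20).
#' @return a `pm_trial_matrix` whose `sequences` are the scalar features.
#' @export
trial_feature_matrix <- function(z, trials, mode = c("mean_activity",
                                                     "state_axis"),
                                 axis = NULL, n_bins = 20L) {
  mode <- match.arg(mode)
  Tt <- ncol(z)
  feat <- switch(mode,
                 mean_activity = colMeans(z),
                 state_axis = {
                   if (is.null(axis)) stop("state_axis mode needs an axis")
                   axis$project(z)
                 })
  ok <- trials$cue_bin + n_bins - 1L <= Tt
  tr <- trials[ok, , drop = FALSE]
  seqs <- t(vapply(tr$cue_bin, function(cb) feat[cb:(cb + n_bins - 1L)],
                   numeric(n_bins)))
  if (any(rowSums(seqs^2) == 0)) stop("zero-norm feature sequence")
  structure(list(sequences = seqs, classes = tr$class,
                 cue_bins = tr$cue_bin),
            class = "pm_trial_matrix")
}

#' Baseline decoders: overall activity level and state-axis projection
#'
#' Runs the summed-similarity decoder on scalar per-bin trial features
#' instead of cluster-label sequences, as control decoders for the
#' cluster-sequence decoder.
#'
#' @param ref_z,other_z neuron x bin matrices of the two sessions.
#' @param ref_trials,other_trials their trial tables.
#' @param mode `"mean_activity"` or `"state_axis"`.
#' @param ref_axis,other_axis `pm_state_axis` objects (state_axis mode).
#' @param n_perm,seed passed to [decode_across()].
#' @return a `pm_decoding`.
#' @export
baseline_decoders <- function(ref_z, ref_trials, other_z, other_trials,
                              mode = c("mean_activity", "state_axis"),
                              ref_axis = NULL, other_axis = NULL,
                              n_perm = 200L, seed = 1L) {
  mode <- match.arg(mode)
  ref_tm <- trial_feature_matrix(ref_z, ref_trials, mode, ref_axis)
  oth_tm <- trial_feature_matrix(other_z, other_trials, mode, other_axis)
  decode_across(ref_tm, oth_tm, n_perm = n_perm, seed = seed)
}
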