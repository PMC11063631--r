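## Behavioral parameterization of the manifold: label vectors and mutual
## information between cluster labels and behavioral variables.

#' Build a per-bin behavioral label vector
#'
#' Trial-outcome variables (one of the six go/no-go outcome classes) are
#' binary: 1 on bins 3-6 s after the cue onset of matching trials (outside
#' the visual-cue period), 0 elsewhere; all bins are valid. The continuous
#' variables `"pupil"` and `"cum_reward"` are divided into eight
#' equal-count bins (levels 1..8), and their valid mask is restricted to
#' the final 3 s of inter-trial intervals following correct-rejection
#' trials, where ongoing activity is unaffected by task events.
#'
#' @param bs a `pm_binned` session.
#' @param variable one of the six class names (see `TRIAL_CLASSES`),
#'   `"pupil"`, or `"cum_reward"`.
#' @return a `pm_behavior_labels`: `variable`, `labels` (length T),
#'   `valid_mask`.
#' @export
build_labels <- function(bs, variable) {
  stopifnot(inherits(bs, "pm_binned"))
  Tt <- bs$n_bins
  off <- round(c(3, 6) / bs$bin_s)           # 3-6 s window, in bins
  if (variable %in% TRIAL_CLASSES) {
    tr <- bs$trials[bs$trials$class == variable, , drop = FALSE]
    if (!nrow(tr)) stop("variable has no occurrences: ", variable)
    labels <- integer(Tt)
    for (cb in tr$cue_bin) {
      idx <- (cb + off[1]):(cb + off[2] - 1L)
      labels[idx[idx <= Tt]] <- 1L
    }
    return(structure(list(variable = variable, labels = labels,
                          valid_mask = rep(TRUE, Tt)),
                     class = "pm_behavior_labels"))
  }
  if (!variable %in% c("pupil", "cum_reward"))
    stop("unknown variable: ", variable)
  x <- bs[[variable]]
  mask <- quiet_iti_mask(bs)
  if (!any(mask)) stop("no valid bins for continuous variable")
  xm <- x[mask]
  if (diff(range(xm)) == 0)
    stop("degenerate continuous variable: octile bins undefined")
  ## equal-count bins via ranks; ties split deterministically by position so
  ## discrete covariates (e.g. reward counts) still fill all eight levels
  labels <- rep(NA_integer_, Tt)
  labels[mask] <-
    as.integer(floor((rank(xm, ties.method = "first") - 1) * 8 / length(xm))) + 1L
  structure(list(variable = variable, labels = labels, valid_mask = mask),
            class = "pm_behavior_labels")
}

## Final 3 s of inter-trial intervals that follow correct rejections.
quiet_iti_mask <- function(bs, trial_len_bins = 20L) {
  Tt <- bs$n_bins
  nfin <- round(3 / bs$bin_s)
  tr <- bs$trials
  mask <- rep(FALSE, Tt)
  for (i in seq_len(nrow(tr))) {
    if (!tr$class[i] %in% c("aversive_cr", "neutral_cr")) next
    nxt <- if (i < nrow(tr)) tr$cue_bin[i + 1L] else
      min(tr$cue_bin[i] + trial_len_bins + 10L, Tt + 1L)
    lo <- max(nxt - nfin, tr$cue_bin[i] + trial_len_bins)
    if (lo < nxt) mask[lo:(nxt - 1L)] <- TRUE
  }
  mask
}

#' Mutual information between cluster labels and a behavioral variable
#'
#' Plug-in mutual information (natural log) of the joint contingency table
#' of manifold cluster label — including the central-point-cloud sentinel —
#' and behavioral label, over the behavior's valid bins.
#'
#' @param clustering a `pm_clustering` (or an integer label vector).
#' @param behavior a `pm_behavior_labels`.
#' @return list with `mi` (nats) and the `contingency` table.
#' @export
mutual_information <- function(clustering, behavior) {
  cl <- if (inherits(clustering, "pm_clustering")) clustering$labels else
    clustering
  stopifnot(inherits(behavior, "pm_behavior_labels"))
  mask <- behavior$valid_mask & !is.na(behavior$labels)
  if (sum(mask) < 10L) stop("fewer than 10 valid overlapping bins")
  tab <- table(cluster = cl[mask], behavior = behavior$labels[mask])
  list(mi = mi_from_table(tab), contingency = tab)
}

mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
}

#' Shuffle test for cluster-behavior mutual information
#'
#' Builds a null by circularly shifting the behavioral labels by random
#' offsets along the valid bins (preserving their autocorrelation) and
#' recomputing MI. `p` is the fraction of null MI values at or above the
#' observed one.
#'
#' @param clustering a `pm_clustering` (or label vector).
#' @param behavior a `pm_behavior_labels`.
#' @param n_shuffle null samples (>= 100).
#' @param seed RNG seed.
#' @return a `pm_mi_result`: `mi`, `null`, `p`, `contingency`.
#' @export
mi_shuffle_test <- function(clustering, behavior, n_shuffle = 1000L,
                            seed = 1L) {
  if (n_shuffle < 100L) stop("n_shuffle must be >= 100")
  cl <- if (inherits(clustering, "pm_clustering")) clustering$labels else
    clustering
  obs <- mutual_information(cl, behavior)
  pos <- which(behavior$valid_mask & !is.na(behavior$labels))
  labs <- behavior$labels[pos]
  clm <- cl[pos]
  L <- length(pos)
  null <- with_seed(derive_seed(seed, 17L), {
    shifts <- sample(L - 1L, n_shuffle, replace = TRUE)
    vapply(shifts, function(s) {
      mi_from_table(table(clm, labs[((seq_len(L) - 1L + s) %% L) + 1L]))
    }, numeric(1))
  })
  structure(list(mi = obs$mi, null = null, p = mean(null >= obs$mi),
                 contingency = obs$contingency),
            class = "pm_mi_result")
}
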