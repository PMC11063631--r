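## Lick-train analysis: anticipatory-lick and cluster-sequence onsets, lick
## pattern similarity, and free-consumption pseudo-trials.

#' Lick-bout detection parameters from cue-period licking
#'
#' The bout threshold is the reciprocal of the typical cue-period lick
#' rate: `threshold_s = 1 / (mu + C * sigma)`, where `mu` and `sigma` are
#' the mean and SD across trials of the per-trial lick rate over the first
#' 0.5 s of cue presentation. `C` is 0.1 for water-reward sessions and
#' 0.35 for food-reward sessions.
#'
#' @param lick_times_s all session lick times (s).
#' @param cue_times_s per-trial cue onset times (s).
#' @param C reward-type constant (0.1 water, 0.35 food).
#' @param cue_window_s length of the early-cue window (default 0.5 s,
#'   i.e. 15 frames at 31 Hz).
#' @return a `pm_lick_params`: `mu`, `sigma` (licks/s), `C`, `threshold_s`.
#' @export
lick_onset_params <- function(lick_times_s, cue_times_s, C = 0.1,
                              cue_window_s = 0.5) {
  rates <- vapply(cue_times_s, function(t0)
    sum(lick_times_s >= t0 & lick_times_s < t0 + cue_window_s) /
      cue_window_s, numeric(1))
  mu <- mean(rates); sigma <- sd(rates)
  denom <- mu + C * sigma
  structure(list(mu = mu, sigma = sigma, C = C,
                 threshold_s = if (denom > 0) 1 / denom else Inf),
            class = "pm_lick_params")
}

#' Detect the anticipatory-lick onset of one trial
#'
#' Scans inter-lick intervals after cue onset for the first pair of licks
#' closer together than the bout threshold whose first lick falls inside
#' the response window; that lick's time is the onset. Absence of such a
#' pair is a valid outcome (`NA`).
#'
#' @param lick_times_s session lick times (s).
#' @param cue_time_s this trial's cue onset (s).
#' @param params a `pm_lick_params`.
#' @param window_s response window relative to cue onset (default
#'   `c(0.5, 4)` s).
#' @return onset in seconds post cue, or `NA`.
#' @export
detect_lick_onset <- function(lick_times_s, cue_time_s, params,
                              window_s = c(0.5, 4)) {
  stopifnot(inherits(params, "pm_lick_params"))
  lt <- sort(lick_times_s[lick_times_s >= cue_time_s &
                            lick_times_s <= cue_time_s + window_s[2] + 1])
  if (length(lt) < 2L) return(NA_real_)
  iv <- diff(lt)
  first <- lt[-length(lt)] - cue_time_s
  ok <- iv < params$threshold_s & first >= window_s[1] & first <= window_s[2]
  if (!any(ok)) return(NA_real_)
  first[which(ok)[1]]
}

#' Detect per-trial cluster-sequence onsets
#'
#' Candidate clusters are the two with the highest occupancy in the
#' response window of the trial sequences (sentinel excluded). For each
#' candidate, the per-trial onset is the first transition from the central
#' point cloud into that cluster; the chosen cluster is the one whose
#' onsets correlate best (Pearson) with the anticipatory-lick onsets.
#' Onset times are reported at bin centers, seconds post cue.
#'
#' @param tm a `pm_trial_matrix` of the trials of interest (e.g. rewarded
#'   trials), row-aligned with `lick_onsets_s`.
#' @param lick_onsets_s per-trial anticipatory-lick onsets (s post cue,
#'   NA allowed).
#' @param bin_s bin duration (s).
#' @param window_pos response-window positions within the sequence
#'   (default 5:8, i.e. 2-4 s post cue at 0.5-s bins).
#' @return a `pm_cluster_onset`: `cluster`, `onsets_s` (per trial, NA when
#'   no transition), `candidates`, `correlations`.
#' @export
detect_cluster_onset <- function(tm, lick_onsets_s, bin_s = 0.5,
                                 window_pos = 5:8) {
  stopifnot(inherits(tm, "pm_trial_matrix"))
  seqs <- tm$sequences
  if (nrow(seqs) < 5L || sum(!is.na(lick_onsets_s)) < 5L)
    stop("need at least 5 trials with detected lick onsets")
  occ <- table(seqs[, window_pos])
  occ <- occ[names(occ) != "-1"]
  if (!length(occ)) stop("no cluster occupancy in the response window")
  cand <- as.integer(names(sort(occ, decreasing = TRUE)))[
    seq_len(min(2L, length(occ)))]
  onset_for <- function(cl) {
    apply(seqs, 1L, function(s) {
      t <- which(s[-1L] == cl & s[-length(s)] == -1L)
      if (!length(t)) NA_real_ else (t[1]) * bin_s + bin_s / 2
    })
  }
  onsets <- lapply(cand, onset_for)
  if (length(cand) == 1L) {
    chosen <- 1L
    cors <- NA_real_
  } else {
    cors <- vapply(onsets, function(o) {
      ok <- !is.na(o) & !is.na(lick_onsets_s)
      if (sum(ok) < 3L) return(-Inf)
      suppressWarnings(cor(o[ok], lick_onsets_s[ok]))
    }, numeric(1))
    cors[is.na(cors)] <- -Inf
    chosen <- which.max(cors)
  }
  structure(list(cluster = cand[chosen], onsets_s = onsets[[chosen]],
                 candidates = cand, correlations = cors),
            class = "pm_cluster_onset")
}

#' Smooth a binary lick vector with a forward sliding window
#'
#' `SL[t]` is the mean of the next `window` frames (truncated at the trial
#' end).
#'
#' @param x binary per-frame lick indicator.
#' @param window frames (default 100, ~3.3 s at 31 Hz).
#' @return numeric vector in [0, 1], same length as `x`.
#' @export
smooth_licks <- function(x, window = 100L) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + window - 1L, n)
  (cs[hi + 1L] - cs[seq_len(n)]) / (hi - seq_len(n) + 1L)
}

#' Lick-pattern similarity between two trials
#'
#' Reciprocal Euclidean distance between the smoothed lick patterns, with
#' an epsilon regularizer so identical patterns give a finite (capped)
#' maximum: `1 / (eps + ||SL_a - SL_b||_2)`.
#'
#' @param a,b equal-length binary per-frame lick vectors.
#' @param window smoothing window in frames.
#' @param eps regularizer (default 1e-6).
#' @return positive similarity value.
#' @export
lick_similarity <- function(a, b, window = 100L, eps = 1e-6) {
  stopifnot(length(a) == length(b))
  1 / (eps + sqrt(sum((smooth_licks(a, window) - smooth_licks(b, window))^2)))
}

#' Construct pseudo-trials from free-consumption lick bouts
#'
#' Within the free-consumption epoch, a pseudo-trial onset is the second
#' lick of any consecutive pair separated by more than `gap_s` (a bout
#' start). Windows span 2 s before to 4 s after the onset; overlapping
#' windows are removed greedily in time order. If fewer than `min_count`
#' pseudo-trials survive, the gap falls back to `fallback_gap_s`.
#'
#' @param lick_times_s session lick times (s).
#' @param epoch_s `c(start, end)` of the free-consumption epoch (s).
#' @param labels per-bin cluster labels (sentinel -1).
#' @param bin_s bin duration (s).
#' @param frame_hz acquisition rate for the lick patterns.
#' @param gap_s bout-defining gap (default 1 s).
#' @param fallback_gap_s fallback gap (default 0.5 s).
#' @param min_count minimum pseudo-trials before falling back (default 5).
#' @param pre_s,post_s window extent around the onset.
#' @return a `pm_trial_matrix` with extra fields: `onsets_s`,
#'   `lick_patterns` (M x frames), `lick_rate_first2s`, `gap_used_s`;
#'   `classes` are all `"pseudo"`.
#' @export
build_pseudo_trials <- function(lick_times_s, epoch_s, labels, bin_s = 0.5,
                                frame_hz = 31, gap_s = 1.0,
                                fallback_gap_s = 0.5, min_count = 5L,
                                pre_s = 2, post_s = 4) {
  lt <- sort(lick_times_s[lick_times_s >= epoch_s[1] &
                            lick_times_s < epoch_s[2]])
  if (length(lt) < 2L) stop("free-consumption epoch has too few licks")
  pick <- function(gap) {
    cand <- lt[which(diff(lt) > gap) + 1L]
    cand <- cand[cand - pre_s >= epoch_s[1] & cand + post_s <= epoch_s[2]]
    keep <- numeric(0)
    last_end <- -Inf
    for (t in cand) {
      if (t - pre_s >= last_end) { keep <- c(keep, t); last_end <- t + post_s }
    }
    keep
  }
  onsets <- pick(gap_s)
  gap_used <- gap_s
  if (length(onsets) < min_count) {
    onsets <- pick(fallback_gap_s)
    gap_used <- fallback_gap_s
  }
  if (!length(onsets)) stop("no pseudo-trial candidates at either gap")
  nb <- floor((pre_s + post_s) / bin_s)
  nf <- floor((pre_s + post_s) * frame_hz)
  seqs <- t(vapply(onsets, function(t) {
    b0 <- floor((t - pre_s) / bin_s) + 1L
    labels[b0:(b0 + nb - 1L)]
  }, integer(nb)))
  pats <- t(vapply(onsets, function(t) {
    f0 <- floor((t - pre_s) * frame_hz)
    fr <- floor(lt * frame_hz)
    as.integer(tabulate(fr - f0 + 1L, nbins = nf) > 0)
  }, integer(nf)))
  rate2 <- vapply(onsets, function(t)
    sum(lt >= t & lt < t + 2) / 2, numeric(1))
  structure(list(sequences = seqs, classes = rep("pseudo", length(onsets)),
                 cue_bins = floor((onsets - pre_s) / bin_s) + 1L,
                 onsets_s = onsets, lick_patterns = pats,
                 lick_rate_first2s = rate2, gap_used_s = gap_used),
            class = c("pm_pseudo_trials", "pm_trial_matrix"))
}

#' Select pseudo-trials with task-matched lick rates
#'
#' Keeps pseudo-trials whose mean lick rate over the first 2 s of the bout
#' lies within mean +/- SD of the task trials' first-2-s rates.
#'
#' @param pseudo a `pm_pseudo_trials` from [build_pseudo_trials()].
#' @param task_rates per-trial task lick rates over the first 2 s of the
#'   lick bout (licks/s).
#' @return the filtered `pm_pseudo_trials` (with a `kept` attribute);
#'   warns and returns an empty selection if nothing matches.
#' @export
rate_matched_selection <- function(pseudo, task_rates) {
  stopifnot(inherits(pseudo, "pm_pseudo_trials"), length(task_rates) > 0)
  mu <- mean(task_rates); s <- sd(task_rates)
  keep <- pseudo$lick_rate_first2s >= mu - s &
    pseudo$lick_rate_first2s <= mu + s
  if (!any(keep)) warning("no pseudo-trials within the task lick-rate band")
  out <- pseudo
  for (f in c("sequences", "lick_patterns"))
    out[[f]] <- out[[f]][keep, , drop = FALSE]
  for (f in c("classes", "cue_bins", "onsets_s", "lick_rate_first2s"))
    out[[f]] <- out[[f]][keep]
  attr(out, "kept") <- which(keep)
  out
}

#' Per-trial lick rate over the first seconds of the lick bout
#'
#' @param lick_times_s session lick times (s).
#' @param bout_start_s per-trial bout start times (s, absolute; NA
#'   skipped).
#' @param window_s rate window (default 2 s).
#' @return licks/s per trial (NA where bout start is NA).
#' @export
trial_lick_rates <- function(lick_times_s, bout_start_s, window_s = 2) {
  vapply(bout_start_s, function(t) {
    if (is.na(t)) return(NA_real_)
    sum(lick_times_s >= t & lick_times_s < t + window_s) / window_s
  }, numeric(1))
}
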