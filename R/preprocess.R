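## Preprocessing: outlier-neuron exclusion, temporal binning, z-scoring.

#' Average consecutive frames into time bins
#'
#' Down-samples a neuron x frame trace matrix by averaging every
#' `frames_per_bin` consecutive frames (15 frames at 31 Hz gives ~0.5 s
#' bins). A trailing partial window is dropped.
#'
#' @param mat neuron x frame numeric matrix.
#' @param frames_per_bin frames per bin (>= 1).
#' @return neuron x bin matrix with `floor(ncol(mat) / frames_per_bin)`
#'   columns.
#' @export
bin_traces <- function(mat, frames_per_bin = 15L) {
  stopifnot(is.matrix(mat), frames_per_bin >= 1)
  fpb <- as.integer(frames_per_bin)
  nb <- ncol(mat) %/% fpb
  if (nb < 1L) stop("fewer frames than one bin")
  x <- mat[, seq_len(nb * fpb), drop = FALSE]
  dim(x) <- c(nrow(mat), fpb, nb)
  colMeans(aperm(x, c(2L, 1L, 3L)), dims = 1L)
}

#' Microscope-specific outlier threshold
#'
#' The maximum plausible \eqn{\Delta F/F} differs between the two
#' microscopes used for acquisition; traces exceeding the threshold are
#' treated as extraction artifacts.
#'
#' @param microscope_id `"A"` (threshold 2000\%) or `"B"` (5000\%).
#' @return threshold in \eqn{\Delta F/F} percent.
#' @export
microscope_threshold <- function(microscope_id) {
  th <- c(A = 2000, B = 5000)
  if (!microscope_id %in% names(th)) stop("unknown microscope_id")
  unname(th[microscope_id])
}

#' Exclude neurons with abnormally high \eqn{\Delta F/F}
#'
#' A neuron is dropped iff its maximum raw \eqn{\Delta F/F} over the whole
#' session exceeds the threshold. Exclusion happens before binning, on raw
#' traces. Survivor order is preserved.
#'
#' @param session a `pm_session` (or a bare neuron x frame matrix).
#' @param threshold_pct threshold in \eqn{\Delta F/F} percent; defaults to
#'   the session's microscope calibration.
#' @return integer indices of kept neurons.
#' @export
exclude_outlier_neurons <- function(session, threshold_pct = NULL) {
  dff <- if (inherits(session, "pm_session")) session$dff else session
  if (is.null(threshold_pct)) {
    id <- if (inherits(session, "pm_session")) session$microscope_id else "A"
    threshold_pct <- microscope_threshold(id)
  }
  stopifnot(threshold_pct > 0)
  mx <- apply(dff, 1L, max)
  kept <- which(mx <= threshold_pct)
  if (!length(kept)) stop("all neurons excluded as outliers (empty dataset)")
  kept
}

#' Z-score binned traces per neuron, per span
#'
#' Within each span (a z-scoring interval of bins), each neuron's trace has
#' its span mean subtracted and is divided by its span SD. The population SD
#' convention (divisor n) is used.
#'
#' @param binned neuron x bin matrix.
#' @param spans list of half-open bin intervals `c(start, end)` (1-based,
#'   `end` exclusive) partitioning the bin axis; default one whole-session
#'   span.
#' @return z-scored matrix of the same shape.
#' @export
zscore_bins <- function(binned, spans = list(c(1L, ncol(binned) + 1L))) {
  out <- binned
  for (sp in spans) {
    idx <- sp[1]:(sp[2] - 1L)
    if (length(idx) < 2L) stop("z-scoring span must have >= 2 bins")
    x <- binned[, idx, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))   # population SD
    bad <- which(sdv == 0)
    if (length(bad))
      stop("zero-variance neuron(s) within a span: ",
           paste(bad, collapse = ", "))
    out[, idx] <- (x - mu) / sdv
  }
  out
}

#' Preprocess a raw session into the binned, z-scored form
#'
#' Applies outlier-neuron exclusion on raw traces, 15-frame binning,
#' per-neuron z-scoring (whole-session by default, or per run), and
#' re-indexes events, trials and covariates to bins. Event time `t` maps to
#' bin `floor(t * frame_hz / frames_per_bin) + 1`, i.e. `floor(t / bin)` in
#' 0-based bins.
#'
#' @param session a `pm_session`.
#' @param per_run_zscore z-score each run separately (for sessions with
#'   extended breaks or z-plane shifts between runs).
#' @param threshold_pct optional outlier threshold override.
#' @return a `pm_binned` object: `z` (neuron x bin, z-units), `bin_s`
#'   (exact bin duration, s), `kept_neurons`, `events`/`trials` with bin
#'   columns, per-bin `pupil` and `cum_reward`, `run_bins`, `n_bins`.
#' @export
preprocess_session <- function(session, per_run_zscore = FALSE,
                               threshold_pct = NULL) {
  stopifnot(inherits(session, "pm_session"))
  fpb <- session$frames_per_bin
  kept <- exclude_outlier_neurons(session, threshold_pct)
  binned <- bin_traces(session$dff[kept, , drop = FALSE], fpb)
  nb <- ncol(binned)
  run_bins <- cbind(start = (session$run_bounds[, "start"] - 1L) %/% fpb + 1L,
                    end = pmin((session$run_bounds[, "end"] - 1L) %/% fpb + 1L,
                               nb + 1L))
  spans <- if (per_run_zscore)
    lapply(seq_len(nrow(run_bins)), function(i) run_bins[i, ]) else
      list(c(1L, nb + 1L))
  z <- zscore_bins(binned, spans)

  bdur <- fpb / session$frame_hz
  to_bin <- function(t) as.integer(floor(t * session$frame_hz / fpb)) + 1L
  events <- session$events
  events$bin <- to_bin(events$time_s)
  trials <- session$trials
  trials$cue_bin <- to_bin(trials$cue_time_s)
  drop <- trials$cue_bin > nb
  trials <- trials[!drop, , drop = FALSE]

  cov <- session$covariates
  cov_bin <- to_bin(cov$time_s)
  keep <- cov_bin >= 1L & cov_bin <= nb
  pupil <- as.numeric(tapply(cov$pupil[keep], cov_bin[keep], mean))
  cum_reward <- as.numeric(tapply(cov$cum_reward[keep], cov_bin[keep], mean))

  structure(list(z = z, bin_s = bdur, kept_neurons = kept,
                 events = events, trials = trials,
                 pupil = pupil, cum_reward = cum_reward,
                 run_bins = run_bins, n_bins = nb,
                 per_run_zscore = per_run_zscore),
            class = "pm_binned")
}
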