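## Synthetic-session generator: go/no-go sessions with a known latent
## cluster-state process, plus geometric fixtures for the estimators.

TRIAL_CLASSES <- c("reward_hit", "reward_miss",
                   "aversive_fa", "aversive_cr",
                   "neutral_fa", "neutral_cr")

#' Configuration for the synthetic-session generator
#'
#' Bundles every knob of the generator. Defaults emulate one imaging day of
#' a head-fixed go/no-go session: 200 neurons at 31 Hz, six trial-outcome
#' classes, a latent state process with one central state (0) and seven
#' peripheral cluster states (1..7), a stereotyped 2-3-cluster sequence on
#' rewarded trials whose onset lags anticipatory-lick onset by ~1 s, slow
#' satiety drift tracking cumulative rewards, a pupil-like covariate coupled
#' to that drift, and a free-consumption epoch of lick bouts after the task.
#'
#' @param n_neurons number of simulated neurons.
#' @param n_trials_per_class trials per each of the six outcome classes.
#' @param bin_s nominal time-bin length in seconds (bins hold
#'   `frames_per_bin` frames; the exact bin duration is
#'   `frames_per_bin / frame_hz`).
#' @param frame_hz acquisition rate in Hz.
#' @param frames_per_bin frames averaged into one bin.
#' @param noise_sd emission noise SD at the bin level, in z-units.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param reward_state_sequence ordered cluster ids (2-3 of them, from 1..7)
#'   visited back-and-forth on rewarded trials.
#' @param lag_mean_s,lag_sd_s distribution of (cluster-sequence onset -
#'   anticipatory-lick onset) on rewarded trials, seconds.
#' @param drift_gain coupling of the slow satiety drift into the traces
#'   (z-units at full drift).
#' @param pupil_coupling coupling of the drift into the pupil covariate.
#' @param free_epoch list: `enabled`, `n_bins`, plus lick-bout statistics
#'   (`bout_rate_hz`, `bout_len_s` range, `gap_s` range).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_neurons = 200,
                       n_trials_per_class = 35,
                       bin_s = 0.5,
                       frame_hz = 31,
                       frames_per_bin = 15,
                       noise_sd = 0.6,
                       seed = 1L,
                       reward_state_sequence = c(6L, 7L),
                       lag_mean_s = 1.0,
                       lag_sd_s = 0.15,
                       drift_gain = 0.5,
                       pupil_coupling = 0.8,
                       state_amp_z = 2.5,
                       central_wander_z = 1.0,
                       free_epoch = list(enabled = TRUE, n_bins = 600,
                                         bout_rate_hz = 6.5,
                                         bout_len_s = c(2, 5),
                                         gap_s = c(2, 8))) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              n_trials_per_class = as.integer(n_trials_per_class),
              bin_s = bin_s, frame_hz = frame_hz,
              frames_per_bin = as.integer(frames_per_bin),
              noise_sd = noise_sd, seed = as.integer(seed),
              reward_state_sequence = as.integer(reward_state_sequence),
              lag_mean_s = lag_mean_s, lag_sd_s = lag_sd_s,
              drift_gain = drift_gain, pupil_coupling = pupil_coupling,
              free_epoch = free_epoch, state_amp_z = state_amp_z,
              central_wander_z = central_wander_z)
  if (cfg$n_neurons < 1L) stop("invalid config: n_neurons must be positive")
  if (cfg$n_trials_per_class < 1L)
    stop("invalid config: n_trials_per_class must be positive")
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (cfg$frames_per_bin < 1L) stop("invalid config: frames_per_bin")
  nseq <- length(cfg$reward_state_sequence)
  if (nseq < 2L || nseq > 3L ||
      !all(cfg$reward_state_sequence %in% 1:7) ||
      anyDuplicated(cfg$reward_state_sequence))
    stop("invalid config: reward_state_sequence must be 2-3 distinct ids in 1..7")
  class(cfg) <- "sim_config"
  cfg
}

bin_duration <- function(cfg) cfg$frames_per_bin / cfg$frame_hz

## Rhythmic lick train on [t0, t1): near-regular inter-lick intervals with
## small uniform jitter (licking is rhythmic, not Poisson).
rhythmic_train <- function(t0, t1, interval, jitter = 0.08 * interval) {
  if (t1 <= t0) return(numeric(0))
  n_max <- ceiling((t1 - t0) / (interval * 0.8)) + 2L
  gaps <- interval + runif(n_max, -jitter, jitter)
  tt <- t0 + cumsum(c(0, gaps))
  tt[tt < t1]
}

## Base transition kernel over states {0..7}: distinct rows so transition
## profiles identify clusters across sessions.
base_kernel <- function() {
  P <- matrix(0, 8, 8)
  stay <- 0.15 + 0.09 * (1:7)          # wide dwell gradient, gaps >> noise
  w <- (1 - stay) / sum(1 - stay)      # balances cluster occupancy
  P[1, ] <- c(0.55, 0.45 * w)
  for (i in 1:7) {
    partner <- (i %% 7) + 1
    row <- numeric(8)
    row[i + 1] <- stay[i]
    row[1] <- 0.9 * (1 - stay[i])
    row[partner + 1] <- row[partner + 1] + 0.1 * (1 - stay[i])
    P[i + 1, ] <- row / sum(row)
  }
  P
}

## Back-and-forth visit plan through the reward sequence, semi-Markov dwell
## times of 1-4 bins per visit, truncated to n_bins.
reward_visit_plan <- function(states, n_bins) {
  k <- length(states)
  path <- if (k == 2) states else c(states, states[(k - 1):1][-(k - 1)])
  out <- integer(0)
  i <- 1L
  while (length(out) < n_bins) {
    out <- c(out, rep(path[((i - 1L) %% length(path)) + 1L], sample(1:4, 1L)))
    i <- i + 1L
  }
  out[seq_len(n_bins)]
}

#' Generate one synthetic imaging session with ground truth
#'
#' Simulates the latent cluster-state process, the stereotyped rewarded-trial
#' sequence, frame-level lick trains, reward deliveries, pupil and
#' cumulative-reward covariates, a free-consumption epoch, and the
#' neuron-by-frame \eqn{\Delta F/F} emission.
#'
#' @param config a [sim_config()].
#' @return a list with elements `session` (class `pm_session`: `dff`
#'   neurons x frames matrix in \eqn{\Delta F/F} percent, `frame_hz`,
#'   `frames_per_bin`, `run_bounds` half-open 1-based frame intervals,
#'   `events` table, `covariates` table, `microscope_id`) and `ground_truth`
#'   (class `pm_ground_truth`: per-bin `state_sequence` in 0..7, emission
#'   `loading_matrix` (neuron x 8, \eqn{\Delta F/F} units), per-trial
#'   `lick_onsets` and `cluster_onsets` in seconds post cue,
#'   `label_permutation`, and the trial table).
#' @export
generate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  fpb <- cfg$frames_per_bin
  bdur <- bin_duration(cfg)
  trial_len <- 20L; iti_len <- 10L; lead_in <- 10L
  n_trials <- 6L * cfg$n_trials_per_class

  ## ---- trial schedule ----
  classes <- sample(rep(TRIAL_CLASSES, cfg$n_trials_per_class))
  cue_bin <- lead_in + (seq_len(n_trials) - 1L) * (trial_len + iti_len) + 1L
  n_task_bins <- lead_in + n_trials * (trial_len + iti_len)
  free_on <- isTRUE(cfg$free_epoch$enabled)
  n_free <- if (free_on) as.integer(cfg$free_epoch$n_bins) else 0L
  n_bins <- n_task_bins + n_free
  n_frames <- n_bins * fpb
  cue_time <- (cue_bin - 1L) * bdur
  cue_type <- c(reward_hit = "reward", reward_miss = "reward",
                aversive_fa = "aversive", aversive_cr = "aversive",
                neutral_fa = "neutral", neutral_cr = "neutral")[classes]
  responded <- classes %in% c("reward_hit", "aversive_fa", "neutral_fa")

  ## ---- licks, rewards, per-trial onsets ----
  lick_times <- numeric(0)
  reward_times <- rep(NA_real_, n_trials)
  lick_onsets <- rep(NA_real_, n_trials)     # s post cue
  cluster_onsets <- rep(NA_real_, n_trials)  # s post cue (latent, pre-binning)
  for (i in seq_len(n_trials)) {
    if (!responded[i]) next
    onset <- runif(1, 1.0, 2.5)
    lick_onsets[i] <- onset
    t0 <- cue_time[i]
    tr <- c(rhythmic_train(t0, t0 + 0.5, 0.25),
            rhythmic_train(t0 + 0.55, t0 + onset, 0.65, 0.05))
    if (classes[i] == "reward_hit") {
      burst <- rhythmic_train(t0 + onset, t0 + onset + 2.5, 0.125, 0.01)
      resp_lick <- burst[burst >= t0 + 2][1]   # first lick in response window
      if (is.na(resp_lick)) resp_lick <- t0 + 2
      reward_times[i] <- resp_lick
      consume <- rhythmic_train(t0 + onset + 2.5, resp_lick + 3.0, 0.15, 0.015)
      tr <- c(tr, burst, consume)
      cluster_onsets[i] <- onset + rnorm(1, cfg$lag_mean_s, cfg$lag_sd_s)
    } else { # false alarms: lick burst, no reward, no stereotyped sequence
      tr <- c(tr, rhythmic_train(t0 + onset, t0 + onset + 1.5, 0.125, 0.01))
    }
    lick_times <- c(lick_times, tr)
  }

  ## ---- free-consumption epoch lick bouts ----
  free_start <- n_task_bins * bdur
  free_end <- n_bins * bdur
  if (free_on) {
    t <- free_start + runif(1, 1, 3)
    while (t < free_end - 2) {
      blen <- runif(1, cfg$free_epoch$bout_len_s[1], cfg$free_epoch$bout_len_s[2])
      lick_times <- c(lick_times,
                      rhythmic_train(t, min(t + blen, free_end),
                                     1 / cfg$free_epoch$bout_rate_hz))
      t <- t + blen + runif(1, cfg$free_epoch$gap_s[1], cfg$free_epoch$gap_s[2])
    }
  }
  ## snap licks to frames, deduplicate
  lick_frames <- sort(unique(pmin(pmax(floor(lick_times * cfg$frame_hz), 0L),
                                  n_frames - 1L)))
  lick_times <- lick_frames / cfg$frame_hz

  ## ---- satiety drift from cumulative rewards ----
  n_rewards_total <- max(1L, sum(!is.na(reward_times)))
  reward_sorted <- sort(reward_times[!is.na(reward_times)])
  bin_end_time <- seq_len(n_bins) * bdur
  cum_reward_bin <- findInterval(bin_end_time, reward_sorted)
  drift <- cum_reward_bin / n_rewards_total    # 0 (thirsty) -> 1 (quenched)

  ## ---- latent state sequence ----
  P0 <- base_kernel()
  state <- integer(n_bins)
  scripted <- integer(n_bins)  # 0 = free-running, else forced state + 1
  for (i in seq_len(n_trials)) {
    if (classes[i] != "reward_hit" || is.na(cluster_onsets[i])) next
    on_bin <- cue_bin[i] + floor(cluster_onsets[i] / bdur)
    seq_len_bins <- 10L
    scripted[cue_bin[i]:(on_bin - 1L)] <- 1L   # attentive central state
    plan <- reward_visit_plan(cfg$reward_state_sequence, seq_len_bins)
    idx <- on_bin:(on_bin + seq_len_bins - 1L)
    scripted[idx] <- plan + 1L
    post <- (on_bin + seq_len_bins):min(on_bin + seq_len_bins + 1L, n_bins)
    scripted[post] <- 1L                        # settle back to center
  }
  cur <- 0L
  for (b in seq_len(n_bins)) {
    if (scripted[b] > 0L) {
      cur <- scripted[b] - 1L
    } else {
      row <- P0[cur + 1L, ]
      if (cur == 0L) { # satiety damps excursions from the central state
        damp <- 1 - 0.5 * drift[b]
        row <- c(1 - damp * (1 - row[1]), row[-1] * damp)
      }
      cur <- sample(0:7, 1L, prob = row)
    }
    state[b] <- cur
  }

  ## ---- emission ----
  m <- max(1L, cfg$n_neurons %/% 8L)
  Lz <- matrix(rnorm(cfg$n_neurons * 8L, 0, 0.3), cfg$n_neurons, 8L)
  Lz[, 1] <- 0
  for (s in 1:7) {
    blk <- (((s - 1L) * m) %% cfg$n_neurons) + seq_len(m)
    Lz[blk, s + 1L] <- Lz[blk, s + 1L] + cfg$state_amp_z
  }
  w_drift <- rnorm(cfg$n_neurons, -0.5, 0.5)   # quenching lowers most neurons
  loading <- 100 * (0.5 + 0.3 * Lz)            # emission units (dff %)
  state_f <- rep(state, each = fpb)
  drift_f <- rep(drift, each = fpb)
  dff <- loading[, state_f + 1L, drop = FALSE] +
    (100 * 0.3 * cfg$drift_gain) * outer(w_drift, drift_f)
  if (cfg$central_wander_z > 0) {
    ## ongoing (central-state) activity wanders slowly through neuron space,
    ## making the central point cloud diffuse as in real recordings
    u <- vapply(1:3, function(j)
      as.numeric(stats::filter(rnorm(n_bins, 0, sqrt(1 - 0.9^2)), 0.9,
                               method = "recursive")), numeric(n_bins))
    Wc <- matrix(rnorm(cfg$n_neurons * 3L, 0, cfg$central_wander_z / sqrt(3)),
                 cfg$n_neurons, 3L)
    wb <- (100 * 0.3) * tcrossprod(Wc, u)    # neurons x bins
    cen_f <- which(state_f == 0L)
    dff[, cen_f] <- dff[, cen_f] + wb[, ((cen_f - 1L) %/% fpb) + 1L]
  }
  if (cfg$noise_sd > 0)
    dff <- dff + matrix(rnorm(length(dff), 0,
                              100 * 0.3 * cfg$noise_sd * sqrt(fpb)),
                        nrow(dff), ncol(dff))

  ## ---- covariates ----
  ar <- stats::filter(rnorm(n_bins, 0, 0.03), 0.95, method = "recursive")
  pupil_bin <- 1.2 - cfg$pupil_coupling * drift +
    0.3 * (state != 0L) + as.numeric(ar)   # arousal transient on excursions
  frame_time <- (seq_len(n_frames) - 1L) / cfg$frame_hz
  covariates <- data.frame(time_s = frame_time,
                           pupil = rep(pupil_bin, each = fpb),
                           cum_reward = rep(cum_reward_bin, each = fpb))

  ## ---- event table ----
  events <- rbind(
    data.frame(time_s = cue_time, event = "cue_on", cue_type = cue_type,
               responded = responded, stringsAsFactors = FALSE),
    data.frame(time_s = lick_times, event = "lick", cue_type = NA,
               responded = NA),
    data.frame(time_s = reward_times[!is.na(reward_times)], event = "reward",
               cue_type = NA, responded = NA),
    if (free_on)
      data.frame(time_s = c(free_start, free_end), cue_type = NA,
                 event = c("epoch_start", "epoch_end"), responded = NA)
  )
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  trials <- data.frame(trial = seq_len(n_trials), class = classes,
                       cue_type = cue_type, responded = responded,
                       cue_bin = cue_bin, cue_time_s = cue_time,
                       stringsAsFactors = FALSE)

  session <- structure(
    list(dff = dff, frame_hz = cfg$frame_hz, frames_per_bin = fpb,
         run_bounds = matrix(c(1L, n_frames + 1L), 1L, 2L,
                             dimnames = list(NULL, c("start", "end"))),
         events = events, covariates = covariates, trials = trials,
         microscope_id = "A"),
    class = "pm_session")
  gt <- structure(
    list(state_sequence = state, loading_matrix = loading,
         lick_onsets = lick_onsets, cluster_onsets = cluster_onsets,
         label_permutation = 0:7, trials = trials,
         reward_state_sequence = cfg$reward_state_sequence,
         drift = drift, config = cfg),
    class = "pm_ground_truth")
  list(session = session, ground_truth = gt)
}

#' Generate a pair of sessions related by a cluster-label permutation
#'
#' The second session is drawn with identical dynamics parameters (and an
#' independent noise realization unless `same_noise = TRUE`) and its latent
#' state ids are relabeled by `permutation`; the central state is fixed
#' (0 maps to 0). Used to exercise cross-dataset label translation.
#'
#' @param config a [sim_config()].
#' @param permutation an integer vector: a bijection of `1:7`.
#' @param same_noise reuse the first session's seed so the two sessions
#'   differ only in labeling.
#' @return list of two `generate_session()`-style lists (`a`, `b`);
#'   `b$ground_truth$label_permutation` records the applied permutation as a
#'   length-8 vector over states 0..7.
#' @export
generate_paired_sessions <- function(config = sim_config(), permutation,
                                     same_noise = FALSE) {
  p <- as.integer(permutation)
  if (length(p) != 7L || !setequal(p, 1:7))
    stop("permutation must be a bijection on 1..7")
  a <- generate_session(config)
  cfg_b <- config
  if (!same_noise) cfg_b$seed <- derive_seed(config$seed, 7919L)
  b <- generate_session(cfg_b)
  full <- c(0L, p)                       # state s (0-based) -> full[s + 1]
  b$ground_truth$state_sequence <- full[b$ground_truth$state_sequence + 1L]
  lm <- b$ground_truth$loading_matrix
  lm2 <- lm
  lm2[, full + 1L] <- lm                 # column for new id = old column
  b$ground_truth$loading_matrix <- lm2
  b$ground_truth$reward_state_sequence <-
    full[b$ground_truth$reward_state_sequence + 1L]
  b$ground_truth$label_permutation <- full
  list(a = a, b = b)
}

#' Generate geometric point-set fixtures
#'
#' Fixtures with known geometry for the dimensionality, embedding, topology
#' and clustering estimators: uniform samples from a d-cube (`"cube"`), a
#' noisy circle (`"ring"`), or seven well-separated Gaussian blobs around a
#' central Gaussian cloud (`"blobs_cloud"`).
#'
#' @param kind one of `"cube"`, `"ring"`, `"blobs_cloud"`.
#' @param n number of points (at least 10).
#' @param params list of kind-specific parameters: cube: `d` (dimension);
#'   ring: `radius`, `noise_sd`, `equally_spaced`; blobs_cloud: `dim`,
#'   `radius`, `blob_sd`, `cloud_sd`, `cloud_frac`.
#' @param seed RNG seed.
#' @return list with `points` (n x d matrix), `labels` (blobs_cloud only:
#'   0 = central cloud, 1..7 = blob), and `kind`.
#' @export
generate_geometry <- function(kind, n, params = list(), seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  with_seed(as.integer(seed), {
    if (kind == "cube") {
      d <- params$d %||% 3L
      list(points = matrix(runif(n * d), n, d), labels = NULL, kind = kind)
    } else if (kind == "ring") {
      r <- params$radius %||% 1
      nsd <- params$noise_sd %||% 0.05
      th <- if (isTRUE(params$equally_spaced))
        seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] else
          sort(runif(n, 0, 2 * pi))
      pts <- cbind(r * cos(th), r * sin(th))
      if (nsd > 0) pts <- pts + matrix(rnorm(2L * n, 0, nsd), n, 2L)
      list(points = pts, labels = NULL, kind = kind)
    } else if (kind == "blobs_cloud") {
      d <- params$dim %||% 6L
      rad <- params$radius %||% 6
      bsd <- params$blob_sd %||% 0.12
      csd <- params$cloud_sd %||% 1.5
      cfrac <- params$cloud_frac %||% 0.10
      n_cloud <- round(n * cfrac)
      n_blob <- n - n_cloud
      lab <- c(rep(0L, n_cloud), rep(1:7, length.out = n_blob))
      centers <- matrix(0, 8L, d)
      if (d >= 6L) {
        ## mutually equidistant blob centers (regular-simplex vertices),
        ## like arms pointing in distinct directions of the embedding space
        V <- diag(7) - 1 / 7
        B <- qr.Q(qr(t(V)))[, 1:6]
        Cc <- V %*% B
        Cc <- Cc / sqrt(sum(Cc[1, ]^2)) * rad
        centers[2:8, 1:6] <- Cc
      } else {
        th <- 2 * pi * (0:6) / 7
        centers[2:8, 1] <- rad * cos(th)
        centers[2:8, 2] <- rad * sin(th)
      }
      sds <- c(csd, rep(bsd, 7L))
      pts <- centers[lab + 1L, , drop = FALSE] +
        matrix(rnorm(n * d, 0, rep(sds[lab + 1L], d)), n, d)
      list(points = pts, labels = lab, kind = kind)
    } else stop("unknown geometry kind: ", kind)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
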