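test_that("bout threshold follows the cue-period lick statistics", {
  licks <- c(0.1, 0.3, 5.1, 5.3, 10.2)
  cues <- c(0, 5, 10)
  p_water <- lick_onset_params(licks, cues, C = 0.1)
  rates <- c(4, 4, 2)                      # licks in first 0.5 s / 0.5
  expect_equal(p_water$mu, mean(rates))
  expect_equal(p_water$sigma, sd(rates))
  expect_equal(p_water$threshold_s, 1 / (mean(rates) + 0.1 * sd(rates)),
               tolerance = 1e-12)
  p_food <- lick_onset_params(licks, cues, C = 0.35)
  expect_equal(p_food$threshold_s, 1 / (mean(rates) + 0.35 * sd(rates)),
               tolerance = 1e-12)
  ## no licking at all: threshold degenerates to infinity
  expect_identical(lick_onset_params(numeric(0), cues)$threshold_s, Inf)
})

test_that("onset detection finds the first fast lick pair in the window", {
  params <- structure(list(mu = 2, sigma = 1, C = 0.1, threshold_s = 0.45),
                      class = "pm_lick_params")
  ## sparse 1 Hz licking then an 8 Hz burst at 2.2 s post cue
  cue <- 100
  licks <- cue + c(0.6, 1.6, 2.2, 2.325, 2.45, 2.575, 2.7)
  expect_equal(detect_lick_onset(licks, cue, params), 2.2, tolerance = 1e-9)
  ## zero licks: no onset
  expect_true(is.na(detect_lick_onset(numeric(0), cue, params)))
  ## sparse-only licking: no onset
  expect_true(is.na(detect_lick_onset(cue + c(0.6, 1.6, 2.6, 3.6), cue,
                                      params)))
  ## translation equivariance
  expect_equal(detect_lick_onset(licks + 55, cue + 55, params),
               detect_lick_onset(licks, cue, params), tolerance = 1e-12)
})

test_that("detected lick onsets track the generator's bout onsets", {
  g <- generate_session(small_session(seed = 31L, n_per_class = 10L))
  licks <- g$session$events$time_s[g$session$events$event == "lick"]
  tr <- g$ground_truth$trials
  params <- lick_onset_params(licks, tr$cue_time_s, C = 0.1)
  ons <- vapply(tr$cue_time_s, function(ct)
    detect_lick_onset(licks, ct, params), numeric(1))
  hit <- tr$class == "reward_hit"
  expect_true(all(!is.na(ons[hit])))
  err <- abs(ons[hit] - g$ground_truth$lick_onsets[hit])
  expect_lt(median(err), 0.2)
  ## correct rejections never lick
  expect_true(all(is.na(ons[tr$class %in% c("aversive_cr", "neutral_cr")])))
})

test_that("cluster onsets are found for the lick-correlated reward cluster", {
  g <- generate_session(small_session(seed = 32L, n_per_class = 12L))
  bs <- preprocess_session(g$session)
  tr <- g$ground_truth$trials
  hit <- tr$class == "reward_hit"
  tm <- build_trial_matrix(gt_labels(g$ground_truth), tr[hit, , drop = FALSE])
  lons <- g$ground_truth$lick_onsets[hit]
  co <- detect_cluster_onset(tm, lons, bin_s = bs$bin_s)
  expect_true(co$cluster %in% g$ground_truth$reward_state_sequence)
  lag <- co$onsets_s - lons
  expect_gt(median(lag, na.rm = TRUE), 0.6)
  expect_lt(median(lag, na.rm = TRUE), 1.4)
  ## onsets ordered like lick onsets
  ok <- !is.na(co$onsets_s)
  expect_gt(cor(co$onsets_s[ok], lons[ok], method = "spearman"), 0.6)
  expect_error(detect_cluster_onset(tm, rep(NA_real_, nrow(tm$sequences))),
               "5 trials")
})

test_that("lick smoothing and similarity match brute-force evaluation", {
  x <- rep(0L, 310); y <- rep(1L, 310)
  sx <- smooth_licks(x); sy <- smooth_licks(y)
  expect_true(all(sx == 0) && all(sy == 1))
  expect_equal(lick_similarity(x, y), 1 / (1e-6 + sqrt(310)),
               tolerance = 1e-12)
  expect_equal(lick_similarity(x, x), 1e6)    # capped maximum
  set.seed(8)
  a <- rbinom(310, 1, 0.2); b <- rbinom(310, 1, 0.2)
  ## brute-force forward window mean
  brute <- vapply(seq_len(310), function(t)
    mean(a[t:min(t + 99, 310)]), numeric(1))
  expect_equal(smooth_licks(a), brute, tolerance = 1e-12)
  expect_equal(lick_similarity(a, b), lick_similarity(b, a),
               tolerance = 1e-12)
})

test_that("pseudo-trials are built from bout onsets with disjoint windows", {
  labels <- rep(c(-1L, 3L), 500)
  ## bouts at 10, 20, 30 s inside a [0, 60) s epoch
  licks <- c(5, 10, 10.2, 10.4, 20, 20.2, 30, 30.15)
  pt <- build_pseudo_trials(licks, c(0, 60), labels, bin_s = 0.5,
                            frame_hz = 31, min_count = 2L)
  expect_equal(pt$onsets_s, c(10, 20, 30), tolerance = 1e-9)
  expect_identical(pt$gap_used_s, 1.0)
  expect_identical(ncol(pt$sequences), 12L)   # 6 s at 0.5-s bins
  ## windows pairwise disjoint
  o <- pt$onsets_s
  expect_true(all(diff(o) >= 6))
  ## dense licking: no 1-s gaps, falls back to 0.5 s
  dense <- seq(5, 50, by = 0.2)
  expect_error(build_pseudo_trials(dense, c(0, 60), labels, 0.5, 31),
               "no pseudo-trial")
  sparse02 <- c(seq(5, 6, 0.2), seq(7.5, 8.5, 0.2), seq(10.5, 11.5, 0.2),
                seq(14, 15, 0.2), seq(17.5, 18.5, 0.2), seq(21, 22, 0.2))
  pt2 <- build_pseudo_trials(sparse02, c(0, 60), labels, 0.5, 31,
                             gap_s = 3, fallback_gap_s = 1, min_count = 5L)
  expect_identical(pt2$gap_used_s, 1.0)       # fallback triggered
})

test_that("rate matching keeps pseudo-trials inside the task band", {
  pt <- structure(list(sequences = matrix(-1L, 4, 12),
                       lick_patterns = matrix(0L, 4, 186),
                       classes = rep("pseudo", 4),
                       cue_bins = 1:4, onsets_s = c(10, 20, 30, 40),
                       lick_rate_first2s = c(6, 6.5, 9.5, 2),
                       gap_used_s = 1),
                  class = c("pm_pseudo_trials", "pm_trial_matrix"))
  task_rates <- c(6, 7, 6.5, 7.5, 6)          # mean 6.6, sd ~0.65
  kept <- rate_matched_selection(pt, task_rates)
  band <- mean(task_rates) + c(-1, 1) * sd(task_rates)
  expect_identical(attr(kept, "kept"),
                   which(pt$lick_rate_first2s >= band[1] &
                           pt$lick_rate_first2s <= band[2]))
  expect_identical(nrow(kept$sequences), length(attr(kept, "kept")))
  expect_warning(rate_matched_selection(pt, c(100, 101, 100)), "band")
})

test_that("free-consumption dynamics differ from rewarded-trial dynamics", {
  g <- generate_session(small_session(seed = 33L, n_per_class = 10L))
  la <- gt_labels(g$ground_truth)
  tr <- g$ground_truth$trials
  ev <- g$session$events
  licks <- ev$time_s[ev$event == "lick"]
  epoch <- c(ev$time_s[ev$event == "epoch_start"],
             ev$time_s[ev$event == "epoch_end"])
  pt <- build_pseudo_trials(licks, epoch, la, bin_s = 15 / 31, frame_hz = 31)
  hit <- tr$class == "reward_hit"
  tm <- build_trial_matrix(la, tr[hit, , drop = FALSE], n_bins = 12L)
  within <- pairwise_trial_similarity(tm$sequences)$pooled
  cross <- as.vector(tcrossprod(
    tm$sequences / sqrt(rowSums(tm$sequences^2)),
    pt$sequences / sqrt(rowSums(pt$sequences^2))))
  expect_gt(mean(within), mean(cross))
})
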