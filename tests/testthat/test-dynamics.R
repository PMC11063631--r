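test_that("trial matrices hold 20-bin label sequences per trial", {
  g <- generate_session(small_session(seed = 15L))
  la <- gt_labels(g$ground_truth)
  tm <- build_trial_matrix(la, g$ground_truth$trials)
  expect_identical(ncol(tm$sequences), 20L)
  expect_identical(nrow(tm$sequences), nrow(g$ground_truth$trials))
  expect_true(all(tm$sequences %in% c(-1L, 1:7)))
  ## a rewarded trial's row equals the ground-truth path
  hit <- which(tm$classes == "reward_hit")[1]
  cb <- tm$cue_bins[hit]
  expect_identical(tm$sequences[hit, ], la[cb:(cb + 19L)])
  ## all-sentinel session
  tm2 <- build_trial_matrix(rep(-1L, 200),
                            data.frame(cue_bin = c(10L, 50L),
                                       class = c("a", "b")))
  expect_true(all(tm2$sequences == -1L))
  ## trials at the session edge are dropped with a warning
  expect_warning(
    tm3 <- build_trial_matrix(la, data.frame(
      cue_bin = c(5L, length(la) - 3L), class = c("a", "b"))),
    "dropped")
  expect_identical(nrow(tm3$sequences), 1L)
})

test_that("cosine trial similarity matches direct evaluation", {
  expect_equal(trial_similarity(c(-1, -1, 2, 2), c(-1, -1, -1, 2)),
               4 / sqrt(70), tolerance = 1e-12)
  expect_equal(trial_similarity(rep(-1, 20), rep(-1, 20)), 1)
  s <- c(-1, 3, 3, 2)
  expect_equal(trial_similarity(s, s), 1, tolerance = 1e-12)
  ps <- pairwise_trial_similarity(rbind(c(-1, 2), c(2, -1), c(-1, 2)))
  expect_identical(length(ps$pooled), 3L)
  expect_equal(ps$matrix, t(ps$matrix), tolerance = 1e-12)
  ps2 <- pairwise_trial_similarity(rbind(c(1, 1), c(1, 1)))
  expect_identical(length(ps2$pooled), 1L)
})

test_that("rewarded trials are more stereotyped than correct rejections", {
  g <- generate_session(small_session(seed = 16L, n_per_class = 12L))
  tm <- build_trial_matrix(gt_labels(g$ground_truth), g$ground_truth$trials)
  sim_within <- function(cl) {
    idx <- tm$classes == cl
    pairwise_trial_similarity(tm$sequences[idx, ])$pooled
  }
  expect_gt(mean(sim_within("reward_hit")), mean(sim_within("aversive_cr")))
})

test_that("transition matrices are row-stochastic with correct structure", {
  ## deterministic cycle 1 -> 2 -> 3 -> 1 embedded in sentinel bins
  cyc <- rep(c(-1L, 1L, 2L, 3L), 50)
  tmx <- transition_matrix(cyc)
  expect_equal(unname(rowSums(tmx$P)), rep(1, 4), tolerance = 1e-9)
  expect_equal(tmx$P["1", "2"], 1)
  expect_equal(tmx$P["2", "3"], 1)
  expect_setequal(tmx$order, c(-1L, 1:3))
  ## zero-occupancy label rejected
  expect_error(transition_matrix(c(-1L, 1L, 3L, -1L, 1L, 3L, 1L, 3L)),
               "zero occupancy")
  ## run boundaries excluded from transition counts
  labs <- c(-1L, 1L, 2L, -1L, 2L, 2L, 1L, -1L, 1L, 2L)
  t_all <- transition_matrix(labs)
  t_run <- transition_matrix(labs, run_bins = rbind(c(1L, 6L), c(6L, 11L)))
  expect_identical(sum(t_run$counts), sum(t_all$counts) - 1L)
})

test_that("label translation recovers a planted permutation", {
  cfg <- small_session(seed = 21L, n_per_class = 40L, n_neurons = 10L,
                       free = FALSE)
  perm <- c(4L, 6L, 1L, 7L, 3L, 2L, 5L)
  pr <- generate_paired_sessions(cfg, perm)
  ta <- transition_matrix(gt_labels(pr$a$ground_truth))
  tb <- transition_matrix(gt_labels(pr$b$ground_truth))
  map <- translate_labels(ta, tb)
  expect_setequal(map, c(-1L, 1:7))            # bijection
  truth <- setNames(c(-1L, 1:7), as.character(c(-1L, perm)))
  expect_identical(map[names(truth)], truth)
  ## dataset vs itself: identity
  self_map <- translate_labels(ta, ta)
  expect_identical(self_map[as.character(ta$order)],
                   setNames(ta$order, as.character(ta$order)))
})

test_that("paired transition matrices agree after applying the permutation", {
  cfg <- small_session(seed = 22L, n_per_class = 40L, n_neurons = 10L,
                       free = FALSE)
  perm <- c(2L, 3L, 4L, 5L, 6L, 7L, 1L)
  pr <- generate_paired_sessions(cfg, perm)
  ta <- transition_matrix(gt_labels(pr$a$ground_truth))
  tb <- transition_matrix(gt_labels(pr$b$ground_truth))
  lev <- as.character(c(-1L, 1:7))
  blev <- as.character(c(-1L, perm))
  expect_lt(max(abs(ta$P[lev, lev] - tb$P[blev, blev])), 0.08)
})

test_that("decoding a session against itself is self-consistent", {
  g <- generate_session(small_session(seed = 23L, n_per_class = 10L))
  tm <- build_trial_matrix(gt_labels(g$ground_truth), g$ground_truth$trials)
  dec <- decode_across(tm, tm, n_perm = 100, seed = 3)
  expect_gte(dec$accuracy[["reward_hit"]],
             max(dec$null_accuracy[, "reward_hit"], na.rm = TRUE))
  expect_true(all(dec$accuracy >= 0 & dec$accuracy <= 1, na.rm = TRUE))
  expect_identical(length(dec$null_overall), 100L)
})

test_that("translation plus decoding is invariant to relabeling", {
  cfg <- small_session(seed = 24L, n_per_class = 10L, free = FALSE)
  pr <- generate_paired_sessions(cfg, c(5L, 3L, 7L, 1L, 6L, 2L, 4L))
  la <- gt_labels(pr$a$ground_truth); lb <- gt_labels(pr$b$ground_truth)
  tma <- build_trial_matrix(la, pr$a$ground_truth$trials)
  tmb <- build_trial_matrix(lb, pr$b$ground_truth$trials)
  map <- translate_labels(transition_matrix(la), transition_matrix(lb))
  d1 <- decode_across(tma, apply_label_mapping(tmb, map), 50, seed = 9)
  ## further permute b's labels; recomputed mapping must undo it
  p2 <- c(3L, 1L, 2L, 6L, 7L, 4L, 5L)
  lb2 <- lb
  lb2[lb != -1L] <- p2[lb[lb != -1L]]
  tmb2 <- build_trial_matrix(lb2, pr$b$ground_truth$trials)
  map2 <- translate_labels(transition_matrix(la), transition_matrix(lb2))
  d2 <- decode_across(tma, apply_label_mapping(tmb2, map2), 50, seed = 9)
  expect_identical(d1$predicted, d2$predicted)
})

test_that("the state axis projects anchors to exactly 1 and 0", {
  set.seed(2)
  z <- matrix(rnorm(30 * 200), 30, 200)
  ax <- state_axis(z, thirsty_bins = 1:40, quenched_bins = 161:200)
  xt <- rowMeans(z[, 1:40]); xq <- rowMeans(z[, 161:200])
  expect_equal(ax$project(xt), 1, tolerance = 1e-12)
  expect_equal(ax$project(xq), 0, tolerance = 1e-12)
  expect_error(state_axis(z, integer(0), 1:5), "anchor")
})

test_that("cluster-sequence decoding beats amplitude baselines on identity-coded data", {
  cfg <- small_session(seed = 25L, n_per_class = 12L, n_neurons = 30L,
                       free = FALSE, drift_gain = 0)
  pr <- generate_paired_sessions(cfg, c(2L, 1L, 3L, 4L, 5L, 6L, 7L))
  bsa <- preprocess_session(pr$a$session)
  bsb <- preprocess_session(pr$b$session)
  la <- gt_labels(pr$a$ground_truth); lb <- gt_labels(pr$b$ground_truth)
  tma <- build_trial_matrix(la, pr$a$ground_truth$trials)
  tmb <- build_trial_matrix(lb, pr$b$ground_truth$trials)
  map <- translate_labels(transition_matrix(la), transition_matrix(lb))
  dec_cl <- decode_across(tma, apply_label_mapping(tmb, map), 50, seed = 4)
  dec_mean <- baseline_decoders(bsa$z, bsa$trials, bsb$z, bsb$trials,
                                mode = "mean_activity", n_perm = 50, seed = 4)
  expect_gte(dec_cl$accuracy[["reward_hit"]],
             dec_mean$accuracy[["reward_hit"]])
  ## zero matrix rejected
  expect_error(trial_feature_matrix(matrix(0, 3, 100),
                                    data.frame(cue_bin = 10L, class = "x"),
                                    "mean_activity"),
               "zero-norm")
})
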