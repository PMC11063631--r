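test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_neurons = 0), "n_neurons")
  expect_error(sim_config(n_trials_per_class = 0), "n_trials_per_class")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(reward_state_sequence = c(1L, 1L)),
               "reward_state_sequence")
  expect_error(sim_config(reward_state_sequence = 1L),
               "reward_state_sequence")
})

test_that("a fixed seed reproduces the session exactly", {
  g1 <- generate_session(small_session(seed = 7L))
  g2 <- generate_session(small_session(seed = 7L))
  expect_identical(g1$session$dff, g2$session$dff)
  expect_identical(g1$session$events, g2$session$events)
  expect_identical(g1$ground_truth$state_sequence,
                   g2$ground_truth$state_sequence)
})

test_that("noiseless emission reproduces the loading-matrix columns", {
  cfg <- small_session(seed = 3L, n_per_class = 2L, n_neurons = 2L,
                       free = FALSE, noise_sd = 0, drift_gain = 0,
                       central_wander_z = 0)
  g <- generate_session(cfg)
  binned <- bin_traces(g$session$dff, cfg$frames_per_bin)
  st <- g$ground_truth$state_sequence
  expect_equal(binned, g$ground_truth$loading_matrix[, st + 1L],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("session structure matches the task design", {
  g <- generate_session(small_session(seed = 2L))
  gt <- g$ground_truth
  expect_setequal(unique(gt$trials$class),
                  c("reward_hit", "reward_miss", "aversive_fa",
                    "aversive_cr", "neutral_fa", "neutral_cr"))
  ## state sequence covers every bin of the emitted frames
  expect_identical(length(gt$state_sequence) * g$session$frames_per_bin,
                   ncol(g$session$dff))
  ## rewarded trials traverse central state then the reward sequence
  hit <- which(gt$trials$class == "reward_hit")
  for (i in hit[1:3]) {
    cb <- gt$trials$cue_bin[i]
    seg <- gt$state_sequence[cb:(cb + 19L)]
    expect_true(seg[1] == 0L)
    expect_true(all(gt$reward_state_sequence %in% seg))
  }
  ## events populated
  ev <- g$session$events
  expect_true(all(c("cue_on", "lick", "reward") %in% ev$event))
  expect_true(all(ev$time_s >= 0 &
                    ev$time_s <= ncol(g$session$dff) / g$session$frame_hz))
})

test_that("latent sequence onset follows lick onset on every rewarded trial", {
  g <- generate_session(small_session(seed = 5L, n_per_class = 10L))
  gt <- g$ground_truth
  hit <- gt$trials$class == "reward_hit"
  lag <- gt$cluster_onsets[hit] - gt$lick_onsets[hit]
  expect_true(all(!is.na(lag)))
  expect_identical(mean(lag > 0), 1)      # every latent onset after lick
  expect_gt(mean(lag), 0.5)               # centered near the 1-s default
  expect_lt(mean(lag), 1.5)
})

test_that("paired sessions are related by the recorded permutation", {
  cfg <- small_session(seed = 9L, free = FALSE)
  perm <- c(3L, 1L, 4L, 7L, 2L, 6L, 5L)
  pr <- generate_paired_sessions(cfg, perm, same_noise = TRUE)
  full <- pr$b$ground_truth$label_permutation
  expect_identical(full[1], 0L)                       # central state fixed
  expect_setequal(full[-1], 1:7)
  ## with frozen noise, state-s bins of A are state-perm[s] bins of B
  expect_identical(pr$b$ground_truth$state_sequence,
                   full[pr$a$ground_truth$state_sequence + 1L])
  expect_identical(pr$a$session$dff, pr$b$session$dff)
  ## transition structures are permutation-equivalent
  ta <- table(head(pr$a$ground_truth$state_sequence, -1),
              tail(pr$a$ground_truth$state_sequence, -1))
  tb <- table(head(pr$b$ground_truth$state_sequence, -1),
              tail(pr$b$ground_truth$state_sequence, -1))
  expect_identical(unname(ta), unname(tb[as.character(full),
                                         as.character(full)]))
  expect_error(generate_paired_sessions(cfg, c(1L, 1L, 3L, 4L, 5L, 6L, 7L)),
               "bijection")
})

test_that("geometric fixtures have the advertised structure", {
  cube1 <- generate_geometry("cube", 50, list(d = 1), seed = 1)
  expect_identical(ncol(cube1$points), 1L)            # colinear by construction
  ring <- generate_geometry("ring", 300, list(noise_sd = 0), seed = 2)
  D <- as.matrix(dist(ring$points))
  expect_lt(abs(max(D) - 2), 0.01)                    # max distance ~ diameter
  bc <- generate_geometry("blobs_cloud", 400, seed = 3)
  expect_identical(sort(unique(bc$labels)), 0:7)      # 8 groups with labels
  expect_identical(length(bc$labels), 400L)
  expect_error(generate_geometry("torus", 100), "unknown")
  expect_error(generate_geometry("cube", 5), "n must be")
})

test_that("sessions round-trip through the plain-text serialization", {
  g <- generate_session(small_session(seed = 4L, n_per_class = 2L,
                                      n_neurons = 5L, free = FALSE))
  dir <- file.path(tempdir(), "pm_session_rt")
  write_session(g$session, dir)
  s2 <- read_session(dir)
  expect_equal(unname(s2$dff), unname(g$session$dff), tolerance = 1e-9)
  expect_identical(s2$frames_per_bin, g$session$frames_per_bin)
  expect_equal(s2$events$time_s, g$session$events$time_s, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
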