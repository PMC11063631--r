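test_that("trial-outcome labels mark the 3-6 s post-cue window", {
  g <- generate_session(small_session(seed = 13L))
  bs <- preprocess_session(g$session)
  bl <- build_labels(bs, "reward_hit")
  expect_setequal(unique(bl$labels), c(0L, 1L))
  hits <- bs$trials[bs$trials$class == "reward_hit", ]
  cb <- hits$cue_bin[1]
  expect_identical(bl$labels[(cb + 6):(cb + 11)], rep(1L, 6))
  expect_identical(bl$labels[cb:(cb + 5)], rep(0L, 6))
  expect_identical(bl$labels[cb + 12], 0L)
  expect_true(all(bl$valid_mask))
  expect_error(build_labels(bs, "no_such_var"), "unknown")
})

test_that("continuous variables get octile labels on quiet ITI bins", {
  g <- generate_session(small_session(seed = 14L, n_per_class = 10L))
  bs <- preprocess_session(g$session)
  bl <- build_labels(bs, "pupil")
  expect_setequal(unique(bl$labels[bl$valid_mask]), 1:8)
  expect_true(all(is.na(bl$labels[!bl$valid_mask])))
  ## equal-count binning
  tab <- table(bl$labels[bl$valid_mask])
  expect_lte(diff(range(tab)), max(2, 0.2 * mean(tab)))
  ## eight levels for cumulative rewards
  bl2 <- build_labels(bs, "cum_reward")
  expect_identical(length(unique(bl2$labels[bl2$valid_mask])), 8L)
  ## constant covariate: octiles undefined
  bs$pupil[] <- 1
  expect_error(build_labels(bs, "pupil"), "degenerate")
})

test_that("mutual information matches a direct summation oracle", {
  tab <- matrix(c(30, 10, 10, 30), 2)
  cl <- rep(rep(c(1L, 2L), c(40, 40)), 1)
  beh <- c(rep(1L, 30), rep(2L, 10), rep(1L, 10), rep(2L, 30))
  bl <- structure(list(variable = "x", labels = beh,
                       valid_mask = rep(TRUE, 80)),
                  class = "pm_behavior_labels")
  r <- mutual_information(cl, bl)
  expect_equal(r$mi, mi_brute(tab), tolerance = 1e-12)
  ## symmetry
  bl2 <- structure(list(variable = "x", labels = cl,
                        valid_mask = rep(TRUE, 80)),
                   class = "pm_behavior_labels")
  expect_equal(mutual_information(beh, bl2)$mi, r$mi, tolerance = 1e-12)
  ## deterministic function of cluster: MI equals behavior entropy
  cl3 <- rep(1:4, each = 25)
  beh3 <- c(1L, 2L, 1L, 2L)[cl3]
  bl3 <- structure(list(variable = "x", labels = beh3,
                        valid_mask = rep(TRUE, 100)),
                   class = "pm_behavior_labels")
  expect_equal(mutual_information(cl3, bl3)$mi, log(2), tolerance = 1e-12)
  ## MI bounded by marginal entropies
  ent <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  expect_lte(r$mi, min(ent(cl), ent(beh)) + 1e-12)
})

test_that("MI vanishes under independence", {
  set.seed(6)
  n <- 2000
  cl <- sample(c(-1L, 1:7), n, TRUE)
  mis <- replicate(30, {
    bl <- structure(list(variable = "x", labels = sample(1:8, n, TRUE),
                         valid_mask = rep(TRUE, n)),
                    class = "pm_behavior_labels")
    mutual_information(cl, bl)$mi
  })
  expect_lt(mean(mis), 3 / n * 8)   # plug-in bias scale, well below signal
})

test_that("the shuffle test detects coupled covariates and stays calibrated", {
  g <- generate_session(small_session(seed = 4L, n_per_class = 20L,
                                      n_neurons = 20L, free = FALSE))
  bs <- preprocess_session(g$session)
  la <- gt_labels(g$ground_truth)
  pupil <- build_labels(bs, "pupil")
  r <- mi_shuffle_test(la, pupil, n_shuffle = 300, seed = 2)
  expect_lt(r$p, 0.05)              # pupil is coupled to the latent drift
  expect_identical(length(r$null), 300L)
  expect_gte(r$p, 0)
  expect_error(mi_shuffle_test(la, pupil, n_shuffle = 10), "100")
})
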