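# Feature encodings, nearest-mean cross-validation, tasks, permutation
# statistics and temporal decoding.

test_that("binary encoding thresholds at blank mean + k blank SD with strict inequality", {
  # 2 cells x 8 trials (4 blank); cell 1 blank counts 0,1,2,1 (mean 1, sd .816)
  nT <- 8
  counts <- array(0, dim = c(nT, 2, 2))
  counts[, 1, 1] <- c(0, 1, 2, 1, 2, 1, 3, 1)   # bin 1
  counts[, 2, 1] <- c(1, 1, 1, 1, 1, 1, 1, 1)
  trials <- data.frame(trial_id = paste0("t", 1:nT),
                       odorant = c(rep("mineral_oil", 4), rep("odA", 4)),
                       concentration = c(rep(0, 4), rep(3e-3, 4)),
                       inhalation_onset_s = seq_len(nT),
                       odor_onset_s = seq_len(nT) - 0.1,
                       is_blank = c(rep(TRUE, 4), rep(FALSE, 4)))
  dimnames(counts) <- list(trials$trial_id, c("c1", "c2"), NULL)
  attr(counts, "trials") <- trials
  attr(counts, "bin_width") <- 0.24
  attr(counts, "window") <- c(0, 0.48)
  f <- encode_features(counts, "binary")
  # threshold for cell 1 is 1.816: count 2 -> 1, counts 1 -> 0
  expect_equal(unname(f$matrix[5:8, 1]), c(1, 0, 1, 0))
  # cell 2: blank sd 0, threshold = mean = 1, count 1 is NOT above threshold
  expect_equal(unname(f$matrix[5:8, 2]), c(0, 0, 0, 0))

  # summed encoding equals the bin-sum of the binned encoding exactly
  fs <- encode_features(counts, "summed")
  fb <- encode_features(counts, "binned")
  expect_equal(unname(fs$matrix),
               unname(fb$matrix[, c(1, 3)] + fb$matrix[, c(2, 4)]))
})

test_that("euclidean nearest-mean cross-validation matches hand-enumerated and brute-force results", {
  # 1-D worked example: A = {0, 0, 10}, B = {8, 9, 9} -> 5/6
  x <- matrix(c(0, 0, 10, 8, 9, 9), ncol = 1)
  y <- rep(c("A", "B"), each = 3)
  expect_equal(euclidean_loo(x, y)$accuracy, 5 / 6)
  expect_equal(euclidean_loo(x, y, folds = "loo")$accuracy, 5 / 6)

  # widely separated clusters classify perfectly
  set.seed(8)
  x2 <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 50), 10))
  y2 <- rep(c("A", "B"), each = 10)
  expect_equal(euclidean_loo(x2, y2)$accuracy, 1)

  # oracle equivalence on random instances, both fold schemes
  for (i in 1:12) {
    nc <- sample(2:4, 1)
    ntr <- sample(3:7, 1)
    xx <- matrix(rnorm(nc * ntr * 3, sd = 3), nc * ntr, 3)
    yy <- rep(letters[1:nc], each = ntr)
    expect_equal(euclidean_loo(xx, yy, "balanced")$accuracy,
                 brute_force_cv(xx, yy, "balanced"))
    expect_equal(euclidean_loo(xx, yy, "loo")$accuracy,
                 brute_force_cv(xx, yy, "loo"))
  }
  expect_error(euclidean_loo(matrix(1:2, 2), c("a", "b")), ">= 2 trials")
})

test_that("run_task is deterministic under a fixed seed and bounded in [0,1]", {
  f <- encode_features(fx_default_binned(), "summed")
  r1 <- run_task(f, "odorant", sizes = c(20, 60), n_permutations = 8, seed = 5)
  r2 <- run_task(f, "odorant", sizes = c(20, 60), n_permutations = 8, seed = 5)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_true(all(r1$accuracy$accuracy >= 0 & r1$accuracy$accuracy <= 1))
  expect_error(run_task(f, "odorant", sizes = 10000), "exceeds")
})

test_that("mean accuracy is non-decreasing with pseudopopulation size on signal-bearing data", {
  f <- encode_features(fx_default_binned(), "binned")
  r <- run_task(f, "odorant", sizes = c(5, 25, 100), n_permutations = 25,
                seed = 2)
  acc <- r$summary$mean_accuracy[order(r$summary$size)]
  expect_true(all(diff(acc) > -0.02))
  expect_gt(acc[3], acc[1])
})

test_that("small random pseudopopulations are almost always above chance (dense code)", {
  f <- encode_features(fx_default_binned(), "binary")
  r <- run_task(f, "odorant", sizes = 25, n_permutations = 100, seed = 3)
  expect_gte(mean(r$accuracy$accuracy > r$chance), 0.95)
})

test_that("expanding window at full width reproduces the static binned accuracy exactly", {
  bn <- fx_default_binned()
  f <- encode_features(bn, "binned")
  static <- run_task(f, "concentration", n_permutations = 1, seed = 1)
  tc <- temporal_decoding(bn, "concentration", "expanding")
  expect_equal(tc$accuracy[nrow(tc)], static$summary$mean_accuracy)
})

test_that("no window before the earliest response latency decodes above chance", {
  cfg <- synth_config(n_cells_pcx = 150, n_cells_ob = 0,
                      early_phase_pcx = c(mean = 0.22, sd = 0.01),
                      late_phase_means_pcx = c(0.33, 0.31, 0.29, 0.27),
                      late_tail = c(mean = 0.42, sd = 0.03, weight = 0.15),
                      suppression_onset = 0.2, seed = 13)
  ds <- generate_dataset(cfg)
  bn <- binned_count_array(ds, region = "PCx")
  sl <- temporal_decoding(bn, "odorant", "sliding")
  # all responses start after 180 ms; the first four 30 ms windows are silent
  expect_true(all(abs(sl$accuracy[1:4] - 1 / 6) < 0.12))
  expect_gt(max(sl$accuracy), 0.7)
})

test_that("paired encoding comparisons detect dominance and report centered bands for identical inputs", {
  f <- encode_features(fx_default_binned(), "summed")
  a <- run_task(f, "odorant", sizes = 40, n_permutations = 30, seed = 9)
  cmp0 <- compare_encodings(a, a)
  expect_equal(cmp0$mean_diff, 0)
  expect_false(cmp0$significant)

  # dominance: destroying the temporal structure of the binned code cannot help
  fb <- encode_features(fx_default_binned(), "binned")
  b <- run_task(fb, "concentration", sizes = 40, n_permutations = 30, seed = 9)
  s <- run_task(f, "concentration", sizes = 40, n_permutations = 30, seed = 9)
  cmp <- compare_encodings(b, s)
  expect_gt(cmp$mean_diff, 0)

  bad <- run_task(f, "odorant", sizes = 40, n_permutations = 30, seed = 10)
  expect_error(compare_encodings(a, bad), "paired")
})

test_that("the linear-SVM robustness check agrees with the nearest-mean rule on separable data", {
  skip_if_not_installed("e1071")
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 6), 10))
  y <- rep(c("A", "B"), each = 10)
  expect_equal(svm_loo(x, y)$accuracy, 1)
  expect_equal(euclidean_loo(x, y)$accuracy, 1)
})

test_that("generalization panel structure: 12 stimuli, 11 training, 3 sharing the held-out identity", {
  panel <- generalization_panel(fx_default_dataset()$trials)
  expect_equal(nrow(panel$stimuli), 12)
  expect_equal(nrow(panel$held_out), 8)
  expect_true(all(panel$held_out$n_train == 11))
  expect_true(all(panel$held_out$n_shared_identity == 3))
  expect_equal(panel$chance_generalization, 3 / 11)
})
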