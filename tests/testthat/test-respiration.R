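# Breath detection, sniff-phase assignment and phase histograms.

test_that("detect_breaths finds sine-wave inhalation onsets at kT", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  trace <- list(samples = -sin(2 * pi * t / 0.3), sampling_rate = fs)
  ev <- detect_breaths(trace)
  expected <- seq(0, 2.7, by = 0.3)
  expect_equal(length(ev$inhalation_onsets), length(expected))
  expect_true(all(abs(ev$inhalation_onsets - expected) <= 1 / fs))
  # exhalation onsets midway through each cycle
  expect_true(all(abs(ev$exhalation_onsets -
                        (expected[seq_along(ev$exhalation_onsets)] + 0.15)) <=
                    1.5 / fs))
})

test_that("local detrending removes linear drift without moving onsets", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  clean <- -sin(2 * pi * t / 0.3)
  drifted <- clean + 0.5 * t
  ev0 <- detect_breaths(list(samples = clean, sampling_rate = fs))
  ev1 <- detect_breaths(list(samples = drifted, sampling_rate = fs))
  common <- intersect(round(ev0$inhalation_onsets, 1),
                      round(ev1$inhalation_onsets, 1))
  expect_gte(length(common), 10)
  m0 <- ev0$inhalation_onsets[round(ev0$inhalation_onsets, 1) %in% common]
  m1 <- ev1$inhalation_onsets[round(ev1$inhalation_onsets, 1) %in% common]
  expect_true(all(abs(m0 - m1) <= 1 / fs))
})

test_that("degenerate traces yield empty breath events", {
  ev <- detect_breaths(list(samples = rep(0, 5000), sampling_rate = 2000))
  expect_length(ev$inhalation_onsets, 0)
  ev2 <- detect_breaths(list(samples = rep(3.2, 5000), sampling_rate = 2000))
  expect_length(ev2$inhalation_onsets, 0)
  expect_error(detect_breaths(list(samples = rnorm(10), sampling_rate = 2000)),
               "shorter")
})

test_that("detection recovers >= 95% of ground-truth onsets within 10 ms on noisy jittered traces", {
  tr <- generate_respiration_trace(30, breath_period = 0.4, period_sd = 0.03,
                                   amplitude_sd = 0.10, noise_sd = 0.02,
                                   seed = 21)
  ev <- detect_breaths(tr)
  expect_false(is.unsorted(ev$inhalation_onsets, strictly = TRUE))
  # interior ground-truth onsets (detrending handles edges less well)
  truth <- tr$inhalation_onsets
  truth <- truth[truth > 1 & truth < 29]
  err <- sapply(truth, function(x) min(abs(ev$inhalation_onsets - x)))
  expect_gte(mean(err <= 0.010), 0.95)
  # alternation: every exhalation onset between consecutive inhalations
  idx <- findInterval(ev$exhalation_onsets, ev$inhalation_onsets)
  expect_true(all(ev$exhalation_onsets > ev$inhalation_onsets[idx]))
  nxt <- c(ev$inhalation_onsets, Inf)[idx + 1]
  expect_true(all(ev$exhalation_onsets < nxt))
})

test_that("spike phases interpolate 0 -> pi across inhalation and pi -> 2pi across exhalation", {
  ev <- breath_events(c(0, 1, 2), c(0.4, 1.4))
  expect_equal(spike_phase(0, ev), 0)
  expect_equal(spike_phase(0.4, ev), pi)
  expect_equal(spike_phase(0.2, ev), pi / 2)
  expect_equal(spike_phase(0.7, ev), pi + pi / 2)
  # monotone within a breath
  tt <- seq(0, 0.999, by = 0.01)
  expect_false(is.unsorted(spike_phase(tt, ev)))
  # outside coverage -> NA
  expect_true(is.na(spike_phase(2.5, ev)))
  expect_true(is.na(spike_phase(-0.1, ev)))
})

test_that("phase histograms normalize, localize point masses and recover a von Mises mode", {
  set.seed(4)
  h <- phase_histogram(runif(20000, 0, 2 * pi))
  expect_equal(nrow(h), 36)
  expect_equal(sum(h$proportion), 1)
  expect_true(all(abs(h$proportion - 1 / 36) < 4 * sqrt((1 / 36) / 20000)))

  h2 <- phase_histogram(rep(pi, 50))
  expect_equal(sum(h2$proportion > 0), 1)
  peak_bin <- which.max(h2$proportion)
  expect_true(h2$phase[peak_bin] - pi / 36 <= pi && pi <= h2$phase[peak_bin] + pi / 36)

  # von Mises sample, kappa = 2, mu = pi/2, via rejection sampling
  vm <- c()
  while (length(vm) < 5000) {
    cand <- runif(10000, 0, 2 * pi)
    keep <- runif(10000) < exp(2 * (cos(cand - pi / 2) - 1))
    vm <- c(vm, cand[keep])
  }
  h3 <- phase_histogram(vm[1:5000])
  pk <- h3$phase[which.max(h3$proportion)]
  expect_lt(abs(pk - pi / 2), 2 * pi / 36 + 1e-9)

  expect_equal(sum(phase_histogram(numeric(0))$proportion), 0)
  expect_error(phase_histogram(1, bin_width_deg = 7), "divide")
})
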