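# Synthetic generator: determinism, structural invariants, calibration of the
# generated statistics against the configured targets.

test_that("identical config and seed give a bit-identical dataset", {
  cfg <- synth_config(n_cells_pcx = 30, n_cells_ob = 10, seed = 3,
                      n_trials_per_stimulus = 4)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$ground_truth, d2$ground_truth)
})

test_that("generated spike times and trials satisfy the basic invariants", {
  ds <- fx_small_dataset()
  expect_true(all(is.finite(ds$spikes$time_s)))
  expect_true(all(ds$spikes$time_s >= 0))
  expect_true(all(is.finite(ds$trials$inhalation_onset_s)))
  expect_true(all(ds$trials$odor_onset_s <= ds$trials$inhalation_onset_s))
  # per-unit spike times sorted
  expect_false(is.unsorted(ds$spikes$time_s[ds$spikes$unit_id ==
                                              ds$spikes$unit_id[1]]))
  # the panel: 6 odorants, two with 4 concentrations, plus one blank stimulus
  panel <- stimulus_panel(ds$config)
  expect_equal(sum(!panel$is_blank), 12)
  expect_equal(sum(panel$is_blank), 1)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synth_config(frac_activated = 1.2), "fractions")
  expect_error(synth_config(frac_activated = 0.5, frac_suppressed = 0.6),
               "> 1")
  expect_error(synth_config(concentrations = c(1e-3, 1e-3, 3e-3, 1e-2)),
               "increasing")
  expect_error(synth_config(late_phase_means_pcx = c(0.1, 0.12, 0.14, 0.16)),
               "decrease")
  expect_silent(synth_config(late_phase_means_pcx = c(0.1, 0.12, 0.14, 0.16),
                             require_monotone_late = FALSE))
  expect_error(synth_config(late_phase_means_pcx = c(0.6, 0.5, 0.4, 0.3) ,
                            require_monotone_late = FALSE), "inside")
  expect_error(synth_config(response_duration_sd = -0.01), "duration")
})

test_that("ground-truth class fractions match the config within 3 binomial SD", {
  ds <- fx_default_dataset()
  cfg <- ds$config
  gt <- ds$ground_truth$pairs
  units <- ds$units
  targets <- list(
    PCx = c(activated = cfg$frac_activated, suppressed = cfg$frac_suppressed),
    OB = cfg$ob_response_fractions)
  for (rg in c("PCx", "OB")) {
    n <- sum(units$region == rg)
    in_rg <- gt$unit_id %in% units$unit_id[units$region == rg]
    odors <- unique(gt$odorant)
    for (pol in c("activated", "suppressed")) {
      p <- targets[[rg]][[pol]]
      frac <- sapply(odors, function(od)
        sum(in_rg & gt$odorant == od & gt$polarity == pol) / n)
      tol <- 3 * sqrt(p * (1 - p) / n)
      expect_true(all(abs(frac - p) <= tol),
                  label = sprintf("%s %s fractions within 3 binomial SD", rg, pol))
    }
  }
})

test_that("spontaneous rates are log-normal with the configured mean", {
  ds <- fx_default_dataset()
  est <- spontaneous_rates(ds)
  expect_equal(mean(est$spont_rate_hz), 3.09, tolerance = 0.20)
  # measured rates track the generating rates cell by cell
  truth <- ds$units$spont_rate_hz[match(est$unit_id, ds$units$unit_id)]
  expect_gt(cor(est$spont_rate_hz, truth), 0.95)
})

test_that("a null config produces no responsive pairs; frac_mixed = 0 produces no mixed cells", {
  ds0 <- fx_null_dataset()
  expect_equal(nrow(ds0$ground_truth$pairs), 0)
  cfg <- synth_config(n_cells_pcx = 150, n_cells_ob = 0, frac_mixed = 0,
                      seed = 5)
  ds <- generate_dataset(cfg)
  gt <- ds$ground_truth$pairs
  pos <- tapply(gt$polarity == "activated", gt$unit_id, any)
  neg <- tapply(gt$polarity == "suppressed", gt$unit_id, any)
  expect_false(any(pos & neg))
  expect_false(any(ds$units$class == "mixed"))
})

test_that("pooled late-component ground-truth latencies match the configured means", {
  ds <- fx_default_dataset()
  cfg <- ds$config
  gt <- ds$ground_truth
  late_pairs <- gt$pairs[gt$pairs$component %in% "late", ]
  pcx <- late_pairs$unit_id %in% ds$units$unit_id[ds$units$region == "PCx"]
  key <- paste(late_pairs$unit_id[pcx], late_pairs$odorant[pcx])
  lat <- gt$latencies[paste(gt$latencies$unit_id, gt$latencies$odorant) %in% key, ]
  for (ci in seq_along(cfg$concentrations)) {
    x <- lat$latency_s[abs(lat$concentration - cfg$concentrations[ci]) < 1e-12]
    sem <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$late_phase_means_pcx[ci]), 2 * sem + 1e-3)
  }
})

test_that("latency mixture sampler matches its stated parameters", {
  cfg <- fx_default_config()
  x <- sample_peak_latencies(20000, cfg, "PCx", 3e-3, seed = 11)
  expect_true(all(x >= 0 & x <= 0.5))
  par <- latency_mixture_params(cfg, "PCx", 3e-3)
  comp <- attr(x, "component")
  expect_equal(as.numeric(table(comp) / length(x)), par$p, tolerance = 0.03)
  expect_equal(mean(x[comp == 2]), par$mu[2], tolerance = 0.01)
})

test_that("synthetic respiration traces carry their ground-truth onsets", {
  # constant-period pure sine: inhalation onsets at exact multiples of T
  tr <- generate_respiration_trace(3, breath_period = 0.3, seed = 1)
  expect_equal(tr$inhalation_onsets, seq(0, 2.7, by = 0.3), tolerance = 1e-9)
  expect_equal(tr$exhalation_onsets - tr$inhalation_onsets[
    seq_along(tr$exhalation_onsets)], rep(0.15, length(tr$exhalation_onsets)),
    tolerance = 1e-9)
  expect_error(generate_respiration_trace(0), "duration")
})
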