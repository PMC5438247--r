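# odorcode

Analysis toolkit for population spike-train recordings from the olfactory
system, built around one question: how do neural populations represent odor
**identity** and odor **intensity** without the two interfering?

The package is aimed at systems neuroscientists with extracellular recordings
(spike times per unit, a trial table with stimulus and inhalation-onset times,
optionally a raw respiration trace). It implements, as tested and reusable
functions:

* **Respiration alignment** — Savitzky-Golay smoothing + local detrending of
  an airflow trace, inhalation/exhalation onset detection at zero crossings
  around large negative peaks, sniff-phase assignment of spikes, and phase
  histograms.
* **Response characterization** — 10 ms-kernel firing-rate estimates (KDF),
  peak latency (undefined at window edges), response duration at 25/50% of
  peak, and the auROC response index `2·auROC − 1` with rank-sum significance
  against mineral-oil blank trials; polarity classes
  (activated-only / suppressed-only / mixed / unresponsive); identity-shuffle
  nulls for tuning breadth; lifetime and population sparseness
  `S = (1 − (Σr_i/n)² / (Σr_i²/n)) / (1 − 1/n)`.
* **Population geometry** — first-sniff population count vectors and
  trial-pair Spearman correlations by stimulus condition.
* **Decoding** — three feature encodings of the 480 ms response (binary
  membership, summed counts, sixteen 30 ms bins), a Euclidean nearest-mean
  classifier with size-matched cross-validation folds, three tasks (6-way
  odorant, 4-way concentration, identity generalization across held-out
  concentrations with chance 3/11), pseudopopulation permutation statistics,
  paired encoding comparisons, and expanding/sliding-window temporal
  decoding.
* **Latency mixture models** — maximum-likelihood mixtures of Gaussians
  truncated to [0, 0.5] s fitted by a monotone EM, BIC component selection,
  1000-resample bootstrap confidence intervals, and constrained refits that
  freeze the mixing proportions and the slow component.
* **Concentration–latency slopes** — OLS slopes of population mean latency
  (first spike or PSTH peak) on log10 concentration, compared between
  olfactory bulb and piriform cortex.
* **Synthetic data** — `generate_dataset()` simulates populations with
  log-normal spontaneous rates (mean ≈ 3.09 Hz), 6.7%/13.3% activated/
  suppressed cells per odor in largely disjoint classes, ~43 ms-wide
  responses, and a three-component latency structure whose late component
  advances from ~206 ms to ~136 ms (cortex) across a 1.5-decade concentration
  range — ground truth for every stage.

## Worked example

```r
library(odorcode)

cfg <- synth_config(seed = 1)          # full study conditions: 459 PCx cells
ds  <- generate_dataset(cfg)
ds
#> <odor_dataset> 585 units (OB: 126, PCx: 459), 130 trials, 538432 spikes

# how strongly does each encoding decode identity vs concentration?
# (200 random 200-cell pseudopopulations per point, the standard protocol)
bn <- binned_count_array(ds, region = "PCx")
for (scheme in c("binary", "summed", "binned")) {
  f <- encode_features(bn, scheme)
  od <- run_task(f, "odorant", sizes = 200, n_permutations = 200, seed = 1)
  cc <- run_task(f, "concentration", sizes = 200, n_permutations = 200, seed = 1)
  cat(sprintf("%-7s odorant %.2f  concentration %.2f\n", scheme,
              od$summary$mean_accuracy, cc$summary$mean_accuracy))
}
#> binary  odorant 0.98  concentration 0.26
#> summed  odorant 1.00  concentration 0.28
#> binned  odorant 1.00  concentration 0.36
```

All three encodings identify the odorant essentially perfectly — identity
lives in *which* cells respond — while concentration is decoded meaningfully
above its 0.25 chance level only by the temporally binned encoding: intensity
lives in *when* cells respond. The latency model makes the timing code
explicit:

```r
x <- sample_peak_latencies(400, cfg, "PCx", 3e-3, seed = 2)
fit <- select_k_by_bic(x, 1:5, seed = 3)
fit$fits[[fit$best_k]]
#> <mixture_fit> k=3 n=400 logL=499.70 BIC=-951.46 converged=TRUE
#>      p mu_ms sigma_ms
#>  0.518  80.7     22.7
#>  0.317 163.6     36.2
#>  0.165 359.3     52.4
```

Three latency components: an early concentration-invariant phase (~80 ms), a
late phase (~164 ms at 0.3% v/v) that advances with concentration (fitted
means move from ~205 ms at 0.03% to ~135 ms at 1% v/v), and a slow tail.
`bootstrap_cis()` and `constrained_two_phase_fit()` quantify the uncertainty
of the component means across concentrations.

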