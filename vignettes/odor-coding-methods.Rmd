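---
title: "Methods: population codes for odor identity and intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population codes for odor identity and intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(odorcode)
```

`odorcode` implements a complete analysis chain for asking how populations of
olfactory neurons represent what an odor is (identity) and how strong it is
(intensity), together with a calibrated synthetic spike-train generator that
provides ground truth for every stage. This vignette explains the models and
procedures, the parameters that matter, the numerical choices, and what the
synthetic experiments do and do not establish.

## The scientific question

Piriform cortex receives olfactory bulb input and must represent odor identity
robustly across concentrations while still signalling concentration itself.
The working hypothesis implemented here is a dissociation:

* **identity** is carried by *which* cells respond — ensemble membership — so
  that binary, rate and temporal readouts of the population all decode odorant
  identity equally well, and identity generalizes across concentrations;
* **intensity** is carried by *when* cells respond: an early response
  component is concentration-invariant while a later component advances
  systematically at higher concentrations, so only readouts that preserve
  coarse spike timing can decode concentration.

Every analysis is aligned to the respiration cycle: time zero of a trial is
the first inhalation onset after odor delivery, and the canonical counting
window is the first full respiration cycle ("first sniff").

## The synthetic generator

`synth_config()` + `generate_dataset()` simulate spike trains for a cortical
(PCx) and a bulbar (OB) population responding to a 12-stimulus panel — six
odorants at a nominal 0.3% v/v dilution, two of them also at 0.03%, 0.1% and
1% (0.5 log10 steps) — plus a mineral-oil blank, 10 trials per stimulus.

Generator structure, with the statistical targets the defaults are calibrated
to:

* **Spontaneous activity**: each cell fires as an inhomogeneous Poisson
  process at a log-normal rate (meanlog `log(1.68)`, sdlog 1.10, giving a
  1.68 Hz median and 3.09 Hz arithmetic mean) with a weak sinusoidal
  sniff-phase preference (depth 0.1, preferred phase uniform), so population
  spiking is nearly decoupled from respiration.
* **Ensembles**: per odor, 6.7% of cells are activated and 13.3% suppressed.
  Cells belong to largely disjoint activated-only / suppressed-only classes;
  4% are mixed-polarity. Suppressed-class cells are drawn preferentially from
  high-rate cells (suppression of a near-silent cell is neither biologically
  meaningful nor statistically detectable); this matches the observation that
  suppressed cells have roughly 1.7-fold higher spontaneous rates.
* **Activated responses**: a Gaussian firing-rate transient whose SD
  (18.3 ms) yields a ~43 ms full width at half maximum. Peak amplitudes are
  log-normal (median 45 Hz, sdlog 0.35). The amplitude default was set by an
  a-priori power calculation — with 10 odor and 10 blank trials and Poisson
  counts, a ~2.2-spike increment gives the rank-sum test ~85% power at
  alpha = 0.05 for typical rates — so that ground-truth "responses" behave
  like detected responses rather than subthreshold ones.
* **Latency components**: each activated cell-odor pair belongs to one of
  three latency components with weights 0.45/0.40/0.15: an *early* component
  (mean 75 ms PCx / 60 ms OB, SD 20 ms) that ignores concentration; a *late*
  component whose population mean advances with concentration (PCx: 206, 183,
  159, 136 ms; OB: 192, 178, 165, 151 ms; between-cell SD 40 ms); and a slow
  *tail* (350 ms, SD 60 ms). Per-trial latency jitter is Gaussian (SD 15 ms).
  The empirically anchored points are the component means at the lowest and
  highest concentrations; the intermediate values are monotone
  interpolations, an assumption rather than a measured fact.
* **Suppression**: suppressed pairs have their spontaneous rate multiplied by
  a factor starting at 0.10 (lowest concentration) and deepening by 0.05 per
  decade, from 50 ms after inhalation onset to the end of the sniff. The
  onset delay reflects that odor-driven inhibition follows excitation; without
  it the suppressed ensemble would make odor identity decodable in the first
  30 ms bin, before any response latency. The factor was set, like the
  activated amplitude, by the a-priori power calculation (including the
  exposure lost to the onset delay).
* **Respiration**: breath period 0.40 +/- 0.03 s; trials are triggered on
  exhalation, aligned to the next inhalation onset.

`generate_respiration_trace()` produces a matching airflow-like signal
(negative lobes = inhalation) with per-breath period and amplitude jitter and
ground-truth onset times, for exercising the breath detector.

What the generator deliberately does **not** emulate: correlated noise across
cells (all variability is independent Poisson plus latency jitter), background
rate drift, sniff-rate behavioral changes, true network dynamics linking bulb
to cortex, and concentration-dependent changes in spike *counts* of activated
cells (set to zero by construction, which is the point of the intensity
analyses). Passing tests on this data therefore show the *pipeline* is
correct and the *coding logic* is coherent — not that real piriform data
would produce identical numbers.

## Respiration alignment

`detect_breaths()` smooths the trace with a second-order Savitzky-Golay
filter in 200 ms frames, removes slow baseline drift by local linear
detrending in 1.5 s windows with 1 s overlap (overlapping window fits averaged
with triangular weights), finds sub-zero local minima, and keeps troughs whose
depth reaches `peak_prominence` (default 0.5) times the median trough depth —
the amplitude criterion for a "large" negative peak is not standardized, so it
is an explicit knob. Inhalation onset is the preceding zero-crossing,
exhalation onset the following one, both linearly interpolated between
samples. `spike_phase()` interpolates 0 to pi across inhalation and pi to 2 pi
across exhalation; spikes outside event coverage get `NA` and are dropped from
`phase_histogram()` (10 degree bins, normalized to sum to one).

## Response characterization

`compute_kdf()` estimates the trial-averaged firing rate with a 10 ms
Gaussian kernel on a 1 ms grid over 0-0.5 s. Kernels are truncated at the
window bounds without renormalization; consequently a response still rising at
the window edge has its maximum on the edge, and `peak_and_duration()` then
reports the peak latency as undefined — the same rule used for inclusion in
the latency-mixture analyses. Durations are widths of the maximal peak at 25%
and 50% of its height with linearly interpolated crossings.

`response_index()` compares odor against blank spike-count distributions over
the per-trial first sniff: the auROC is computed from the Mann-Whitney U
statistic with mid-rank ties (tied pairs count 1/2) and mapped to
`2 auROC - 1`, so -1/0/+1 mean unequivocal suppression / no change /
unambiguous activation. Significance is the two-sided Wilcoxon rank-sum test
(exact for small tie-free samples, otherwise normal approximation with tie
and continuity corrections), uncorrected at alpha = 0.05 — deliberately no
multiple-testing correction, matching the strict-threshold convention of the
response-fraction statistics this emulates. On discrete low counts the test
is conservative (empirical false-positive rate ~4% at nominal 5%), which the
null-model acceptance band accounts for.

Sparseness uses the normalized peakedness formula
`S = (1 - (sum(r)/n)^2 / (sum(r^2)/n)) / (1 - 1/n)` with `r` the
trial-averaged counts in the first sniff (not blank-subtracted — a documented
choice; the formula assumes non-negative responses, so suppressed responses
are rectified to zero). `tuning_shuffle_null()` permutes cell identities
within each odor column 100 times, preserving each odor's response count, to
give the expected tuning-breadth distribution and mixed-polarity count under
random assignment.

## Population geometry and decoding

`build_vectors()` counts spikes per cell in the per-trial first sniff.
`correlation_by_condition()` computes Spearman correlations (mid-rank ties)
between all trial pairs and averages by condition; within-stimulus averages
use the 45 unordered distinct trial pairs, the cross-product convention
applying only between different stimuli. Pearson is available but sits above
Spearman on skewed counts. Note that because the generator makes activated
spike counts concentration-invariant by construction, same-odorant
correlations decay only marginally with concentration difference on synthetic
data (via suppression depth); real piriform counts redistribute more and show
a clearer decay. The within-odorant versus across-odorant separation is the
robust synthetic signature.

`encode_features()` implements the three readouts over the 480 ms following
inhalation: `summed` (per-cell counts), `binned` (sixteen 30 ms bins per
cell, concatenated), and `binary` (responding/not, thresholded strictly above
the blank-trial mean plus one blank-trial SD, pooled over all blank trials;
sample SD with n-1; an SD of zero leaves the threshold at the mean).

`euclidean_loo()` is the nearest-mean classifier. One numerical choice
deserves emphasis: with classical single-trial exclusion, the held-out
trial's own class mean is computed from n-1 trials while the other classes
use n, and that asymmetry biases label-shuffled accuracy measurably below
`1/n_classes` at 10 trials per class (about 1.5 accuracy points here). The
default therefore holds out one trial per class per fold, which keeps all
training classes size-matched and centers the shuffle control exactly on
theoretical chance — the property the chance-level checks require. The
literal single-trial variant remains available (`folds = "loo"`) and is used
automatically for unbalanced designs. Distance ties break deterministically
toward the lowest class index.

The three tasks: *odorant* (6-way at the nominal concentration),
*concentration* (4-way, trained and tested separately per series odorant and
averaged — the per-odorant protocol is the stated one, even though summary
figures average), and *identity generalization* (train on 11 stimuli with one
concentration of one series odorant excluded; a held-out trial is correct if
the predicted training stimulus shares its odorant, so chance is exactly 3/11
because 3 of the 11 training stimuli share the held-out identity). Accuracy
is macro-averaged across classes. Pseudopopulations are drawn without
replacement within a permutation, freshly per permutation; draws depend only
on the seed, the sizes and the permutation count, so runs with the same seed
are paired across encodings and `compare_encodings()` can build paired
difference bands (2.5-97.5 percentiles across permutations). A linear-kernel
SVM can replace the nearest-mean rule as a robustness check via `svm_loo()`.

`temporal_decoding()` runs the full population with either an expanding
window of 30 ms bins or a single sliding 30 ms bin. `decoding_onset()`
operationalizes "rises above chance" as the earliest window end from which
accuracy exceeds chance by 0.05 and stays there; the identity-vs-intensity
latency comparison uses that definition on expanding windows.

One caveat documented rather than hidden: with a Euclidean nearest-mean
reader, adding cells that are uninformative *for a given task* dilutes the
distance contrast, so concentration-task accuracy is not monotone in
population size on this synthetic data (only ~30 cells carry concentration
information); the monotonicity property holds for the identity tasks, where
informative cells are plentiful.

## Truncated-Gaussian latency mixtures

Peak-latency distributions are modelled as
`f(x) = sum_k p_k phi(x; mu_k, sigma_k) / Z_k` on [0, 0.5] s, each component
individually renormalized (`Z_k` the component's mass on the support — each
component density integrates to one on the interval). Fitting is EM:

* E-step: responsibilities under the truncated component densities.
* M-step: mixing proportions in closed form; each component's (mu, sigma) is
  updated by one inner EM step of the weighted truncated-normal MLE using the
  classical phantom-sample augmentation (the observed points are imagined
  alongside the expected untruncated mass outside the bounds, giving
  closed-form moment updates). Both steps are EM steps, so the observed
  log-likelihood is provably non-decreasing — a tested invariant.

Initialization uses k-means cluster assignments; fits are reinitialized five
times and the best converged restart wins. Convergence requires the
per-observation log-likelihood change to fall below 1e-7 within 8000
iterations; fits that exhaust the budget or collapse a component onto the
1 ms sigma floor are flagged non-converged and excluded downstream.
`select_k_by_bic()` uses `BIC = -2 logL + q log n` with `q = 3k - 1` free
parameters (bounds fixed; the p's lose one degree of freedom to the sum
constraint; whether to charge 3k or 3k-1 is genuinely open — the choice is
explicit in the `q` field and constrained parameters reduce it).

`bootstrap_cis()` refits 1000 (default) equal-sized resamples and reports
2.5-97.5 percentile intervals; components are matched across resamples by
increasing mean, the standard response to label switching (a real limitation:
when components approach each other the attribution is uncertain). Bootstrap
refits are warm-started from the point estimate with a single EM run — the
point fit keeps the full multi-restart protocol — which makes the
1000-resample protocol tractable without changing the point estimates.
`constrained_two_phase_fit()` implements the stabilization protocol: refit
each concentration with all mixing proportions and the slow third component
frozen at the across-concentration means of the unconstrained estimates;
its tested effect is a narrowing of the late-component CIs.

## Concentration-latency slopes

`population_latency_slope()` computes per-trial latencies (first spike after
inhalation within the sniff, or the single-trial KDF peak), keeps cells with
latencies measurable on more than one trial, averages cells within a
population per concentration, and fits OLS against log10 concentration (the
stimulus design is logarithmic; raw concentration is an option).
`compare_regions()` is an unpaired Welch t-test on the per-population-odor
slopes. Whether all cells or only responsive cells enter is not standardized;
the default is all cells, but with ~3 activated cells per population-odor the
late-component shift contributes only ~2 ms to the all-cell population mean
and drowns in spontaneous first-spike noise, so the regional analyses in the
tests use `responsive_only = TRUE`, where the slope reflects the response
components directly. By default cells must have measurable latencies at every
concentration (`complete_cells`, the same inclusion rule as the mixture
analysis): each cell's constant latency offset then cancels out of the slope
instead of leaking in when cells enter at a subset of concentrations.

A power caveat: even then, the PCx-OB *difference* of spike-level slopes
(~4 ms/decade after dilution by early/tail components and background spikes)
sits within its own sampling noise at 9 + 6 populations, so the tests assert
the robust facts — latencies advance with concentration in both regions, and
the fitted late-component mean shifts further in cortex (206 to 136 ms) than
in bulb (192 to 151 ms) — rather than a significance flag for the spike-level
regional t-test, whose machinery is exercised on constructed data instead.

## Problem sizes and experiment design

The test suite and `scripts/acceptance.R` run the decoding analyses on the
full 459-cell cortical population. Chance-level controls use 200 label
shuffles of 50-cell pseudopopulations. The mixture experiments use latency
samples of n = 400 (the order of the number of includable cell-odor pairs):
the component-count experiment reruns BIC selection on 200 bootstrap
resamples; the recovery experiment uses 50 independent samples with
500-resample CIs, counting each component mean's coverage separately (each CI
is a marginal 95% interval, so marginal coverage is the calibrated quantity;
joint coverage of two 95% intervals is expected near 0.90 by construction and
is not a meaningful pass/fail line). Full-population accuracies use 3
permutations because drawing 459 of 459 cells without replacement makes every
permutation identical; the 200-permutation protocol matters at smaller sizes,
where it is used. These sizes are the package's experiment design and are
stated here so that reported numbers are interpretable.

## Known limitations

* The generator shares one trial table across simulated populations
  (pseudo-simultaneous recordings); real recordings have separate sessions.
* Empirical quantities that depend on the precise biological effect sizes
  (sparseness values, correlation magnitudes, absolute decoding accuracies)
  are not calibration targets — only the structural/statistical targets
  listed above are.
* The EM sigma floor (1 ms) and the increasing-mean component matching can
  bias bootstrap intervals for strongly overlapping components.
* The nearest-mean decoder has no feature weighting; its population-size
  behavior on tasks with few informative cells reflects that (see above).
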