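# Per cell-odor response characterization: kernel density firing-rate
# estimates, peak latency and duration, auROC response indices, polarity
# classes, tuning, sparseness, and population synchrony.

#' Trial-averaged kernel density firing-rate estimate
#'
#' Smooths spike times with a Gaussian kernel (10 ms SD by default) and
#' averages across trials, yielding a firing rate in Hz on a uniform 1 ms grid.
#' Kernels are truncated at the window bounds without renormalization, so a
#' peak pushed against the edge stays at the edge (where peak latency is
#' undefined).
#'
#' @param spike_times spike times (s) relative to inhalation onset, pooled over
#'   trials (values outside `window` are ignored by the grid, but still
#'   contribute their in-window kernel mass).
#' @param n_trials number of trials the spikes were pooled from (>= 1).
#' @param kernel_sd Gaussian kernel SD (s).
#' @param window response window (s).
#' @param dt grid step (s).
#' @return object of class `kdf`: list with `time` (s) and `rate` (Hz).
#' @export
compute_kdf <- function(spike_times, n_trials, kernel_sd = 0.010,
                        window = c(0, 0.5), dt = 0.001) {
  if (n_trials < 1) stopf("n_trials must be >= 1")
  if (kernel_sd <= 0 || window[1] >= window[2]) stopf("invalid KDF config")
  grid <- seq(window[1], window[2], by = dt)
  spike_times <- spike_times[is.finite(spike_times)]
  # drop spikes whose kernel cannot reach the window
  spike_times <- spike_times[spike_times > window[1] - 6 * kernel_sd &
                               spike_times < window[2] + 6 * kernel_sd]
  rate <- rep(0, length(grid))
  if (length(spike_times)) {
    # chunked kernel accumulation keeps memory flat for large pooled samples
    chunks <- split(spike_times, ceiling(seq_along(spike_times) / 2000))
    for (ch in chunks)
      rate <- rate + rowSums(outer(grid, ch, function(g, s)
        stats::dnorm(g, s, kernel_sd)))
    rate <- rate / n_trials
  }
  structure(list(time = grid, rate = rate, n_trials = n_trials,
                 kernel_sd = kernel_sd), class = "kdf")
}

#' Peak latency, peak rate and response duration from a KDF
#'
#' The maximal peak of the rate estimate defines peak latency and rate;
#' response duration is the width of that peak at 25% and 50% of its height
#' (crossings located by linear interpolation, clipped at the window bounds).
#' When the maximum sits at a window edge — a response rising to or falling
#' from a peak outside the window — peak latency and durations are undefined.
#'
#' @param kdf a [compute_kdf()] result.
#' @return list with `peak_latency`, `peak_rate`, `duration25`, `duration50`
#'   (all NA for a flat or edge-peaked KDF, except `peak_rate`).
#' @export
peak_and_duration <- function(kdf) {
  r <- kdf$rate; t <- kdf$time
  out <- list(peak_latency = NA_real_, peak_rate = NA_real_,
              duration25 = NA_real_, duration50 = NA_real_)
  if (all(r <= 0) || max(r) - min(r) < 1e-12) return(out)
  i <- which.max(r)
  out$peak_rate <- r[i]
  if (i == 1L || i == length(r)) return(out)
  out$peak_latency <- t[i]
  width_at <- function(frac) {
    thr <- frac * r[i]
    below_l <- which(r[1:(i - 1L)] < thr)
    tl <- if (length(below_l)) {
      j <- max(below_l)
      t[j] + (thr - r[j]) / (r[j + 1L] - r[j]) * (t[j + 1L] - t[j])
    } else t[1]
    below_r <- which(r[(i + 1L):length(r)] < thr) + i
    tr <- if (length(below_r)) {
      j <- min(below_r)
      t[j - 1L] + (r[j - 1L] - thr) / (r[j - 1L] - r[j]) * (t[j] - t[j - 1L])
    } else t[length(t)]
    tr - tl
  }
  out$duration25 <- width_at(0.25)
  out$duration50 <- width_at(0.50)
  out
}

#' auROC response index and rank-sum significance
#'
#' Discriminability of odor versus blank spike-count distributions as the area
#' under the ROC curve computed from the Mann-Whitney U statistic with mid-rank
#' tie handling (tied pairs contribute 1/2). The response index is
#' `2 * auROC - 1`: -1 unequivocal suppression, 0 no change, +1 unambiguous
#' activation. Significance is a two-sided Wilcoxon rank-sum test on the same
#' distributions (exact for small tie-free samples, otherwise normal
#' approximation with tie and continuity correction).
#'
#' @param odor_counts,blank_counts per-trial spike counts.
#' @return list with `auroc`, `index` and `p_value`.
#' @export
response_index <- function(odor_counts, blank_counts) {
  n1 <- length(odor_counts); n2 <- length(blank_counts)
  if (n1 == 0 || n2 == 0) stopf("empty count vector")
  rk <- rank(c(odor_counts, blank_counts))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auroc <- u / (n1 * n2)
  p <- suppressWarnings(stats::wilcox.test(odor_counts, blank_counts,
                                           exact = NULL)$p.value)
  if (is.na(p)) p <- 1  # fully tied samples carry no evidence either way
  list(auroc = auroc, index = 2 * auroc - 1, p_value = p)
}

#' Response statistics for every cell-odor(-concentration) pair
#'
#' For each unit and each non-blank stimulus: spike counts in the per-trial
#' first full respiration cycle are compared to the unit's blank-trial counts
#' (auROC response index, two-sided rank-sum p, polarity at `alpha`), and a
#' 10 ms-kernel KDF over `window` defines peak latency, peak rate and response
#' durations. First-spike latency is the per-trial time of the first spike
#' after inhalation onset, averaged over trials with at least one spike;
#' it is reported only when measurable on more than one trial.
#'
#' @param dataset an `odor_dataset`.
#' @param alpha significance level for polarity calls (uncorrected).
#' @param kernel_sd KDF kernel SD (s).
#' @param window KDF response window (s).
#' @param region optional region filter.
#' @return data.frame, one row per unit x stimulus.
#' @export
compute_response_stats <- function(dataset, alpha = 0.05, kernel_sd = 0.010,
                                   window = c(0, 0.5), region = NULL) {
  units <- select_units(dataset, region = region)
  trials <- dataset$trials
  counts <- spike_count_matrix(dataset, "sniff", cells = units)
  dur <- sniff_durations(dataset)
  al <- align_spikes(dataset, window + c(-0.06, 0.06))
  al <- al[al$unit_id %in% units, ]
  key <- paste(al$unit_id, al$trial_id)
  spikes_by <- split(al$rel_time_s, key)

  blank_rows <- which(trials$is_blank)
  stim <- unique(trials[!trials$is_blank, c("odorant", "concentration")])
  umeta <- dataset$units[match(units, dataset$units$unit_id), ]
  out <- vector("list", length(units) * nrow(stim))
  n <- 0L
  for (ui in seq_along(units)) {
    u <- units[ui]
    blank_counts <- counts[blank_rows, ui]
    for (si in seq_len(nrow(stim))) {
      rows <- which(trials$odorant == stim$odorant[si] &
                      abs(trials$concentration - stim$concentration[si]) < 1e-12)
      oc <- counts[rows, ui]
      ri <- response_index(oc, blank_counts)
      pol <- if (ri$p_value < alpha)
        if (ri$index > 0) "activated" else "suppressed" else "none"
      pooled <- unlist(spikes_by[paste(u, trials$trial_id[rows])],
                       use.names = FALSE)
      pooled <- pooled %||% numeric(0)
      kdf <- compute_kdf(pooled[pooled >= window[1] - 0.06 &
                                  pooled <= window[2] + 0.06],
                         n_trials = length(rows), kernel_sd = kernel_sd,
                         window = window)
      pk <- peak_and_duration(kdf)
      fs <- vapply(rows, function(k) {
        s <- spikes_by[[paste(u, trials$trial_id[k])]]
        s <- s[s >= 0 & s < dur[k]]
        if (length(s)) min(s) else NA_real_
      }, numeric(1))
      nfs <- sum(!is.na(fs))
      n <- n + 1L
      out[[n]] <- data.frame(
        unit_id = u, region = umeta$region[ui],
        population_id = umeta$population_id[ui],
        odorant = stim$odorant[si], concentration = stim$concentration[si],
        n_trials = length(rows), mean_count = mean(oc),
        blank_mean_count = mean(blank_counts),
        auroc = ri$auroc, response_index = ri$index, p_value = ri$p_value,
        polarity = pol,
        peak_latency_s = pk$peak_latency, peak_rate_hz = pk$peak_rate,
        duration25_s = pk$duration25, duration50_s = pk$duration50,
        first_spike_latency_s = if (nfs > 1) mean(fs, na.rm = TRUE) else NA_real_,
        n_first_spike_trials = nfs)
    }
  }
  res <- do.call(rbind, out[seq_len(n)])
  rownames(res) <- NULL
  res
}

#' Cell-level polarity classes
#'
#' Classifies each cell from the set of its significant per-odor polarities:
#' `activated-only`, `suppressed-only`, `mixed` (at least one significant
#' response of each sign) or `unresponsive`.
#'
#' @param stats a [compute_response_stats()] data.frame (filter to the stimulus
#'   subset of interest first, e.g. one concentration).
#' @param alpha significance level.
#' @return data.frame with unit_id, class, n_activated, n_suppressed.
#' @export
classify_polarity <- function(stats, alpha = 0.05) {
  sig <- stats$p_value < alpha
  pos <- sig & stats$response_index > 0
  neg <- sig & stats$response_index < 0
  na_ <- tapply(pos, stats$unit_id, sum)
  ns_ <- tapply(neg, stats$unit_id, sum)
  cls <- ifelse(na_ > 0 & ns_ > 0, "mixed",
         ifelse(na_ > 0, "activated-only",
         ifelse(ns_ > 0, "suppressed-only", "unresponsive")))
  data.frame(unit_id = names(na_), class = unname(cls),
             n_activated = as.integer(na_), n_suppressed = as.integer(ns_))
}

#' Identity-shuffle null for tuning and mixed-polarity counts
#'
#' Shuffles cell identities independently within each odor column (preserving
#' every odor's response count) and recomputes, per shuffle, the percentage of
#' cells responding to k odors and the number of mixed-polarity cells. The
#' observed tuning distribution is compared to the mean and 5th-95th percentile
#' band of the shuffles.
#'
#' @param polarity_matrix cells x odors matrix with entries -1 (suppressed),
#'   0 (no response) or +1 (activated).
#' @param n_shuffles number of shuffles (default 100).
#' @param seed optional seed.
#' @return list with `observed` (data.frame k, pct, and mixed count) and
#'   `null` (per-k mean and 5th/95th percentiles, and the mixed-count
#'   distribution).
#' @export
tuning_shuffle_null <- function(polarity_matrix, n_shuffles = 100, seed = NULL) {
  m <- as.matrix(polarity_matrix)
  nc <- nrow(m); no <- ncol(m)
  tuning_pct <- function(x) {
    k <- rowSums(x != 0)
    100 * tabulate(k + 1L, no + 1L) / nc
  }
  mixed_count <- function(x) sum(rowSums(x > 0) > 0 & rowSums(x < 0) > 0)
  obs_pct <- tuning_pct(m)
  obs_mixed <- mixed_count(m)
  with_seed(seed, {
    null_pct <- matrix(0, n_shuffles, no + 1L)
    null_mixed <- integer(n_shuffles)
    for (s in seq_len(n_shuffles)) {
      sh <- apply(m, 2, function(col) col[sample.int(nc)])
      null_pct[s, ] <- tuning_pct(sh)
      null_mixed[s] <- mixed_count(sh)
    }
    list(observed = data.frame(k = 0:no, pct = obs_pct),
         observed_mixed = obs_mixed,
         null = data.frame(k = 0:no,
                           mean = colMeans(null_pct),
                           lo = apply(null_pct, 2, stats::quantile, 0.05),
                           hi = apply(null_pct, 2, stats::quantile, 0.95)),
         null_mixed = null_mixed,
         null_mixed_q = stats::quantile(null_mixed, c(0.05, 0.5, 0.95)))
  })
}

#' Lifetime / population sparseness
#'
#' `S = (1 - (sum(r)/n)^2 / (sum(r^2)/n)) / (1 - 1/n)`, the normalized
#' peakedness of a response distribution: 0 for uniform nonzero responses, 1
#' when a single entry is nonzero. For lifetime sparseness `r` holds one cell's
#' trial-averaged responses across odors; for population sparseness, the
#' responses of all cells to one odor. Negative entries (suppressed responses)
#' are rectified to zero; an all-zero `r` gives NA.
#'
#' @param r non-negative responses (counts or rates); negatives are rectified.
#' @param n number of odors/cells; defaults to `length(r)`.
#' @return sparseness in `[0, 1]`, or NA.
#' @export
sparseness <- function(r, n = length(r)) {
  if (n < 2) stopf("sparseness needs n >= 2")
  r <- pmax(r, 0)
  if (all(r == 0)) return(NA_real_)
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Lifetime and population sparseness of a response matrix
#'
#' @param counts trials x cells count matrix (attribute `"trials"` used for
#'   stimulus labels), or a cells x odors matrix of trial-averaged responses
#'   when `trials` is NULL.
#' @param trials trial table matching the rows of `counts`.
#' @param concentration restrict to one concentration (default: all non-blank).
#' @return list with per-cell lifetime sparseness and per-odor population
#'   sparseness.
#' @export
sparseness_summary <- function(counts, trials = attr(counts, "trials"),
                               concentration = NULL) {
  keep <- !trials$is_blank
  if (!is.null(concentration))
    keep <- keep & abs(trials$concentration - concentration) < 1e-12
  m <- counts[keep, , drop = FALSE]
  od <- trials$odorant[keep]
  rbar <- apply(m, 2, function(col) tapply(col, od, mean))  # odors x cells
  list(lifetime = apply(rbar, 2, sparseness),
       population = apply(rbar, 1, sparseness))
}

#' Peak/average synchrony ratio of a rate trace
#'
#' @param rate non-negative rate trace values.
#' @return `max(rate) / mean(rate)`; NA when the trace carries no activity.
#' @export
peak_average_ratio <- function(rate) {
  if (all(rate == 0)) return(NA_real_)
  max(rate) / mean(rate)
}

#' Population PSTH and synchrony
#'
#' Average of per-cell trial-averaged KDFs (population mean rate, i.e. summed
#' activity normalized by the number of cells) for one stimulus, and the
#' peak/average ratio of that trace over the first sniff — a synchrony index
#' that increases when response phases align.
#'
#' @param dataset an `odor_dataset`.
#' @param odorant,concentration stimulus selector.
#' @param region region filter (default `"PCx"`).
#' @param kernel_sd KDF kernel SD (s).
#' @return list with `time`, `rate` (Hz per cell), and `peak_average_ratio`
#'   computed over the median first-sniff duration.
#' @export
population_psth <- function(dataset, odorant, concentration, region = "PCx",
                            kernel_sd = 0.010) {
  units <- select_units(dataset, region = region)
  if (!length(units)) stopf("no units in region")
  trials <- dataset$trials
  rows <- which(trials$odorant == odorant &
                  abs(trials$concentration - concentration) < 1e-12)
  if (!length(rows)) stopf("no trials for stimulus")
  al <- align_spikes(dataset, c(-0.06, 0.56))
  al <- al[al$unit_id %in% units & al$trial_id %in% trials$trial_id[rows], ]
  kdf <- compute_kdf(al$rel_time_s, n_trials = length(rows),
                     kernel_sd = kernel_sd, window = c(0, 0.5))
  rate <- kdf$rate / length(units)
  sniff <- stats::median(sniff_durations(dataset)[rows])
  in_sniff <- kdf$time <= sniff
  list(time = kdf$time, rate = rate,
       peak_average_ratio = peak_average_ratio(rate[in_sniff]))
}

#' Total spiking output by concentration
#'
#' Re-aggregates the spike trains of all units over the per-trial first sniff,
#' averages across trials of each concentration of one odorant, and normalizes
#' by the mean across concentrations (so concentration-invariant total output
#' sits at 1).
#'
#' @param dataset an `odor_dataset`.
#' @param odorant a concentration-series odorant.
#' @param region region filter.
#' @param per_second divide each trial's total by its sniff duration before
#'   averaging, removing breath-period variability from the comparison.
#' @return data.frame with concentration, total_count (mean summed count per
#'   trial, or count rate with `per_second`) and normalized output.
#' @export
total_spiking_output <- function(dataset, odorant, region = "PCx",
                                 per_second = FALSE) {
  counts <- spike_count_matrix(dataset, "sniff", region = region)
  trials <- attr(counts, "trials")
  rows <- which(trials$odorant == odorant)
  conc <- trials$concentration[rows]
  tot <- rowSums(counts[rows, , drop = FALSE])
  if (per_second) tot <- tot / sniff_durations(dataset)[rows]
  res <- aggregate(list(total_count = tot), list(concentration = conc), mean)
  res$normalized <- res$total_count / mean(res$total_count)
  res
}

#' Mean spontaneous firing rate from inter-trial epochs
#'
#' Counts spikes in the pre-trial segment of each trial window (by default
#' `[-1, -0.1]` s before inhalation onset) and converts to Hz per unit.
#'
#' @param dataset an `odor_dataset`.
#' @param window pre-onset epoch (s, both negative).
#' @return data.frame unit_id, spont_rate_hz.
#' @export
spontaneous_rates <- function(dataset, window = c(-1, -0.1)) {
  counts <- spike_count_matrix(dataset, window = window)
  rate <- colSums(counts) / (nrow(dataset$trials) * diff(window))
  data.frame(unit_id = colnames(counts), spont_rate_hz = unname(rate))
}
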