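# Trial alignment and spike-count containers shared by the analysis stages.
# Analysis time zero is the per-trial inhalation onset; counting windows are
# half-open [start, end).

#' Align spikes to per-trial inhalation onsets
#'
#' @param dataset an `odor_dataset` (or a list with `spikes` and `trials`).
#' @param window window (s) relative to inhalation onset to retain.
#' @return data.frame with unit_id, trial_id and rel_time_s. Trials must be
#'   spaced so that windows do not overlap.
#' @export
align_spikes <- function(dataset, window = c(-1, 1)) {
  trials <- dataset$trials
  o <- order(trials$inhalation_onset_s)
  onset <- trials$inhalation_onset_s[o]
  if (length(onset) > 1 && min(diff(onset)) < diff(window))
    warning("trial windows overlap; spikes assigned to the later trial")
  idx <- findInterval(dataset$spikes$time_s, onset + window[1])
  ok <- idx >= 1
  rel <- dataset$spikes$time_s[ok] - onset[idx[ok]]
  keep <- rel < window[2]
  data.frame(unit_id = dataset$spikes$unit_id[ok][keep],
             trial_id = trials$trial_id[o][idx[ok]][keep],
             rel_time_s = rel[keep])
}

#' Per-trial first-sniff durations
#'
#' Duration (s) of the first full respiration cycle after odor onset for each
#' trial, from the dataset's breath events. Falls back to a fixed 0.48 s window
#' when no breath events are available.
#'
#' @param dataset an `odor_dataset`.
#' @param fallback window length (s) used without respiration data.
#' @return numeric vector, one duration per row of `dataset$trials`.
#' @export
sniff_durations <- function(dataset, fallback = 0.48) {
  trials <- dataset$trials
  if (is.null(dataset$breaths) || !length(dataset$breaths$inhalation_onsets))
    return(rep(fallback, nrow(trials)))
  inh <- dataset$breaths$inhalation_onsets
  i <- findInterval(trials$inhalation_onset_s + 1e-9, inh)
  nxt <- ifelse(i + 1L <= length(inh), inh[pmin(i + 1L, length(inh))], NA_real_)
  d <- nxt - trials$inhalation_onset_s
  d[is.na(d) | d <= 0] <- fallback
  d
}

# unit subset helper: NULL = all units, a region name, or explicit ids
select_units <- function(dataset, cells = NULL, region = NULL) {
  u <- dataset$units$unit_id
  if (!is.null(region)) u <- u[dataset$units$region %in% region]
  if (!is.null(cells)) u <- intersect(u, cells)
  u
}

#' Spike-count matrix over a response window
#'
#' Counts spikes per trial and unit either in the per-trial first sniff
#' (`window = "sniff"`) or in a fixed window relative to inhalation onset.
#'
#' @param dataset an `odor_dataset`.
#' @param window `"sniff"` or `c(start, end)` in seconds.
#' @param region optional region filter (e.g. `"PCx"`).
#' @param cells optional explicit unit ids.
#' @return integer matrix trials x units with dimnames, plus the trial table as
#'   attribute `"trials"`.
#' @export
spike_count_matrix <- function(dataset, window = "sniff", region = NULL,
                               cells = NULL) {
  units <- select_units(dataset, cells, region)
  trials <- dataset$trials
  sniff <- identical(window, "sniff")
  wmax <- if (sniff) max(sniff_durations(dataset)) else window[2]
  wmin <- if (sniff) 0 else window[1]
  al <- align_spikes(dataset, c(wmin, wmax))
  if (sniff) {
    dur <- sniff_durations(dataset)[match(al$trial_id, trials$trial_id)]
    al <- al[al$rel_time_s >= 0 & al$rel_time_s < dur, ]
  }
  ti <- match(al$trial_id, trials$trial_id)
  ui <- match(al$unit_id, units)
  ok <- !is.na(ui)
  counts <- matrix(tabulate(ti[ok] + (ui[ok] - 1L) * nrow(trials),
                            nbins = nrow(trials) * length(units)),
                   nrow = nrow(trials), ncol = length(units),
                   dimnames = list(trials$trial_id, units))
  attr(counts, "trials") <- trials
  counts
}

#' Binned spike-count array
#'
#' Counts spikes in consecutive bins of `bin_width` seconds covering
#' `[window[1], window[2])` after inhalation onset, for every trial and unit —
#' the raw material of the binned (temporal) feature encoding.
#'
#' @inheritParams spike_count_matrix
#' @param window counting window (s); its length must be a multiple of
#'   `bin_width`.
#' @param bin_width bin width (s), default 30 ms.
#' @return 3-d array `[trial, unit, bin]` with the trial table attached as
#'   attribute `"trials"`.
#' @export
binned_count_array <- function(dataset, window = c(0, 0.48), bin_width = 0.03,
                               region = NULL, cells = NULL) {
  nb <- (window[2] - window[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stopf("window length must be a multiple of bin_width")
  nb <- as.integer(round(nb))
  units <- select_units(dataset, cells, region)
  trials <- dataset$trials
  al <- align_spikes(dataset, window)
  al <- al[al$rel_time_s >= window[1], ]
  ti <- match(al$trial_id, trials$trial_id)
  ui <- match(al$unit_id, units)
  bi <- pmin(floor((al$rel_time_s - window[1]) / bin_width) + 1L, nb)
  ok <- !is.na(ui)
  nT <- nrow(trials); nU <- length(units)
  a <- array(tabulate(ti[ok] + (ui[ok] - 1L) * nT + (bi[ok] - 1L) * nT * nU,
                      nbins = nT * nU * nb),
             dim = c(nT, nU, nb),
             dimnames = list(trials$trial_id, units, NULL))
  attr(a, "trials") <- trials
  attr(a, "bin_width") <- bin_width
  attr(a, "window") <- window
  a
}
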