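# Concentration-dependence of response latencies per simultaneously recorded
# population, and the bulb-vs-cortex slope comparison.

#' OLS latency-vs-concentration slope
#'
#' Ordinary least-squares regression of mean latency on log10 concentration
#' (the stimulus design spaces concentrations in 0.5 log10 steps; a raw
#' concentration abscissa is available via `log_concentration = FALSE`).
#'
#' @param mean_latencies mean latency (s) per concentration.
#' @param concentrations matching v/v fractions (>= 2 values).
#' @param log_concentration regress on log10 concentration (default) or raw.
#' @return list with `slope` (s per log10 unit), `intercept`, `n_points`.
#' @export
latency_slope_fit <- function(mean_latencies, concentrations,
                              log_concentration = TRUE) {
  ok <- is.finite(mean_latencies) & is.finite(concentrations)
  if (sum(ok) < 2) stopf("need latencies at >= 2 concentrations")
  xx <- if (log_concentration) log10(concentrations[ok]) else concentrations[ok]
  fit <- stats::lm(mean_latencies[ok] ~ xx)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_points = sum(ok))
}

# per-trial response latencies for one unit/stimulus: first spike after
# inhalation onset, or the peak of the single-trial KDF
trial_latencies <- function(spikes_by_trial, sniff_dur, type, kernel_sd = 0.010) {
  vapply(seq_along(spikes_by_trial), function(i) {
    s <- spikes_by_trial[[i]]
    if (type == "first_spike") {
      s <- s[s >= 0 & s < sniff_dur[i]]
      if (length(s)) min(s) else NA_real_
    } else {
      if (!length(s)) return(NA_real_)
      kdf <- compute_kdf(s, n_trials = 1, kernel_sd = kernel_sd)
      peak_and_duration(kdf)$peak_latency
    }
  }, numeric(1))
}

#' Concentration-latency slope for one population-odor pair
#'
#' Response latency for each cell is the trial-averaged time to first spike or
#' to the single-trial KDF peak; a cell contributes at a concentration only
#' when its latency was measurable on more than one trial. Cell latencies are
#' averaged per concentration and a regression line on log10 concentration
#' gives the slope.
#'
#' @param dataset an `odor_dataset`.
#' @param population_id a population (recording) identifier from
#'   `dataset$units$population_id`.
#' @param odorant a concentration-series odorant.
#' @param latency_type `"first_spike"` or `"psth_peak"`.
#' @param min_trials minimum trials with measurable latency (default 2, i.e.
#'   "more than one trial").
#' @param cells optional explicit unit subset (e.g. odor-activated cells from
#'   [compute_response_stats()]); by default every cell of the population with
#'   measurable latencies contributes. Restricting to activated cells avoids
#'   diluting the concentration-latency effect with spontaneous first spikes.
#' @param complete_cells require latencies at every concentration (default
#'   TRUE, the same inclusion rule as the latency-mixture analysis); then each
#'   cell's constant latency offset cancels out of the slope instead of
#'   leaking into it when cells enter at some concentrations only.
#' @return one-row data.frame (population_id, odorant, region, latency_type,
#'   slope, intercept, n_cells, n_concentrations), or NULL with a message when
#'   no latencies could be retrieved.
#' @export
population_latency_slope <- function(dataset, population_id, odorant,
                                     latency_type = c("first_spike",
                                                      "psth_peak"),
                                     min_trials = 2, cells = NULL,
                                     complete_cells = TRUE) {
  latency_type <- match.arg(latency_type)
  units <- dataset$units[dataset$units$population_id == population_id, ]
  if (!is.null(cells)) units <- units[units$unit_id %in% cells, ]
  if (!nrow(units)) {
    message(sprintf("population %s / %s: no eligible cells; pair dropped",
                    population_id, odorant))
    return(NULL)
  }
  trials <- dataset$trials
  rows <- which(trials$odorant == odorant)
  if (!length(rows)) stopf("no trials for odorant '%s'", odorant)
  dur <- sniff_durations(dataset)
  al <- align_spikes(dataset, c(0, 0.56))
  al <- al[al$unit_id %in% units$unit_id & al$trial_id %in% trials$trial_id[rows], ]
  spikes_by <- split(al$rel_time_s, paste(al$unit_id, al$trial_id))

  concs <- sort(unique(trials$concentration[rows]))
  cell_means <- matrix(NA_real_, nrow(units), length(concs),
                       dimnames = list(units$unit_id, NULL))
  for (ci in seq_along(concs)) {
    tr <- rows[abs(trials$concentration[rows] - concs[ci]) < 1e-12]
    for (u in units$unit_id) {
      sbt <- lapply(tr, function(k) {
        s <- spikes_by[[paste(u, trials$trial_id[k])]]
        s %||% numeric(0)
      })
      lat <- trial_latencies(sbt, dur[tr], latency_type)
      if (sum(!is.na(lat)) >= min_trials)
        cell_means[u, ci] <- mean(lat, na.rm = TRUE)
    }
  }
  if (complete_cells && length(concs) > 1) {
    full <- rowSums(is.finite(cell_means)) == length(concs)
    if (any(full)) cell_means <- cell_means[full, , drop = FALSE]
  }
  pop_means <- colMeans(cell_means, na.rm = TRUE)
  ok <- is.finite(pop_means)
  if (sum(ok) < 2) {
    message(sprintf("population %s / %s: no latencies retrievable; pair dropped",
                    population_id, odorant))
    return(NULL)
  }
  fit <- latency_slope_fit(pop_means[ok], concs[ok])
  data.frame(population_id = population_id, odorant = odorant,
             region = units$region[1], latency_type = latency_type,
             slope = fit$slope, intercept = fit$intercept,
             n_cells = sum(rowSums(!is.na(cell_means)) > 0),
             n_concentrations = sum(ok))
}

#' Concentration-latency slopes for all population-odor pairs
#'
#' @inheritParams population_latency_slope
#' @param responsive_only restrict each pair to cells significantly activated
#'   by that odorant at one or more concentrations. Including every cell
#'   follows the measurement protocol literally but buries the latency shift
#'   of the few responsive cells under concentration-independent spontaneous
#'   first spikes; responsive inclusion recovers the response-driven slope.
#' @param stats precomputed [compute_response_stats()] table (computed on the
#'   fly when needed and `responsive_only = TRUE`).
#' @param alpha significance level for the activation filter.
#' @return data.frame of [population_latency_slope()] rows (dropped pairs
#'   omitted).
#' @export
all_population_slopes <- function(dataset, latency_type = c("first_spike",
                                                            "psth_peak"),
                                  responsive_only = FALSE, stats = NULL,
                                  alpha = 0.05) {
  latency_type <- match.arg(latency_type)
  panel <- generalization_panel(dataset$trials)
  pops <- unique(dataset$units$population_id[dataset$units$region %in%
                                               c("PCx", "OB")])
  if (responsive_only && is.null(stats))
    stats <- compute_response_stats(dataset, alpha = alpha)
  rows <- list()
  for (p in pops) for (od in panel$series_odorants) {
    cells <- NULL
    if (responsive_only) {
      sel <- stats$odorant == od & stats$p_value < alpha &
        stats$response_index > 0
      cells <- unique(stats$unit_id[sel])
    }
    r <- population_latency_slope(dataset, p, od, latency_type, cells = cells)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare concentration-latency slopes between regions
#'
#' Unpaired two-sample t-test of the per-population-odor slope distributions
#' of the two regions (negative differences mean steeper, i.e. more strongly
#' latency-advancing, cortical slopes).
#'
#' @param slopes a data.frame from [all_population_slopes()] with slopes for
#'   both regions, or two numeric vectors via `slopes_ob`.
#' @param slopes_ob optional second slope vector (then `slopes` is the PCx
#'   vector).
#' @return list with `mean_diff` (PCx - OB), `t`, `df`, `p_value` and per-group
#'   means.
#' @export
compare_regions <- function(slopes, slopes_ob = NULL) {
  if (is.data.frame(slopes)) {
    s_pcx <- slopes$slope[slopes$region == "PCx"]
    s_ob <- slopes$slope[slopes$region == "OB"]
  } else {
    s_pcx <- slopes
    s_ob <- slopes_ob
  }
  if (length(s_pcx) < 2 || length(s_ob) < 2)
    stopf("need >= 2 slope fits per region")
  tt <- stats::t.test(s_pcx, s_ob, var.equal = FALSE)
  list(mean_diff = mean(s_pcx) - mean(s_ob),
       mean_pcx = mean(s_pcx), mean_ob = mean(s_ob),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
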