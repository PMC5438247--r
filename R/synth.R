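#' Configuration for the synthetic spike-train generator
#'
#' Builds a validated configuration for [generate_dataset()]. Defaults emulate
#' the response structure of awake-mouse recordings from piriform cortex (PCx)
#' and olfactory bulb (OB): log-normal spontaneous rates with arithmetic mean
#' ~3.09 Hz, ~6.7% of cells activated and ~13.3% suppressed per odor with
#' largely disjoint activated-only/suppressed-only cell classes (~4% mixed),
#' brief responses (~43 ms full width at half maximum), and a three-component
#' peak-latency distribution whose early component is concentration-invariant
#' while the late component advances from ~206 ms at 0.03% v/v to ~136 ms at
#' 1% v/v in cortex (192 to 151 ms in bulb).
#'
#' @param n_cells_pcx,n_cells_ob number of cortical / bulb units.
#' @param n_populations_pcx,n_populations_ob number of simulated recordings the
#'   units are split across (used by the latency-slope analysis).
#' @param n_odorants number of odorants in the panel; the first
#'   `length(series_odorants)` are presented at every concentration, the rest
#'   only at `nominal_concentration`.
#' @param concentrations v/v dilution fractions, strictly increasing. Defaults
#'   to 0.03%, 0.1%, 0.3% and 1% v/v in 0.5 log10 steps.
#' @param series_odorants indices of odorants presented at all concentrations.
#' @param nominal_concentration concentration of the single-dilution stimuli.
#' @param n_trials_per_stimulus trials per panel stimulus (and per blank).
#' @param spont_lognormal `c(meanlog, sdlog)` of spontaneous rates in Hz.
#'   Defaults reproduce a 1.68 Hz median / 3.09 Hz mean.
#' @param frac_activated,frac_suppressed expected fraction of cortical cells
#'   activated / suppressed per odor.
#' @param ob_response_fractions `c(activated, suppressed)` per-odor response
#'   fractions for the olfactory-bulb population. Mitral/tufted cells are far
#'   less odor-selective than piriform cells, and bulb latency distributions
#'   are fit from a comparable number of cell-odor pairs despite the smaller
#'   population; set both to zero for a fully response-free dataset.
#' @param frac_mixed fraction of cells with mixed polarity across odors; mixed
#'   cells are only generated when both response fractions are positive.
#' @param early_phase_pcx,early_phase_ob `c(mean, sd)` in seconds of the
#'   concentration-invariant early latency component.
#' @param late_phase_means_pcx,late_phase_means_ob mean late-component latency
#'   (s) at each concentration; must be decreasing when
#'   `require_monotone_late = TRUE`.
#' @param late_phase_sd between-cell SD (s) of late-component latencies.
#' @param late_tail `c(mean, sd, weight)` of the slow third latency component.
#' @param component_weights probabilities that an activated cell-odor pair is
#'   assigned to the early / late / tail component (sums to 1).
#' @param response_duration_sd SD (s) of the Gaussian firing-rate bump; the
#'   default gives a ~43 ms full width at half maximum.
#' @param response_peak_rate `c(meanlog, sdlog)` of the bump peak amplitude in
#'   Hz, drawn per responsive cell-odor pair.
#' @param latency_jitter_sd trial-to-trial SD (s) of response latency.
#' @param suppression_factor multiplicative rate factor of suppressed pairs at
#'   the lowest concentration.
#' @param suppression_gain_per_logconc amount the factor decreases per decade
#'   of concentration (suppression deepens with concentration).
#' @param suppression_onset delay (s) after inhalation onset before suppression
#'   takes effect within the sniff (odor-driven inhibition follows excitation).
#' @param suppression_min_rate minimum spontaneous rate (Hz) for a cell to be
#'   eligible for the suppressed class; suppression of a near-silent cell is
#'   neither meaningful nor detectable. Suppressed cells are additionally
#'   sampled with probability proportional to rate.
#' @param phase_modulation_depth depth of the weak sinusoidal sniff-phase
#'   modulation of spontaneous rates (0 = none).
#' @param breath_period,breath_period_sd mean and SD (s) of the respiration
#'   cycle.
#' @param trial_interval spacing (s) between consecutive trials.
#' @param trial_window window (s) around each inhalation onset in which spikes
#'   are generated; the pre-onset part serves as the inter-trial epoch for
#'   spontaneous-rate estimation.
#' @param n_cells_vgat optional broadly tuned inhibitory-like subpopulation
#'   whose early PSTH peak sharpens and advances with concentration.
#' @param require_monotone_late reject configurations whose late-phase means do
#'   not decrease with concentration.
#' @param seed default seed used by [generate_dataset()].
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_cells_pcx = 459,
                         n_cells_ob = 126,
                         n_populations_pcx = 9,
                         n_populations_ob = 6,
                         n_odorants = 6,
                         concentrations = c(3e-4, 1e-3, 3e-3, 1e-2),
                         series_odorants = 1:2,
                         nominal_concentration = 3e-3,
                         n_trials_per_stimulus = 10,
                         spont_lognormal = c(meanlog = log(1.68),
                                             sdlog = sqrt(2 * log(3.09 / 1.68))),
                         frac_activated = 0.067,
                         frac_suppressed = 0.133,
                         frac_mixed = 0.04,
                         ob_response_fractions = c(activated = 0.30,
                                                   suppressed = 0.25),
                         early_phase_pcx = c(mean = 0.075, sd = 0.02),
                         early_phase_ob = c(mean = 0.060, sd = 0.02),
                         late_phase_means_pcx = c(0.206, 0.183, 0.159, 0.136),
                         late_phase_means_ob = c(0.192, 0.178, 0.165, 0.151),
                         late_phase_sd = 0.04,
                         late_tail = c(mean = 0.35, sd = 0.06, weight = 0.15),
                         component_weights = c(early = 0.45, late = 0.40,
                                               tail = 0.15),
                         response_duration_sd = 0.043 / (2 * sqrt(2 * log(2))),
                         response_peak_rate = c(meanlog = log(45), sdlog = 0.35),
                         latency_jitter_sd = 0.015,
                         suppression_factor = 0.08,
                         suppression_gain_per_logconc = 0.04,
                         suppression_onset = 0.05,
                         suppression_min_rate = 2,
                         phase_modulation_depth = 0.10,
                         breath_period = 0.40,
                         breath_period_sd = 0.03,
                         trial_interval = 3,
                         trial_window = c(-1.0, 1.2),
                         n_cells_vgat = 0,
                         require_monotone_late = TRUE,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fr <- c(cfg$frac_activated, cfg$frac_suppressed, cfg$frac_mixed,
          cfg$ob_response_fractions)
  if (any(fr < 0 | fr > 1)) stopf("response fractions must lie in [0, 1]")
  if (sum(fr[1:3]) > 1) stopf("frac_activated + frac_suppressed + frac_mixed > 1")
  if (sum(cfg$ob_response_fractions) + cfg$frac_mixed > 1)
    stopf("OB response fractions plus frac_mixed > 1")
  if (any(diff(cfg$concentrations) <= 0))
    stopf("concentrations must be strictly increasing")
  lat <- c(cfg$early_phase_pcx[1], cfg$early_phase_ob[1],
           cfg$late_phase_means_pcx, cfg$late_phase_means_ob, cfg$late_tail[1])
  if (any(lat <= 0 | lat >= 0.5))
    stopf("latency-component means must lie strictly inside (0, 0.5) s")
  if (length(cfg$late_phase_means_pcx) != length(cfg$concentrations) ||
      length(cfg$late_phase_means_ob) != length(cfg$concentrations))
    stopf("late_phase_means must have one entry per concentration")
  if (isTRUE(cfg$require_monotone_late)) {
    if (any(diff(cfg$late_phase_means_pcx) >= 0) ||
        any(diff(cfg$late_phase_means_ob) >= 0))
      stopf("late-phase means must decrease with concentration (set require_monotone_late = FALSE to allow)")
  }
  if (cfg$spont_lognormal[2] < 0) stopf("spontaneous rate sdlog must be >= 0")
  if (cfg$suppression_factor < 0 || cfg$suppression_factor > 1)
    stopf("suppression_factor must lie in [0, 1]")
  if (cfg$response_duration_sd <= 0) stopf("response_duration_sd must be > 0")
  if (abs(sum(cfg$component_weights) - 1) > 1e-8)
    stopf("component_weights must sum to 1")
  if (!is.null(cfg$nominal_concentration) &&
      !any(abs(cfg$concentrations - cfg$nominal_concentration) < 1e-12))
    stopf("nominal_concentration must be one of `concentrations`")
  invisible(cfg)
}

default_odorant_names <- function(n) {
  std <- c("ethyl_butyrate", "hexanal", "2_hexanone", "isoamyl_acetate",
           "ethyl_tiglate", "ethyl_acetate")
  if (n <= length(std)) std[seq_len(n)] else c(std, sprintf("odorant_%02d", seq_len(n - length(std)) + length(std)))
}

#' Stimulus panel implied by a generator configuration
#'
#' @param config a [synth_config()].
#' @return data.frame with one row per distinct stimulus (odorant,
#'   concentration, is_blank); the blank (mineral oil) stimulus is included.
#' @export
stimulus_panel <- function(config) {
  odors <- default_odorant_names(config$n_odorants)
  rows <- list(data.frame(odorant = "mineral_oil", concentration = 0,
                          is_blank = TRUE))
  for (i in seq_len(config$n_odorants)) {
    conc <- if (i %in% config$series_odorants) config$concentrations
            else config$nominal_concentration
    rows[[length(rows) + 1L]] <-
      data.frame(odorant = odors[i], concentration = conc, is_blank = FALSE)
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel
}

# Sniff-cycle phase (0 at inhalation onset, pi at exhalation onset, wrapping
# at the next inhalation) for absolute times against a breath-event grid.
breath_phase_at <- function(times, inh, exh) {
  i <- findInterval(times, inh)
  phase <- rep(NA_real_, length(times))
  ok <- i >= 1 & i < length(inh)
  ii <- i[ok]
  t0 <- inh[ii]; t1 <- exh[ii]; t2 <- inh[ii + 1L]
  tt <- times[ok]
  inhal <- tt < t1
  ph <- numeric(length(tt))
  ph[inhal] <- pi * (tt[inhal] - t0[inhal]) / (t1[inhal] - t0[inhal])
  ph[!inhal] <- pi + pi * (tt[!inhal] - t1[!inhal]) / (t2[!inhal] - t1[!inhal])
  phase[ok] <- ph %% (2 * pi)
  phase
}

# Assign per-cell response classes and per-odor polarities for one region.
# Suppressed-type cells are sampled with probability proportional to their
# spontaneous rate; breadth constants calibrated so that per-odor response
# fractions hit the configured targets while ~19% / ~29% of cells end up
# activated-only / suppressed-only.
assign_classes <- function(unit_ids, rates, odors, cfg) {
  n <- length(unit_ids)
  both <- cfg$frac_activated > 0 && cfg$frac_suppressed > 0
  n_m <- if (both) round(cfg$frac_mixed * n) else 0L
  breadth_act <- 2.84
  breadth_sup <- 2.18
  n_a <- if (cfg$frac_activated > 0)
    round(cfg$frac_activated * breadth_act * n) else 0L
  n_s <- if (cfg$frac_suppressed > 0)
    round(cfg$frac_suppressed * breadth_sup * n) else 0L
  # broadly tuned configs can exceed the population; shrink both classes
  # proportionally (their per-odor response probabilities rise to compensate)
  if (n_a + n_s > n - n_m) {
    sc <- (n - n_m) / (n_a + n_s)
    n_a <- floor(n_a * sc)
    n_s <- floor(n_s * sc)
  }

  idx <- seq_len(n)
  mixed <- if (n_m > 0) sample(idx, n_m) else integer(0)
  rest <- setdiff(idx, mixed)
  sup <- if (n_s > 0) {
    elig <- rest[rates[rest] >= cfg$suppression_min_rate]
    if (length(elig) < n_s)   # fall back to the highest-rate remainder
      elig <- rest[order(rates[rest], decreasing = TRUE)][seq_len(min(n_s, length(rest)))]
    w <- rates[elig]
    elig[sample.int(length(elig), min(n_s, length(elig)), prob = w / sum(w))]
  } else integer(0)
  rest2 <- setdiff(rest, sup)
  act <- if (n_a > 0) sample(rest2, min(n_a, length(rest2))) else integer(0)

  n_od <- length(odors)
  # expected activated/suppressed odors per mixed cell under the scheme below
  q_mix <- 0.25 + (0.75 ^ n_od) / n_od
  q_a <- if (length(act) > 0)
    min(1, max(0, (cfg$frac_activated * n - n_m * q_mix) / length(act))) else 0
  q_s <- if (length(sup) > 0)
    min(1, max(0, (cfg$frac_suppressed * n - n_m * q_mix) / length(sup))) else 0

  pairs <- list()
  add <- function(cells, odor, polarity) {
    if (length(cells) > 0)
      pairs[[length(pairs) + 1L]] <<- data.frame(
        unit_id = unit_ids[cells], odorant = odor, polarity = polarity)
  }
  for (od in odors) {
    add(act[stats::runif(length(act)) < q_a], od, "activated")
    add(sup[stats::runif(length(sup)) < q_s], od, "suppressed")
  }
  for (cell in mixed) {
    status <- sample(c("activated", "suppressed", "none"), n_od,
                     replace = TRUE, prob = c(0.25, 0.25, 0.5))
    if (!any(status == "activated")) status[sample.int(n_od, 1)] <- "activated"
    if (!any(status == "suppressed")) {
      free <- which(status != "activated")
      status[free[sample.int(length(free), 1)]] <- "suppressed"
    }
    for (j in which(status != "none")) add(cell, odors[j], status[j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(unit_id = character(0), odorant = character(0),
               polarity = character(0))

  class4 <- rep("unresponsive", n)
  class4[act] <- "activated"
  class4[sup] <- "suppressed"
  class4[mixed] <- "mixed"
  # cells with no realized responsive odor revert to unresponsive
  responsive <- unit_ids %in% pairs$unit_id
  class4[!responsive] <- "unresponsive"
  list(pairs = pairs, class = class4)
}

# Latency component means per concentration for one activated pair.
pair_latencies <- function(component, region, cfg) {
  nc <- length(cfg$concentrations)
  if (component == "early") {
    ep <- if (region == "OB") cfg$early_phase_ob else cfg$early_phase_pcx
    rep(max(0.02, min(0.45, stats::rnorm(1, ep[1], ep[2]))), nc)
  } else if (component == "late") {
    base <- if (region == "OB") cfg$late_phase_means_ob else cfg$late_phase_means_pcx
    pmax(0.02, pmin(0.48, base + stats::rnorm(1, 0, cfg$late_phase_sd)))
  } else {
    rep(max(0.02, min(0.48, stats::rnorm(1, cfg$late_tail["mean"],
                                         cfg$late_tail["sd"]))), nc)
  }
}

suppression_factor_at <- function(conc, cfg) {
  dec <- log10(conc / min(cfg$concentrations))
  pmax(0.02, pmin(1, cfg$suppression_factor -
                    cfg$suppression_gain_per_logconc * dec))
}

#' Generate a synthetic population spike-train dataset
#'
#' Simulates extracellular spike trains for populations of piriform cortex and
#' olfactory bulb units responding to a 12-stimulus odor panel (six odorants,
#' two of them presented at four concentrations) plus a mineral-oil blank.
#' Spontaneous spiking is inhomogeneous Poisson at each cell's log-normal rate
#' with a weak, uniformly distributed sniff-phase preference. Activated
#' cell-odor pairs add a Gaussian firing-rate transient whose center latency is
#' drawn from the pair's assigned latency component (early: concentration
#' invariant; late: advancing with concentration; tail: slow, invariant), with
#' per-trial latency jitter. Suppressed pairs multiply the spontaneous rate
#' within the first sniff by a factor < 1 that decreases with concentration.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical config and
#'   seed yield a bit-identical dataset.
#' @return An object of class `odor_dataset`: a list with `spikes`
#'   (unit_id, time_s), `units` (unit_id, region, population_id, spont_rate_hz,
#'   phase_pref, class), `trials` (trial_id, odorant, concentration,
#'   inhalation_onset_s, odor_onset_s, is_blank), `breaths` (breath_events for
#'   the whole recording), `ground_truth` (pairs, latencies, suppression) and
#'   the `config`.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  panel <- stimulus_panel(cfg)
  n_trials <- nrow(panel) * cfg$n_trials_per_stimulus
  stim_idx <- sample(rep(seq_len(nrow(panel)), cfg$n_trials_per_stimulus))

  # continuous breath grid covering the recording
  total_dur <- n_trials * cfg$trial_interval + 4
  n_breaths <- ceiling(total_dur / (cfg$breath_period - 3 * cfg$breath_period_sd)) + 4
  periods <- pmax(0.15, stats::rnorm(n_breaths, cfg$breath_period,
                                     cfg$breath_period_sd))
  inh <- 0.2 + cumsum(c(0, periods))
  exh <- inh[-length(inh)] + 0.45 * periods
  breaths <- breath_events(inh, exh)

  sched <- 1 + (seq_len(n_trials) - 1) * cfg$trial_interval
  onset_idx <- findInterval(sched, inh) + 1L
  onset <- inh[onset_idx]
  trials <- data.frame(
    trial_id = sprintf("t%03d", seq_len(n_trials)),
    odorant = panel$odorant[stim_idx],
    concentration = panel$concentration[stim_idx],
    inhalation_onset_s = onset,
    odor_onset_s = exh[pmax(onset_idx - 1L, 1L)],
    is_blank = panel$is_blank[stim_idx])
  sniff_end <- inh[onset_idx + 1L]

  regions <- c(rep("PCx", cfg$n_cells_pcx), rep("OB", cfg$n_cells_ob),
               rep("VGAT", cfg$n_cells_vgat))
  n_units <- length(regions)
  pops <- c(
    if (cfg$n_cells_pcx) sprintf("PCx_pop%02d", rep_len(seq_len(cfg$n_populations_pcx), cfg$n_cells_pcx)),
    if (cfg$n_cells_ob) sprintf("OB_pop%02d", rep_len(seq_len(cfg$n_populations_ob), cfg$n_cells_ob)),
    if (cfg$n_cells_vgat) rep("VGAT_pop01", cfg$n_cells_vgat))
  units <- data.frame(
    unit_id = sprintf("%s_%03d", tolower(regions), stats::ave(seq_len(n_units), regions, FUN = seq_along)),
    region = regions,
    population_id = pops,
    spont_rate_hz = stats::rlnorm(n_units, cfg$spont_lognormal[1],
                                  cfg$spont_lognormal[2]),
    phase_pref = stats::runif(n_units, 0, 2 * pi))

  odors <- default_odorant_names(cfg$n_odorants)
  gt_pairs <- list(); cls <- rep("unresponsive", n_units)
  for (rg in c("PCx", "OB")) {
    sel <- which(units$region == rg)
    if (!length(sel)) next
    cfg_rg <- cfg
    if (rg == "OB") {
      cfg_rg$frac_activated <- cfg$ob_response_fractions[["activated"]]
      cfg_rg$frac_suppressed <- cfg$ob_response_fractions[["suppressed"]]
    }
    a <- assign_classes(units$unit_id[sel], units$spont_rate_hz[sel], odors,
                        cfg_rg)
    cls[sel] <- a$class
    gt_pairs[[rg]] <- a$pairs
  }
  if (cfg$n_cells_vgat > 0) {
    sel <- which(units$region == "VGAT")
    cls[sel] <- "activated"
    vg <- expand.grid(unit_id = units$unit_id[sel], odorant = odors,
                      stringsAsFactors = FALSE)
    vg <- vg[stats::runif(nrow(vg)) < 0.8, ]
    vg$polarity <- "activated"
    gt_pairs[["VGAT"]] <- vg[, c("unit_id", "odorant", "polarity")]
  }
  pairs <- do.call(rbind, gt_pairs)
  rownames(pairs) <- NULL
  units$class <- cls

  # per-pair response parameters
  nP <- nrow(pairs)
  pairs$component <- rep(NA_character_, nP)
  pairs$amplitude_hz <- rep(NA_real_, nP)
  pairs$duration_sd_s <- rep(NA_real_, nP)
  lat_rows <- list(); sup_rows <- list()
  if (nP > 0) {
    reg_of <- units$region[match(pairs$unit_id, units$unit_id)]
    for (i in seq_len(nP)) {
      if (pairs$polarity[i] == "activated") {
        if (reg_of[i] == "VGAT") {
          pairs$component[i] <- "early"
          mus <- seq(0.091, 0.065, length.out = length(cfg$concentrations))
          dur <- cfg$response_duration_sd *
            seq(89 / 43, 50 / 43, length.out = length(cfg$concentrations))
        } else {
          pairs$component[i] <- sample(names(cfg$component_weights), 1,
                                       prob = cfg$component_weights)
          mus <- pair_latencies(pairs$component[i], reg_of[i], cfg)
          dur <- rep(cfg$response_duration_sd * exp(stats::rnorm(1, 0, 0.45)),
                     length(cfg$concentrations))
        }
        pairs$amplitude_hz[i] <- stats::rlnorm(1, cfg$response_peak_rate[1],
                                               cfg$response_peak_rate[2])
        pairs$duration_sd_s[i] <- dur[1]
        lat_rows[[length(lat_rows) + 1L]] <- data.frame(
          unit_id = pairs$unit_id[i], odorant = pairs$odorant[i],
          concentration = cfg$concentrations, latency_s = mus,
          duration_sd_s = dur)
      } else {
        sup_rows[[length(sup_rows) + 1L]] <- data.frame(
          unit_id = pairs$unit_id[i], odorant = pairs$odorant[i],
          concentration = cfg$concentrations,
          factor = suppression_factor_at(cfg$concentrations, cfg))
      }
    }
  }
  gt_lat <- if (length(lat_rows)) do.call(rbind, lat_rows) else
    data.frame(unit_id = character(0), odorant = character(0),
               concentration = numeric(0), latency_s = numeric(0),
               duration_sd_s = numeric(0))
  gt_sup <- if (length(sup_rows)) do.call(rbind, sup_rows) else
    data.frame(unit_id = character(0), odorant = character(0),
               concentration = numeric(0), factor = numeric(0))

  # spike generation
  w0 <- cfg$trial_window[1]; w1 <- cfg$trial_window[2]
  len <- w1 - w0
  m <- cfg$phase_modulation_depth
  conc_key <- function(od, cc) paste(od, signif(cc, 6))
  trial_key <- conc_key(trials$odorant, trials$concentration)

  spk_unit <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    r0 <- units$spont_rate_hz[u]
    theta <- units$phase_pref[u]
    # background (inhomogeneous Poisson via thinning of rate r0 * (1 + m))
    nb <- stats::rpois(1, r0 * (1 + m) * len * n_trials)
    tt <- numeric(0)
    if (nb > 0) {
      uu <- stats::runif(nb, 0, len * n_trials)
      tr <- pmin(floor(uu / len) + 1L, n_trials)
      tabs <- onset[tr] + w0 + uu %% len
      ph <- breath_phase_at(tabs, inh, exh)
      acc <- (1 + m * cos(ph - theta)) / (1 + m)
      acc[is.na(acc)] <- 1 / (1 + m)
      keep <- stats::runif(nb) < acc
      tabs <- tabs[keep]; tr <- tr[keep]
      # multiplicative suppression within the first sniff
      up <- pairs$unit_id == units$unit_id[u] & pairs$polarity == "suppressed"
      if (any(up)) {
        sup_u <- gt_sup[gt_sup$unit_id == units$unit_id[u], ]
        fac <- rep(1, length(tabs))
        key <- trial_key[tr]
        mkey <- match(key, conc_key(sup_u$odorant, sup_u$concentration))
        in_sniff <- tabs >= onset[tr] + cfg$suppression_onset &
          tabs < sniff_end[tr]
        hit <- !is.na(mkey) & in_sniff
        fac[hit] <- sup_u$factor[mkey[hit]]
        keep2 <- stats::runif(length(tabs)) < fac
        tabs <- tabs[keep2]
      }
      tt <- tabs
    }
    # additive response transients for activated pairs
    up <- which(pairs$unit_id == units$unit_id[u] & pairs$polarity == "activated")
    if (length(up)) {
      lat_u <- gt_lat[gt_lat$unit_id == units$unit_id[u], ]
      for (j in up) {
        lat_j <- lat_u[lat_u$odorant == pairs$odorant[j], ]
        trj <- which(trials$odorant == pairs$odorant[j])
        for (k in trj) {
          row <- which(abs(lat_j$concentration - trials$concentration[k]) < 1e-12)
          if (!length(row)) next
          sdd <- lat_j$duration_sd_s[row]
          ctr <- onset[k] + lat_j$latency_s[row] +
            stats::rnorm(1, 0, cfg$latency_jitter_sd)
          nr <- stats::rpois(1, pairs$amplitude_hz[j] * sdd * sqrt(2 * pi))
          if (nr > 0) {
            ts <- stats::rnorm(nr, ctr, sdd)
            ts <- ts[ts > onset[k] + 0.002 & ts < onset[k] + w1]
            tt <- c(tt, ts)
          }
        }
      }
    }
    if (length(tt))
      spk_unit[[u]] <- data.frame(unit_id = units$unit_id[u], time_s = sort(tt))
  }
  spikes <- do.call(rbind, spk_unit[!vapply(spk_unit, is.null, logical(1))])
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), time_s = numeric(0))
  rownames(spikes) <- NULL

  structure(list(spikes = spikes, units = units, trials = trials,
                 breaths = breaths,
                 ground_truth = list(pairs = pairs, latencies = gt_lat,
                                     suppression = gt_sup),
                 config = cfg),
            class = "odor_dataset")
}

#' @export
print.odor_dataset <- function(x, ...) {
  cat(sprintf("<odor_dataset> %d units (%s), %d trials, %d spikes\n",
              nrow(x$units),
              paste(sprintf("%s: %d", names(table(x$units$region)),
                            table(x$units$region)), collapse = ", "),
              nrow(x$trials), nrow(x$spikes)))
  invisible(x)
}

#' Draw peak latencies from the generator's three-component mixture
#'
#' Samples response-latency values directly from the latency model used by the
#' generator at a given region and concentration: an early
#' concentration-invariant component, a late component whose mean decreases
#' with concentration, and a slow tail, each a Gaussian truncated to
#' \[0, 0.5\] s (rejection sampling).
#'
#' @param n sample size.
#' @param config a [synth_config()].
#' @param region `"PCx"` or `"OB"`.
#' @param concentration one of `config$concentrations`.
#' @param seed optional seed.
#' @return numeric vector of latencies (s) with a `"component"` attribute.
#' @export
sample_peak_latencies <- function(n, config, region = "PCx",
                                  concentration = config$concentrations[3],
                                  seed = NULL) {
  par <- latency_mixture_params(config, region, concentration)
  with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = par$p)
    x <- stats::rnorm(n, par$mu[comp], par$sigma[comp])
    bad <- which(x < 0 | x > 0.5)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), par$mu[comp[bad]], par$sigma[comp[bad]])
      bad <- bad[x[bad] < 0 | x[bad] > 0.5]
    }
    attr(x, "component") <- comp
    x
  })
}

#' Generating mixture parameters of the latency model
#'
#' @inheritParams sample_peak_latencies
#' @return list with `p`, `mu`, `sigma` (components ordered by increasing mean).
#' @export
latency_mixture_params <- function(config, region = "PCx",
                                   concentration = config$concentrations[3]) {
  ci <- which(abs(config$concentrations - concentration) < 1e-12)
  if (!length(ci)) stopf("concentration %g not in config", concentration)
  ep <- if (region == "OB") config$early_phase_ob else config$early_phase_pcx
  lm_ <- if (region == "OB") config$late_phase_means_ob else config$late_phase_means_pcx
  list(p = unname(config$component_weights),
       mu = unname(c(ep[1], lm_[ci], config$late_tail["mean"])),
       sigma = unname(c(ep[2], config$late_phase_sd, config$late_tail["sd"])))
}

#' Generate a synthetic respiration trace
#'
#' Produces a quasi-periodic airflow-like signal whose negative lobes mark
#' inhalation (matching the sign convention of a mass-airflow sensor) together
#' with the ground-truth inhalation and exhalation onset times.
#'
#' @param duration trace duration (s); must be > 0.
#' @param breath_period,period_sd mean and SD (s) of the breath period.
#' @param sampling_rate samples per second (default 2000).
#' @param amplitude signal amplitude; 0 gives a flat trace.
#' @param amplitude_sd per-breath amplitude jitter (fraction of amplitude).
#' @param noise_sd additive Gaussian noise SD (fraction of amplitude).
#' @param inhale_frac fraction of the cycle occupied by inhalation.
#' @param seed optional seed.
#' @return A `respiration_trace`: list with `samples`, `sampling_rate`, and
#'   ground-truth `inhalation_onsets` / `exhalation_onsets` (s).
#' @export
generate_respiration_trace <- function(duration, breath_period = 0.4,
                                       period_sd = 0, sampling_rate = 2000,
                                       amplitude = 1, amplitude_sd = 0,
                                       noise_sd = 0, inhale_frac = 0.5,
                                       seed = NULL) {
  if (duration <= 0) stopf("duration must be > 0")
  with_seed(seed, {
    nb <- ceiling(duration / max(breath_period - 3 * period_sd, 0.05)) + 2
    periods <- pmax(0.05, stats::rnorm(nb, breath_period, period_sd))
    starts <- cumsum(c(0, periods))
    t <- seq(0, duration, by = 1 / sampling_rate)
    i <- pmax(findInterval(t, starts), 1L)
    tau <- t - starts[i]
    d_in <- inhale_frac * periods[i]
    d_ex <- periods[i] - d_in
    amp <- amplitude * pmax(0, 1 + stats::rnorm(nb, 0, amplitude_sd))[i]
    x <- ifelse(tau < d_in,
                -amp * sin(pi * tau / d_in),
                amp * sin(pi * (tau - d_in) / d_ex))
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd * amplitude)
    inh_t <- starts[starts < duration]
    exh_all <- starts[seq_len(nb)] + inhale_frac * periods
    exh_t <- exh_all[exh_all < duration]
    structure(list(samples = x, sampling_rate = sampling_rate,
                   inhalation_onsets = inh_t, exhalation_onsets = exh_t),
              class = "respiration_trace")
  })
}
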