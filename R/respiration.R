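#' Breath-event container
#'
#' @param inhalation_onsets,exhalation_onsets strictly increasing times (s);
#'   events must alternate (each exhalation onset lies between the inhalation
#'   onset that precedes it and the next one).
#' @return object of class `breath_events`.
#' @export
breath_events <- function(inhalation_onsets, exhalation_onsets) {
  if (is.unsorted(inhalation_onsets, strictly = TRUE) ||
      is.unsorted(exhalation_onsets, strictly = TRUE))
    stopf("breath onsets must be strictly increasing")
  ev <- structure(list(inhalation_onsets = inhalation_onsets,
                       exhalation_onsets = exhalation_onsets),
                  class = "breath_events")
  stopifnot(breath_events_alternate(ev))
  ev
}

# TRUE when every exhalation onset lies strictly between consecutive
# inhalation onsets.
breath_events_alternate <- function(events) {
  inh <- events$inhalation_onsets
  exh <- events$exhalation_onsets
  if (!length(exh)) return(TRUE)
  idx <- findInterval(exh, inh)
  all(idx >= 1) && !anyDuplicated(idx) &&
    all(exh > inh[idx]) &&
    all(idx == length(inh) | exh < c(inh, Inf)[idx + 1L])
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf("<breath_events> %d inhalations, %d exhalations\n",
              length(x$inhalation_onsets), length(x$exhalation_onsets)))
  invisible(x)
}

# Local detrending in overlapping windows; overlapping estimates are averaged
# with triangular weights. Default order 0 subtracts blended window means:
# the triangular blend interpolates the means linearly between window centers,
# so slow (including linear) drift is still removed, while an order-1 fit
# would systematically tilt windows holding only a few respiration cycles
# (the time-sine covariance over a finite window is nonzero).
local_detrend <- function(x, fs, window = 1.5, overlap = 1.0, order = 0) {
  n <- length(x)
  wlen <- max(round(window * fs), 4L)
  step <- max(round((window - overlap) * fs), 1L)
  trend <- numeric(n)
  wsum <- numeric(n)
  starts <- unique(c(seq(1L, max(n - wlen + 1L, 1L), by = step),
                     max(n - wlen + 1L, 1L)))
  tri <- {
    k <- min(wlen, n)
    w <- 1 - abs(seq_len(k) - (k + 1) / 2) / ((k + 1) / 2)
    pmax(w, 1e-3)
  }
  for (s in starts) {
    e <- min(s + wlen - 1L, n)
    idx <- s:e
    tloc <- seq_along(idx)
    fitted <- if (order == 0) rep(mean(x[idx]), length(idx)) else {
      basis <- cbind(1, outer(tloc / length(tloc), seq_len(order), `^`))
      drop(basis %*% stats::lm.fit(basis, x[idx])$coefficients)
    }
    w <- tri[seq_along(idx)]
    trend[idx] <- trend[idx] + w * fitted
    wsum[idx] <- wsum[idx] + w
  }
  x - trend / pmax(wsum, 1e-12)
}

# linearly interpolated zero-crossing time between samples i and i+1
cross_time <- function(x, i, fs) {
  (i - 1 + x[i] / (x[i] - x[i + 1L])) / fs
}

#' Detect inhalation and exhalation onsets from a respiration trace
#'
#' Smooths the trace with a second-order Savitzky-Golay filter (200 ms frames
#' by default), locally detrends it in overlapping windows (1.5 s windows with
#' 1 s overlap by default), locates large negative peaks, and marks the
#' zero-crossing preceding each accepted trough as an inhalation onset and the
#' following zero-crossing as an exhalation onset. "Large" means a trough depth
#' of at least `peak_prominence` times the median depth of all sub-zero local
#' minima (the amplitude criterion is configurable because airflow units are
#' arbitrary).
#'
#' @param trace a `respiration_trace`, or a list with `samples` and
#'   `sampling_rate`, or a numeric vector (then `sampling_rate` is used).
#' @param smooth_window Savitzky-Golay frame length (s).
#' @param detrend_window,detrend_overlap local detrending window and overlap (s).
#' @param detrend_order polynomial order of the local detrend (default 0:
#'   overlap-blended window means, which still track linear drift; see
#'   `local_detrend`).
#' @param peak_prominence fraction of the median trough depth a negative peak
#'   must reach to count as a breath.
#' @param sampling_rate Hz, used when `trace` is a bare numeric vector.
#' @return a [breath_events()] object; empty when no negative peaks are found.
#' @export
detect_breaths <- function(trace, smooth_window = 0.2, detrend_window = 1.5,
                           detrend_overlap = 1.0, peak_prominence = 0.5,
                           detrend_order = 0, sampling_rate = 2000) {
  if (is.numeric(trace)) trace <- list(samples = trace, sampling_rate = sampling_rate)
  x <- as.numeric(trace$samples)
  fs <- trace$sampling_rate
  if (any(!is.finite(x))) stopf("respiration trace contains non-finite samples")
  frame <- round(smooth_window * fs)
  if (frame %% 2 == 0) frame <- frame + 1L
  if (length(x) < frame) stopf("trace shorter than one smoothing frame")
  # odd (point-symmetric) reflection padding keeps filter and detrending edge
  # transients out of the analyzed span while continuing oscillations smoothly
  np <- min(length(x) - 1L, round(detrend_window * fs))
  n <- length(x)
  xp <- c(2 * x[1] - rev(x[2:(np + 1L)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1L)]))
  xs <- signal::sgolayfilt(xp, p = 2, n = frame)
  xs <- local_detrend(xs, fs, detrend_window, detrend_overlap, detrend_order)

  empty <- breath_events(numeric(0), numeric(0))
  d <- diff(xs)
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  # troughs must lie in the unpadded span; their flanking zero-crossings may
  # fall just inside the padding (a breath starting at the trace boundary)
  mins <- mins[mins > np & mins <= np + length(x)]
  # depth floor rejects numerical fuzz on flat traces
  mins <- mins[xs[mins] < -(1e-9 + 1e-7 * max(abs(xs)))]
  if (!length(mins)) return(empty)
  depth <- -xs[mins]
  mins <- mins[depth >= peak_prominence * stats::median(depth)]
  if (!length(mins)) return(empty)

  sgn <- xs >= 0
  down <- which(sgn[-length(sgn)] & !sgn[-1])   # + -> - between i, i+1
  up <- which(!sgn[-length(sgn)] & sgn[-1])     # - -> + between i, i+1
  inh_i <- vapply(mins, function(i) {
    j <- down[down < i]
    if (length(j)) j[length(j)] else NA_integer_
  }, integer(1))
  exh_i <- vapply(mins, function(i) {
    j <- up[up >= i]
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  ok <- !is.na(inh_i) & !is.na(exh_i)
  if (!any(ok)) return(empty)
  key <- paste(inh_i[ok], exh_i[ok])   # merge troughs sharing both crossings
  keep <- !duplicated(key)
  inh_i <- inh_i[ok][keep]; exh_i <- exh_i[ok][keep]
  dur <- (length(x) - 1) / fs
  inh_t <- pmin(pmax(cross_time(xs, inh_i, fs) - np / fs, 0), dur)
  exh_t <- pmin(pmax(cross_time(xs, exh_i, fs) - np / fs, 0), dur)
  o <- order(inh_t)
  inh_t <- inh_t[o]; exh_t <- exh_t[o]
  dup <- duplicated(inh_t)
  breath_events(inh_t[!dup], exh_t[!dup])
}

#' Sniff phase of spike times
#'
#' Assigns each spike a phase in the respiration cycle by linear interpolation
#' between 0 (start of inhalation) and pi (start of exhalation), continuing
#' from pi to 2*pi across exhalation up to the next inhalation onset. Spikes
#' outside the coverage of the breath events get `NA`.
#'
#' @param spike_times numeric vector of times (s).
#' @param events a [breath_events()] object.
#' @return numeric vector of phases in `[0, 2*pi)` (NA outside coverage).
#' @export
spike_phase <- function(spike_times, events) {
  breath_phase_at(spike_times, events$inhalation_onsets,
                  events$exhalation_onsets)
}

#' Normalized sniff-phase histogram
#'
#' @param phases numeric phases in `[0, 2*pi)`; NAs are dropped.
#' @param bin_width_deg bin width in degrees; must divide 360 (default 10,
#'   giving 36 bins).
#' @return data.frame with bin midpoints (radians) and the normalized density
#'   per bin (sums to 1; all zero for an empty phase list).
#' @export
phase_histogram <- function(phases, bin_width_deg = 10) {
  if (360 %% bin_width_deg != 0) stopf("bin width must divide 360 degrees")
  nb <- 360 %/% bin_width_deg
  breaks <- seq(0, 2 * pi, length.out = nb + 1L)
  phases <- phases[!is.na(phases)] %% (2 * pi)
  counts <- if (length(phases))
    tabulate(pmin(findInterval(phases, breaks, rightmost.closed = TRUE), nb), nb)
  else rep(0L, nb)
  dens <- if (sum(counts) > 0) counts / sum(counts) else rep(0, nb)
  data.frame(phase = (breaks[-1] + breaks[-(nb + 1)]) / 2,
             proportion = dens, count = counts)
}
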