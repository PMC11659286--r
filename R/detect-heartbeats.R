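#' Heartbeat-detection configuration
#'
#' @param channel Preferred cardiac channel; when absent the breath channel
#'   is used (the cardiogenic oscillation rides on it).
#' @param fallback_channel Channel used when `channel` is missing.
#' @param band_hz Cardiac band-pass edges in Hz; the default 4-12 Hz spans
#'   240-720 beats/min, the neonatal mouse range.
#' @param peak_frac Peak threshold as a fraction of the robust (95th
#'   percentile) band-passed amplitude.
#' @param refractory_frac Refractory period as a fraction of the running
#'   median inter-beat interval (default 0.6).
#' @param hr_grid_hz Output grid for the instantaneous heart-rate series.
#' @param hr_gap_max Seconds without beats after which the heart-rate series
#'   is marked undefined (needed during apnea, not an error).
#' @return List of class `beat_cfg`.
#' @export
beat_cfg <- function(channel = "cardiac", fallback_channel = "breath",
                     band_hz = c(4, 12), peak_frac = 0.3,
                     refractory_frac = 0.6, hr_grid_hz = 10,
                     hr_gap_max = 5) {
  structure(as.list(environment()), class = "beat_cfg")
}

#' Detect heartbeats and derive an instantaneous heart-rate series
#'
#' Band-pass filters the cardiac (or breath) channel around the configured
#' cardiac band, detects peaks with sub-sample parabolic refinement and a
#' refractory period of `refractory_frac` times the running median
#' inter-beat interval, and linearly interpolates `60 / IBI` onto a uniform
#' grid. Grid points farther than `hr_gap_max` from any beat are `NA`.
#'
#' @param rec A [trace_recording()].
#' @param cfg A [beat_cfg()].
#' @return List of class `beat_series`: `beat_times` (s) and `hr`, a tibble
#'   `time_s`, `hr_bpm` on the uniform grid.
#' @export
detect_heartbeats <- function(rec, cfg = beat_cfg()) {
  stopifnot(inherits(rec, "trace_recording"))
  x <- rec_channel(rec, cfg$channel, required = FALSE)
  if (is.null(x)) x <- rec_channel(rec, cfg$fallback_channel)
  fs <- rec$sample_rate
  t <- rec$signals$time_s
  grid <- seq(0, max(t), by = 1 / cfg$hr_grid_hz)
  empty <- structure(
    list(beat_times = numeric(),
         hr = tibble(time_s = grid, hr_bpm = NA_real_)),
    class = "beat_series"
  )
  ny <- fs / 2
  bp <- signal::butter(2, pmin(cfg$band_hz / ny, 0.999), type = "pass")
  xf <- signal::filtfilt(bp, x)
  thr <- cfg$peak_frac * quantile(abs(xf), 0.95, names = FALSE)
  if (thr <= 0 || sd(xf) == 0) {
    warn("no cardiac signal found; heart rate undefined.")
    return(empty)
  }
  n <- length(xf)
  is_pk <- which(xf[2:(n - 1)] > thr &
                   xf[2:(n - 1)] >= xf[1:(n - 2)] &
                   xf[2:(n - 1)] > xf[3:n]) + 1L
  if (length(is_pk) < 3) {
    warn("no cardiac peaks found; heart rate undefined.")
    return(empty)
  }
  # sub-sample parabolic refinement of peak times
  y0 <- xf[is_pk - 1]; y1 <- xf[is_pk]; y2 <- xf[is_pk + 1]
  denom <- y0 - 2 * y1 + y2
  shift <- ifelse(denom < 0, 0.5 * (y0 - y2) / denom, 0)
  pk_t <- t[is_pk] + shift / fs

  # refractory screen with a running median IBI
  kept <- numeric(length(pk_t))
  kept[1] <- pk_t[1]
  m <- 1
  recent <- rep(median(diff(pk_t)), 11)
  for (i in 2:length(pk_t)) {
    gap <- pk_t[i] - kept[m]
    if (gap >= cfg$refractory_frac * median(recent)) {
      m <- m + 1
      kept[m] <- pk_t[i]
      if (gap < cfg$hr_gap_max) recent <- c(recent[-1], gap)
    }
  }
  beat_times <- kept[seq_len(m)]
  if (m < 3) {
    warn("too few beats for a heart-rate series.")
    return(empty)
  }
  ibi <- diff(beat_times)
  mid <- beat_times[-length(beat_times)] + ibi / 2
  ok <- ibi <= cfg$hr_gap_max
  hr_bpm <- approx(mid[ok], 60 / ibi[ok], xout = grid, rule = 1)$y
  # undefined wherever the nearest beat is farther than hr_gap_max
  gap_start <- beat_times[-length(beat_times)][!ok]
  gap_end <- beat_times[-1][!ok]
  if (length(gap_start)) {
    for (g in seq_along(gap_start)) {
      hr_bpm[grid > gap_start[g] & grid < gap_end[g]] <- NA_real_
    }
  }
  structure(
    list(beat_times = beat_times, hr = tibble(time_s = grid, hr_bpm = hr_bpm)),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat("<beat_series> ", length(x$beat_times), " beats",
      if (length(x$beat_times) > 1) {
        paste0(", mean HR ",
               round(60 / mean(diff(x$beat_times)), 1), " bpm")
      }, "\n", sep = "")
  invisible(x)
}

#' Instantaneous ventilatory frequency on a uniform grid
#'
#' Converts breath onsets into an instantaneous rate series (60 / IBI at
#' interval midpoints, linearly interpolated), the ventilatory counterpart
#' of the heart-rate series used for recovery-latency tracking. Intervals
#' longer than `gap_max` (apneas) contribute their true, low rate rather
#' than `NA` so that recovery crossings are well defined.
#'
#' @param onsets Breath onset times, s (gasps included).
#' @param t_end End of the grid, s.
#' @param grid_hz Grid rate, Hz (default 10).
#' @param gap_max Intervals longer than this are rendered as rate plateaus at
#'   `60 / ibi` rather than interpolated ramps.
#' @return Tibble `time_s`, `vf_bpm`.
#' @export
vf_series <- function(onsets, t_end, grid_hz = 10, gap_max = 30) {
  grid <- seq(0, t_end, by = 1 / grid_hz)
  if (length(onsets) < 3) {
    return(tibble(time_s = grid, vf_bpm = NA_real_))
  }
  onsets <- sort(onsets)
  ibi <- diff(onsets)
  mid <- onsets[-length(onsets)] + ibi / 2
  vf <- approx(mid, 60 / ibi, xout = grid, rule = 2)$y
  tibble(time_s = grid, vf_bpm = vf)
}
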