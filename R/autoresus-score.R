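#' Recovery latency of a gridded signal
#'
#' Smallest `t - t0` at which the series reaches `fraction * baseline_value`,
#' with the first grid crossing refined by linear interpolation between the
#' bracketing samples. Returns 0 when the series is already at or above the
#' threshold at `t0`, and `NA` when no crossing occurs before the series (or
#' the supplied `t_max`) ends. Leading `NA` stretches (e.g. heart rate
#' undefined during apnea) are skipped.
#'
#' @param series Tibble whose first column is `time_s` and second the signal
#'   (e.g. `hr_bpm` or `vf_bpm`).
#' @param baseline_value Baseline the fraction refers to (> 0).
#' @param fraction Recovery fraction in (0, 1); the study uses 0.63 for
#'   heart rate and 0.50 for ventilatory frequency.
#' @param t0 Origin of the latency (the first gasp).
#' @param t_max Ignore crossings at or beyond this time (the next challenge).
#' @return Latency in seconds, 0, or `NA`.
#' @export
recovery_latency <- function(series, baseline_value, fraction, t0,
                             t_max = Inf) {
  if (!is.finite(baseline_value) || baseline_value <= 0) {
    abort("`baseline_value` must be positive.")
  }
  stopifnot(fraction > 0, fraction < 1)
  tt <- series[[1]]
  y <- series[[2]]
  sel <- tt >= t0 & tt < t_max
  tt <- tt[sel]; y <- y[sel]
  def <- !is.na(y)
  if (!any(def)) return(NA_real_)
  thr <- fraction * baseline_value
  first_def <- which(def)[1]
  if (y[first_def] >= thr && tt[first_def] <= t0 + (tt[2] - tt[1])) return(0)
  above <- def & y >= thr
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(tt[1] - t0)
  if (is.na(y[i - 1])) return(tt[i] - t0)
  # linear interpolation between the bracketing grid points
  t_cross <- tt[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) *
    (tt[i] - tt[i - 1])
  max(0, t_cross - t0)
}

#' Baseline cardiorespiratory values before the first challenge
#'
#' Means over calm breaths and defined heart rate within the baseline window
#' (by default the last 120 s before the first anoxic switch).
#'
#' @param breaths Calm-flagged breath tibble (VT column optional).
#' @param beats A `beat_series` from [detect_heartbeats()].
#' @param baseline_end Time of the first anoxic switch, s.
#' @param window Baseline window length, s; the window is
#'   `[baseline_end - window, baseline_end)` and must be positive.
#' @return One-row tibble: `vf`, `vt`, `ve`, `hr`, `amp`, `n_breaths`.
#'   Heart rate is `NA` with a warning when undefined throughout.
#' @export
score_baseline <- function(breaths, beats, baseline_end, window = 120) {
  if (window <= 0 || baseline_end <= 0) {
    abort("baseline window must have positive length.")
  }
  lo <- max(0, baseline_end - window)
  b <- breaths[breaths$onset_s >= lo & breaths$onset_s < baseline_end, ]
  if ("calm" %in% names(b)) b <- b[b$calm, ]
  if (nrow(b) < 2) abort("too few calm breaths in the baseline window.")
  vf <- 60 / mean(b$tt_s)
  vt <- if ("vt_ml" %in% names(b)) mean(b$vt_ml) else mean(b$integ_insp)
  hr_w <- beats$hr[beats$hr$time_s >= lo & beats$hr$time_s < baseline_end, ]
  hr <- if (all(is.na(hr_w$hr_bpm))) {
    warn("heart rate undefined throughout baseline; HR metrics disabled.")
    NA_real_
  } else {
    mean(hr_w$hr_bpm, na.rm = TRUE)
  }
  tibble(vf = vf, vt = vt, ve = vf * vt, hr = hr,
         amp = mean(b$amp), n_breaths = nrow(b))
}

#' Apnea onset within one anoxic trial
#'
#' Searching forward from the anoxic switch, the apnea onset is the offset
#' of the last breath that is followed by at least `terminal_apnea_gap`
#' seconds without a detected breath. The induction length is
#' `apnea_onset - switch_time`.
#'
#' @param breaths Breath tibble (gasps included).
#' @param switch_time Anoxic switch, s.
#' @param next_switch Upper bound of the trial window, s.
#' @param terminal_apnea_gap Minimum breath-free gap defining apnea, s
#'   (default 10).
#' @return One-row tibble `apnea_onset_s`, `induction_s`; both `NA` with a
#'   warning when breathing never ceases within the window.
#' @export
detect_apnea_onset <- function(breaths, switch_time, next_switch = Inf,
                               terminal_apnea_gap = 10) {
  b <- breaths[breaths$onset_s < next_switch, ]
  cand <- which(b$onset_s >= switch_time)
  if (length(cand)) {
    next_on <- c(b$onset_s[-1], Inf)
    gaps <- pmin(next_on, next_switch) - b$offset_s
    hit <- cand[gaps[cand] >= terminal_apnea_gap]
    if (length(hit)) {
      onset <- b$offset_s[hit[1]]
      return(tibble(apnea_onset_s = onset,
                    induction_s = onset - switch_time))
    }
  }
  warn("no qualifying apnea before the next challenge; trial unscoreable.")
  tibble(apnea_onset_s = NA_real_, induction_s = NA_real_)
}

#' Gasps within one anoxic trial
#'
#' Gasps are isolated breath-like deflections after apnea onset: amplitude
#' at least `gasp_amp_factor` times the baseline mean amplitude and preceded
#' by at least `gasp_isolation` seconds without breathing.
#'
#' @param breaths Breath tibble.
#' @param apnea_onset Apnea onset, s.
#' @param baseline_amp Baseline mean breath amplitude.
#' @param next_switch Upper bound of the search window.
#' @param gasp_amp_factor Amplitude threshold relative to baseline
#'   (default 0.5).
#' @param gasp_isolation Minimum preceding quiescence, s (default 1).
#' @return Vector of gasp onset times (possibly empty).
#' @export
detect_gasps <- function(breaths, apnea_onset, baseline_amp,
                         next_switch = Inf, gasp_amp_factor = 0.5,
                         gasp_isolation = 1) {
  if (is.na(apnea_onset)) return(numeric())
  prev_off <- c(-Inf, breaths$offset_s[-nrow(breaths)])
  sel <- breaths$onset_s > apnea_onset & breaths$onset_s < next_switch &
    breaths$amp >= gasp_amp_factor * baseline_amp &
    (breaths$onset_s - prev_off) >= gasp_isolation
  breaths$onset_s[sel]
}

#' Score a full autoresuscitation session
#'
#' Runs the whole neonatal pipeline on one recording: breath and heartbeat
#' detection, baseline scoring, and per-trial apnea induction, gasping,
#' heart-rate and ventilatory-frequency recovery latencies (measured from
#' the first gasp), cardiorespiratory decoupling
#' (`decoupling = latency_HR_63 - latency_VF_50`, exactly), and survival
#' (both reported latencies defined before the next challenge). Trials are
#' delimited by `anoxia_<i>` markers.
#'
#' @param rec A [trace_recording()] of a neonatal session.
#' @param breath_cfg,beat_cfg Detection configurations.
#' @param baseline_window Baseline window before the first switch, s.
#' @param terminal_apnea_gap,gasp_amp_factor,gasp_isolation Trial-scoring
#'   parameters, see [detect_apnea_onset()] and [detect_gasps()].
#' @param calm_window Rolling window for calm-breath flagging.
#' @return List of class `autoresus_session`: `baseline` (one-row tibble),
#'   `trials` (per-trial metrics tibble), `episodes_survived`, and
#'   `averages` (across-trial means of each metric).
#' @export
score_session <- function(rec, breath_cfg = pneumotrace::breath_cfg(),
                          beat_cfg = pneumotrace::beat_cfg(),
                          baseline_window = 120, terminal_apnea_gap = 10,
                          gasp_amp_factor = 0.5, gasp_isolation = 1,
                          calm_window = 21) {
  stopifnot(inherits(rec, "trace_recording"))
  switches <- rec$markers |>
    filter(grepl("^anoxia_", .data$label)) |>
    arrange(.data$time_s)
  if (!nrow(switches)) abort("no `anoxia_<i>` markers: cannot delimit trials.")

  breaths <- detect_breaths(rec, breath_cfg) |>
    select_calm_breaths(rec, window = calm_window)
  beats <- detect_heartbeats(rec, beat_cfg)
  base <- score_baseline(breaths, beats, switches$time_s[1],
                         window = baseline_window)
  dur <- rec_duration(rec)
  vf <- vf_series(breaths$onset_s, t_end = dur)
  grid_dt <- 1 / beat_cfg$hr_grid_hz

  n_tr <- nrow(switches)
  bounds <- c(switches$time_s, dur)
  rows <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    sw <- bounds[i]; nx <- bounds[i + 1]
    ap <- detect_apnea_onset(breaths, sw, nx, terminal_apnea_gap)
    gasps <- detect_gasps(breaths, ap$apnea_onset_s, base$amp, nx,
                          gasp_amp_factor, gasp_isolation)
    g1 <- if (length(gasps)) gasps[1] else NA_real_
    lat <- function(series, baseline, frac) {
      if (is.na(g1) || is.na(baseline)) return(NA_real_)
      recovery_latency(series, baseline, frac, t0 = g1, t_max = nx)
    }
    lat_hr63 <- lat(beats$hr, base$hr, 0.63)
    lat_hr50 <- lat(beats$hr, base$hr, 0.50)
    lat_vf50 <- lat(vf, base$vf, 0.50)
    lat_vf63 <- lat(vf, base$vf, 0.63)
    rows[[i]] <- tibble(
      trial = i, switch_s = sw,
      apnea_onset_s = ap$apnea_onset_s, induction_s = ap$induction_s,
      gasp_latency_s = if (!is.na(g1)) g1 - ap$apnea_onset_s else NA_real_,
      inter_gasp_s = if (length(gasps) >= 2) gasps[2] - gasps[1] else NA_real_,
      gasps_per_min = if (length(gasps) >= 2) {
        60 / (gasps[2] - gasps[1])
      } else NA_real_,
      n_gasps = length(gasps),
      lat_hr63_s = lat_hr63, lat_hr50_s = lat_hr50,
      lat_vf50_s = lat_vf50, lat_vf63_s = lat_vf63,
      decoupling_s = lat_hr63 - lat_vf50,
      survived = !is.na(lat_hr63) && !is.na(lat_vf50)
    )
  }
  trials <- list_rbind(rows)
  metric_cols <- c("induction_s", "gasp_latency_s", "inter_gasp_s",
                   "gasps_per_min", "lat_hr63_s", "lat_hr50_s", "lat_vf50_s",
                   "lat_vf63_s", "decoupling_s")
  averages <- trials |>
    summarise(across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  structure(
    list(baseline = base, trials = trials,
         episodes_survived = sum(trials$survived),
         averages = averages),
    class = "autoresus_session"
  )
}

#' @export
print.autoresus_session <- function(x, ...) {
  cat("<autoresus_session> ", nrow(x$trials), " trials, ",
      x$episodes_survived, " survived\n", sep = "")
  cat("  baseline: Vf ", round(x$baseline$vf, 1), " /min, HR ",
      round(x$baseline$hr, 1), " bpm\n", sep = "")
  print(x$trials)
  invisible(x)
}

#' Per-trial metrics of a scored session
#' @param x An `autoresus_session`.
#' @param ... Unused.
#' @return The per-trial metrics tibble.
#' @export
tidy.autoresus_session <- function(x, ...) x$trials

#' One-row session summary
#' @param x An `autoresus_session`.
#' @param ... Unused.
#' @return One-row tibble of baseline values, trial count, episodes
#'   survived, and across-trial metric means.
#' @export
glance.autoresus_session <- function(x, ...) {
  bind_cols(
    x$baseline |> rename_with(~ paste0("baseline_", .x)),
    tibble(n_trials = nrow(x$trials),
           episodes_survived = x$episodes_survived),
    x$averages |> rename_with(~ paste0("mean_", .x))
  )
}
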