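#' Parameters of one simulated anoxic challenge
#'
#' One autoresuscitation trial: anoxia is switched on, breathing ceases after
#' `induction_time` seconds, gasps occur at cumulative `gasp_intervals` after
#' apnea onset, and - if the pup recovers - heart rate and ventilatory
#' frequency rise from their floors toward baseline as `1 - exp(-t/tau)`
#' measured from the first gasp. The next challenge starts `recovery_hold`
#' seconds (default 300, i.e. five minutes) after the first gasp.
#'
#' @param induction_time Seconds of anoxia needed to induce apnea (> 0).
#' @param gasp_intervals Strictly positive gaps (s); the first is the gasp
#'   latency from apnea onset, later ones the inter-gasp intervals.
#' @param hr_recovery_tau,vf_recovery_tau Exponential recovery time constants
#'   (s) for heart rate and ventilatory frequency.
#' @param hr_floor,vf_floor Floors the two signals recover from (beats/min,
#'   breaths/min).
#' @param recovers Logical; `FALSE` marks the terminal, failed trial.
#' @param recovery_hold Seconds between the first gasp and the next anoxic
#'   switch.
#' @return A list of class `autoresus_trial`.
#' @export
autoresus_trial <- function(induction_time = 30, gasp_intervals = c(42, 12),
                            hr_recovery_tau = 15, vf_recovery_tau = 25,
                            hr_floor = 100, vf_floor = 20,
                            recovers = TRUE, recovery_hold = 300) {
  if (induction_time <= 0) abort("`induction_time` must be positive.")
  if (length(gasp_intervals) && any(gasp_intervals <= 0)) {
    abort("`gasp_intervals` must be strictly positive.")
  }
  if (hr_recovery_tau <= 0 || vf_recovery_tau <= 0) {
    abort("recovery time constants must be positive.")
  }
  structure(as.list(environment()), class = "autoresus_trial")
}

#' Closed-form recovery latency of an exponential rise
#'
#' For `x(t) = floor + (base - floor) * (1 - exp(-t/tau))`, returns the
#' smallest `t` with `x(t) >= fraction * base`: zero when the threshold sits
#' at or below the floor, `NA` when it is unreachable.
#'
#' @param base Baseline value the signal recovers toward.
#' @param floor Value the recovery starts from.
#' @param tau Time constant, s.
#' @param fraction Fraction of baseline defining recovery, in (0, 1).
#' @return Latency in seconds (possibly 0 or `NA`).
#' @export
recovery_latency_exact <- function(base, floor, tau, fraction) {
  thr <- fraction * base
  if (thr <= floor) return(0)
  if (thr >= base) return(NA_real_)
  -tau * log(1 - (thr - floor) / (base - floor))
}

#' Simulate a neonatal autoresuscitation session
#'
#' Renders baseline breathing, then for each trial: the anoxic switch,
#' breathing cessation after the programmed induction time, a gasp train,
#' and (for recovering trials) resumption of breathing whose instantaneous
#' rate follows the programmed ventilatory-frequency recovery curve, with
#' heart rate rendered as a dedicated cardiac channel whose instantaneous
#' rate persists through apnea (decaying toward its floor) and recovers from
#' the first gasp. Ground truth stores the analytic recovery latencies.
#'
#' @param trials List of [autoresus_trial()]; every trial but the last must
#'   have `recovers = TRUE` and the last `recovers = FALSE`.
#' @param baseline [breath_model()] for eupneic breathing; its `rate_mean` is
#'   the ventilatory-frequency baseline and `hr_mean` the heart-rate
#'   baseline.
#' @param sample_rate Hz (>= 100).
#' @param seed Integer seed.
#' @param baseline_lead Seconds of room-air baseline before the first switch.
#' @param anoxia_hr_tau Time constant (s) of the heart-rate fall during
#'   anoxic apnea.
#' @param terminal_tail Seconds of recording kept after the terminal trial.
#' @param animal Optional [animal_meta()].
#' @return List of `recording` (channels `breath`, `cardiac`; markers
#'   `anoxia_<i>` and `recovery_<i>`) and `truth` with `breath_onsets`,
#'   `event_log` (gasps), and per-trial tibble `trials` holding programmed
#'   and analytic values (induction, gasp latency, inter-gasp interval,
#'   latencies to 50%/63% of baseline for HR and VF, decoupling, recovers).
#' @export
sim_autoresus_session <- function(trials = default_autoresus_trials(),
                                  baseline = breath_model(
                                    rate_mean = 180, rate_cv = 0.04,
                                    amp_mean = 1, amp_cv = 0.06,
                                    sigh_rate = 0, apnea_rate = 0,
                                    cardiac_amp = 0.05, hr_mean = 450,
                                    noise_sd = 0.02),
                                  sample_rate = 200, seed = 1,
                                  baseline_lead = 120, anoxia_hr_tau = 10,
                                  terminal_tail = 60, animal = NULL) {
  stopifnot(all(vapply(trials, inherits, TRUE, "autoresus_trial")))
  if (sample_rate < 100) abort("`sample_rate` must be >= 100 Hz.")
  n_tr <- length(trials)
  if (n_tr < 1) abort("at least one trial is required.")
  recov <- vapply(trials, `[[`, TRUE, "recovers")
  if (any(recov[-n_tr] == FALSE)) {
    abort("trials after a non-recovering trial are not allowed.")
  }
  if (recov[n_tr]) {
    abort("the final trial must have `recovers = FALSE` (session ends in failure).")
  }
  local_seed(seed)

  p <- baseline
  vf_base <- p$rate_mean
  hr_base <- p$hr_mean
  jitter_per <- function(per) per * max(0.2, 1 + p$rate_cv * rnorm(1))
  jitter_amp <- function() p$amp_mean * max(0.05, 1 + p$amp_cv * rnorm(1))

  # sequential breath schedule; rate_fn gives instantaneous breaths/min
  gen_run <- function(start, end, rate_fn) {
    if (end <= start) {
      return(tibble(onset_s = numeric(), period_s = numeric(),
                    amp = numeric(), is_gasp = logical()))
    }
    cap <- ceiling((end - start) * vf_base / 60 * 2) + 10
    on <- per <- am <- numeric(cap)
    cur <- start; k <- 0
    repeat {
      r <- rate_fn(cur)
      if (r < 1) r <- 1
      pp <- jitter_per(60 / r)
      if (cur + pp > end) break
      k <- k + 1
      on[k] <- cur; per[k] <- pp; am[k] <- jitter_amp()
      cur <- cur + pp
    }
    tibble(onset_s = on[seq_len(k)], period_s = per[seq_len(k)],
           amp = am[seq_len(k)], is_gasp = rep(FALSE, k))
  }

  breaths <- list()
  hr_segs <- list()  # (start, end, kind, from, tau) for HR rendering
  truth_rows <- list()
  markers <- list()
  gasp_log <- list()

  # baseline + each trial laid out sequentially
  run_start <- 0
  switch_t <- baseline_lead
  for (i in seq_len(n_tr)) {
    tr <- trials[[i]]
    if (i == 1) {
      rate_fn <- function(t) vf_base
    } else {
      prev <- trials[[i - 1]]
      g1 <- attr(prev, "first_gasp")
      rate_fn <- function(t) {
        min(vf_base,
            prev$vf_floor + (vf_base - prev$vf_floor) *
              (1 - exp(-(t - g1) / prev$vf_recovery_tau)))
      }
    }
    cease_target <- switch_t + tr$induction_time
    run <- gen_run(run_start, cease_target, rate_fn)
    breaths[[length(breaths) + 1]] <- run
    cease <- if (nrow(run)) {
      with(run[nrow(run), ], onset_s + period_s)
    } else run_start

    gasps <- cease + cumsum(tr$gasp_intervals)
    if (length(gasps)) {
      breaths[[length(breaths) + 1]] <- tibble(
        onset_s = gasps, period_s = 0.4,
        amp = 1.3 * p$amp_mean, is_gasp = TRUE
      )
      gasp_log[[i]] <- tibble(time_s = gasps, type = "gasp", trial = i)
    }
    g1 <- if (length(gasps)) gasps[1] else NA_real_
    attr(trials[[i]], "first_gasp") <- g1
    # re-fetch with attribute for closures above
    tr <- trials[[i]]

    markers[[length(markers) + 1]] <- tibble(
      time_s = switch_t, label = paste0("anoxia_", i))
    if (!is.na(g1)) {
      markers[[length(markers) + 1]] <- tibble(
        time_s = g1, label = paste0("recovery_", i))
    }

    hr_segs[[length(hr_segs) + 1]] <- tibble(
      start = switch_t, kind = "decay", g1 = g1,
      tau = anoxia_hr_tau, floor = tr$hr_floor, rec_tau = tr$hr_recovery_tau,
      recovers = tr$recovers
    )

    lat <- function(base, flo, tau, frac) {
      recovery_latency_exact(base, flo, tau, frac)
    }
    truth_rows[[i]] <- tibble(
      trial = i,
      switch_s = switch_t,
      apnea_onset_s = cease,
      induction_s = cease - switch_t,
      induction_programmed_s = tr$induction_time,
      first_gasp_s = g1,
      gasp_latency_s = if (length(gasps)) tr$gasp_intervals[1] else NA_real_,
      inter_gasp_s = if (length(gasps) >= 2) tr$gasp_intervals[2] else NA_real_,
      lat_hr63_s = if (tr$recovers) lat(hr_base, tr$hr_floor, tr$hr_recovery_tau, 0.63) else NA_real_,
      lat_hr50_s = if (tr$recovers) lat(hr_base, tr$hr_floor, tr$hr_recovery_tau, 0.50) else NA_real_,
      lat_vf50_s = if (tr$recovers) lat(vf_base, tr$vf_floor, tr$vf_recovery_tau, 0.50) else NA_real_,
      lat_vf63_s = if (tr$recovers) lat(vf_base, tr$vf_floor, tr$vf_recovery_tau, 0.63) else NA_real_,
      recovers = tr$recovers
    )

    if (tr$recovers) {
      if (is.na(g1)) abort("a recovering trial must have at least one gasp.")
      next_switch <- g1 + tr$recovery_hold
      # resume continuous breathing one instantaneous breath period after the
      # last gasp, so the first resumed breath is not an isolated deflection
      vf_resume <- tr$vf_floor + (vf_base - tr$vf_floor) *
        (1 - exp(-(max(gasps) - g1) / tr$vf_recovery_tau))
      run_start <- max(gasps) + 60 / max(1, vf_resume)
      switch_t <- next_switch
    } else {
      session_end <- max(c(cease, gasps)) + terminal_tail
    }
  }

  truth_trials <- list_rbind(truth_rows) |>
    mutate(decoupling_s = .data$lat_hr63_s - .data$lat_vf50_s)

  breaths <- list_rbind(breaths) |> arrange(.data$onset_s)
  n <- round(session_end * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- render_breath_cycles(t, breaths$onset_s, breaths$period_s,
                            breaths$amp, ti_frac = p$ti_frac)

  # instantaneous heart rate over the session
  hr <- rep(hr_base, n)
  for (seg in seq_along(hr_segs)) {
    s <- hr_segs[[seg]]
    after_sw <- t >= s$start
    rel <- t[after_sw] - s$start
    hr[after_sw] <- s$floor + (hr_base - s$floor) * exp(-rel / s$tau)
    if (!is.na(s$g1) && s$recovers) {
      after_g <- t >= s$g1
      relg <- t[after_g] - s$g1
      hr[after_g] <- s$floor + (hr_base - s$floor) *
        (1 - exp(-relg / s$rec_tau))
    } else if (!is.na(s$g1)) {
      after_g <- t >= s$g1
      hr[after_g] <- s$floor
    }
  }
  phase <- 2 * pi * cumsum(hr / 60) / sample_rate
  # the dedicated cardiac channel mirrors the separately recorded heartbeat;
  # its amplitude scales with cardiac_amp so an absent cardiac signal
  # propagates to both channels
  cardiac <- 10 * p$cardiac_amp * sin(phase)
  if (p$cardiac_amp > 0) y <- y + p$cardiac_amp * sin(phase)
  if (p$noise_sd > 0) {
    y <- y + rnorm(n, 0, p$noise_sd)
    cardiac <- cardiac + rnorm(n, 0, min(p$noise_sd, 0.02))
  }

  rec <- trace_recording(
    tibble(time_s = t, breath = y, cardiac = cardiac),
    sample_rate, markers = list_rbind(markers), animal = animal
  )
  list(
    recording = rec,
    truth = list(
      breath_onsets = breaths$onset_s[!breaths$is_gasp],
      gasp_times = breaths$onset_s[breaths$is_gasp],
      event_log = if (length(gasp_log)) list_rbind(gasp_log) else
        tibble(time_s = numeric(), type = character(), trial = integer()),
      trials = truth_trials,
      vf_base = vf_base, hr_base = hr_base, params = p
    )
  )
}

#' Default five-trial session design (four recoveries, terminal failure)
#' @param n_trials Total number of trials including the terminal failure.
#' @return List of [autoresus_trial()].
#' @export
default_autoresus_trials <- function(n_trials = 5) {
  c(
    lapply(seq_len(n_trials - 1), function(i) autoresus_trial()),
    list(autoresus_trial(gasp_intervals = c(42), recovers = FALSE))
  )
}
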