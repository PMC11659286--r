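#' Breath-model parameters for the synthetic trace generator
#'
#' Describes eupneic breathing plus programmed sigh/apnea events and a
#' superimposed cardiogenic oscillation. Defaults emulate calm adult mouse
#' breathing in room air. Event magnitudes are constrained so that every
#' programmed event satisfies the detector definitions by construction: a
#' sigh's amplitude is `sigh_amp_factor` (>= 2) times the programmed mean
#' amplitude, and an apnea stretches one interbreath interval (IBI) to
#' `apnea_ibi_factor` (>= 2) times the local IBI.
#'
#' @param rate_mean Mean breathing rate, breaths/min (must lie in (10, 900)).
#' @param rate_cv Coefficient of variation of the breath period.
#' @param amp_mean Mean breath amplitude, signal units.
#' @param amp_cv Coefficient of variation of breath amplitude.
#' @param sigh_rate Programmed sighs per 100 breaths.
#' @param sigh_amp_factor Sigh amplitude as a multiple of `amp_mean`; >= 2.
#' @param apnea_rate Programmed apneas per 100 breaths.
#' @param apnea_ibi_factor Stretch factor applied to an apneic IBI; >= 2.
#' @param cardiac_amp Amplitude of the additive cardiac sinusoid, signal units.
#' @param hr_mean Heart rate of the cardiac oscillation, beats/min.
#' @param noise_sd Additive white-noise standard deviation, signal units.
#' @param ti_frac Inspiratory fraction of the breath cycle (Ti / TT).
#' @return A list of class `breath_model`.
#' @export
breath_model <- function(rate_mean = 150, rate_cv = 0.05,
                         amp_mean = 1, amp_cv = 0.08,
                         sigh_rate = 1, sigh_amp_factor = 2.5,
                         apnea_rate = 1, apnea_ibi_factor = 2.5,
                         cardiac_amp = 0.02, hr_mean = 600,
                         noise_sd = 0.02, ti_frac = 0.35) {
  if (rate_mean <= 10 || rate_mean >= 900) {
    abort("`rate_mean` must lie in (10, 900) breaths/min.")
  }
  if (any(c(rate_cv, amp_cv, sigh_rate, apnea_rate, cardiac_amp, noise_sd) < 0)) {
    abort("rates, CVs, `cardiac_amp` and `noise_sd` must be non-negative.")
  }
  if (amp_mean <= 0) abort("`amp_mean` must be positive.")
  if (sigh_amp_factor < 2) abort("`sigh_amp_factor` must be >= 2.")
  if (apnea_ibi_factor < 2) abort("`apnea_ibi_factor` must be >= 2.")
  if (ti_frac <= 0 || ti_frac >= 1) abort("`ti_frac` must lie in (0, 1).")
  structure(as.list(environment()), class = "breath_model")
}

# Programmed event counts are deterministic given the breath count:
# round(rate/100 * n) events at seeded positions, so tests can dial an exact
# number of events.
program_events <- function(n_breaths, sigh_rate, apnea_rate) {
  n_sigh <- round(sigh_rate / 100 * n_breaths)
  n_apnea <- round(apnea_rate / 100 * n_breaths)
  # keep events off the first/last breaths and mutually disjoint
  eligible <- seq_len(n_breaths)
  eligible <- eligible[eligible > 1 & eligible < n_breaths]
  if (n_sigh + n_apnea > length(eligible)) {
    abort("programmed event count exceeds available breaths.")
  }
  picks <- sample(eligible, n_sigh + n_apnea)
  list(sigh = sort(head(picks, n_sigh)),
       apnea = sort(tail(picks, n_apnea)))
}

# Vectorised renderer: half-sinusoid inspiration, exponentially damped
# negative expiratory lobe, silence during any IBI stretch beyond the cycle.
# The expiratory lobe is scaled so each cycle integrates to zero (flow in =
# flow out), which keeps the signal baseline-stable under high-pass
# filtering.
render_breath_cycles <- function(t, onsets, periods, amps, ti_frac = 0.35,
                                 expir_decay = 3) {
  y <- numeric(length(t))
  if (!length(onsets)) return(y)
  idx <- findInterval(t, onsets)
  inside <- idx >= 1
  rel <- t[inside] - onsets[idx[inside]]
  per <- periods[idx[inside]]
  amp <- amps[idx[inside]]
  ti <- ti_frac * per
  te <- per - ti
  # area of sin(pi*u)*exp(-k*u) on [0,1]; balances the inspiratory 2/pi area
  k <- expir_decay
  lobe_area <- pi * (1 + exp(-k)) / (k^2 + pi^2)
  e_scale <- (2 / pi) * ti / (te * lobe_area)
  v <- numeric(sum(inside))
  ins <- rel < ti
  v[ins] <- amp[ins] * sin(pi * rel[ins] / ti[ins])
  exb <- !ins & rel < per
  u <- (rel[exb] - ti[exb]) / te[exb]
  v[exb] <- -amp[exb] * e_scale[exb] * sin(pi * u) * exp(-k * u)
  y[inside] <- v
  y
}

#' Simulate a breathing trace with analytic ground truth
#'
#' Concatenates breath cycles (half-sinusoid inspiration, exponentially
#' damped expiration) with jittered period and amplitude. Programmed sighs
#' replace a breath's amplitude with `sigh_amp_factor * amp_mean`; programmed
#' apneas stretch that breath's IBI to `apnea_ibi_factor` times the local
#' IBI (silence fills the stretch). A low-amplitude cardiac sinusoid at
#' `hr_mean` and white noise are superimposed.
#'
#' @param params A [breath_model()].
#' @param duration Recording length, seconds (> 0).
#' @param sample_rate Sampling rate, Hz (>= 100).
#' @param seed Integer seed; identical `(params, seed)` give byte-identical
#'   output.
#' @param animal Optional [animal_meta()] attached to the recording.
#' @param cardiac_channel When `TRUE` a dedicated `cardiac` channel is also
#'   recorded (amplitude `10 * cardiac_amp`), emulating rigs that record the
#'   heartbeat separately from the breathing signal.
#' @return A list with elements `recording` (a [trace_recording()] with a
#'   `breath` channel) and `truth`, a list holding `breath_onsets` (exact
#'   programmed onset times, s), `breaths` (per-breath tibble with period,
#'   ibi, amplitude and event flags) and `event_log`
#'   (tibble: `time_s`, `type`, `breath_index`).
#' @export
sim_breathing_trace <- function(params = breath_model(), duration,
                                sample_rate = 200, seed = 1, animal = NULL,
                                cardiac_channel = FALSE) {
  stopifnot(inherits(params, "breath_model"))
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive (seconds).")
  }
  if (sample_rate < 100) abort("`sample_rate` must be >= 100 Hz.")
  local_seed(seed)

  p <- params
  t_mean <- 60 / p$rate_mean
  n_max <- ceiling(duration / t_mean * (1 + 6 * p$rate_cv)) + 10
  periods <- t_mean * pmax(0.2, 1 + p$rate_cv * rnorm(n_max))
  amps <- p$amp_mean * pmax(0.05, 1 + p$amp_cv * rnorm(n_max))

  # provisional onsets ignoring apnea stretches, to fix the breath count
  onsets0 <- cumsum(c(0, periods))[seq_len(n_max)]
  n_breaths <- sum(onsets0 < duration - t_mean * 0.5)
  ev <- program_events(n_breaths, p$sigh_rate, p$apnea_rate)

  periods <- periods[seq_len(n_breaths)]
  amps <- amps[seq_len(n_breaths)]
  is_sigh <- seq_len(n_breaths) %in% ev$sigh
  is_apnea <- seq_len(n_breaths) %in% ev$apnea
  amps[is_sigh] <- p$sigh_amp_factor * p$amp_mean
  # an apnea hosted by a shorter-than-average breath could fall below the
  # relative calling threshold; clamping the host period at the mean keeps
  # every programmed apnea >= factor x average IBI by construction
  periods[is_apnea] <- pmax(periods[is_apnea], t_mean)
  ibis <- periods
  ibis[is_apnea] <- p$apnea_ibi_factor * periods[is_apnea]
  onsets <- cumsum(c(0, ibis))[seq_len(n_breaths)]
  keep <- onsets + periods <= duration
  n_breaths <- sum(keep)
  onsets <- onsets[keep]; periods <- periods[keep]; amps <- amps[keep]
  ibis <- ibis[keep]; is_sigh <- is_sigh[keep]; is_apnea <- is_apnea[keep]
  # an apnea needs a following breath to delimit its interval; if trimming
  # left an apnea on the final breath, it is not a renderable event
  if (n_breaths && is_apnea[n_breaths]) {
    is_apnea[n_breaths] <- FALSE
    ibis[n_breaths] <- periods[n_breaths]
  }

  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- render_breath_cycles(t, onsets, periods, amps, ti_frac = p$ti_frac)
  if (p$cardiac_amp > 0) {
    y <- y + p$cardiac_amp * sin(2 * pi * p$hr_mean / 60 * t)
  }
  if (p$noise_sd > 0) y <- y + rnorm(n, 0, p$noise_sd)

  breaths <- tibble(
    index = seq_len(n_breaths), onset_s = onsets, period_s = periods,
    ibi_s = ibis, amp = amps, is_sigh = is_sigh, is_apnea = is_apnea
  )
  event_log <- bind_rows(
    tibble(time_s = onsets[is_sigh], type = "sigh",
           breath_index = which(is_sigh)),
    tibble(time_s = onsets[is_apnea], type = "apnea",
           breath_index = which(is_apnea))
  ) |> arrange(.data$time_s)

  signals <- tibble(time_s = t, breath = y)
  if (cardiac_channel) {
    signals$cardiac <- 10 * p$cardiac_amp * sin(2 * pi * p$hr_mean / 60 * t) +
      rnorm(n, 0, min(p$noise_sd, 0.02))
  }
  rec <- trace_recording(signals, sample_rate, animal = animal)
  list(
    recording = rec,
    truth = list(breath_onsets = onsets, breaths = breaths,
                 event_log = event_log, params = p)
  )
}

# set.seed scoped to the calling function; the caller's RNG state is restored
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
  invisible()
}
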