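#' Adult flow-through gas protocol
#'
#' The five-period adult chemoreflex protocol: room air, hypercapnia
#' (5% CO2 / 21% O2), room air, hypoxia (10% O2), room air, each 20 min by
#' default, delivered at 198 mL/min through a water-jacketed chamber held at
#' 30 degrees C.
#'
#' @param epochs Tibble with columns `label`, `o2`, `co2` (inflow fractions)
#'   and `duration_s`. Defaults to the five-period protocol above.
#' @param flow_rate Chamber inflow, mL/min.
#' @param chamber_volume Effective chamber volume, mL; sets the washout time
#'   constant `tau = chamber_volume / flow_rate`.
#' @param chamber_temp Chamber temperature, degrees C.
#' @return A list of class `adult_protocol`.
#' @export
adult_protocol <- function(epochs = NULL, flow_rate = 198,
                           chamber_volume = 450, chamber_temp = 30) {
  if (is.null(epochs)) {
    epochs <- tibble(
      label = c("room_air_1", "hypercapnia", "room_air_2", "hypoxia",
                "room_air_3"),
      o2 = c(0.2095, 0.21, 0.2095, 0.10, 0.2095),
      co2 = c(0, 0.05, 0, 0, 0),
      duration_s = rep(1200, 5)
    )
  }
  epochs <- as_tibble(epochs)
  if (!nrow(epochs)) abort("`epochs` must be nonempty.")
  if (any(epochs$o2 < 0 | epochs$o2 > 1 | epochs$co2 < 0 | epochs$co2 > 1)) {
    abort("gas fractions must lie in [0, 1].")
  }
  if (any(epochs$o2 + epochs$co2 > 1)) abort("O2 + CO2 fractions exceed 1.")
  if (flow_rate < 0) abort("`flow_rate` must be non-negative.")
  if (chamber_volume < 0) abort("`chamber_volume` must be non-negative.")
  structure(
    list(epochs = epochs, flow_rate = flow_rate,
         chamber_volume = chamber_volume, chamber_temp = chamber_temp),
    class = "adult_protocol"
  )
}

#' Simulate chamber gas channels under first-order washout
#'
#' Chamber O2 and CO2 follow first-order washout toward each period's inflow
#' fraction with time constant `tau = chamber_volume / flow_rate`. Animal
#' metabolism depresses steady-state chamber O2 below the inflow fraction by
#' `programmed_vo2 / flow_rate` (the flow-through respirometry mass balance),
#' so at steady state `flow * (FiO2 - FeO2) = programmed_vo2`.
#'
#' @param protocol An [adult_protocol()].
#' @param programmed_vo2 Whole-animal oxygen consumption, mL O2/min.
#' @param sample_rate Output sampling rate, Hz.
#' @param noise_sd Optional analyser noise (percent O2/CO2 units), default 0.
#' @param seed Seed for the analyser noise.
#' @return Tibble with columns `time_s`, `o2_pct`, `co2_pct`,
#'   `chamber_temp_c`.
#' @export
sim_gas_channels <- function(protocol, programmed_vo2 = 0, sample_rate = 200,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "adult_protocol"))
  if (protocol$flow_rate <= 0) {
    abort("`flow_rate` must be positive: washout is undefined at zero flow.")
  }
  local_seed(seed)
  ep <- protocol$epochs
  tau <- protocol$chamber_volume / protocol$flow_rate * 60  # seconds
  depression <- programmed_vo2 / protocol$flow_rate          # O2 fraction
  starts <- cumsum(c(0, ep$duration_s))[seq_len(nrow(ep))]
  total <- sum(ep$duration_s)
  n <- round(total * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate

  o2 <- numeric(n)
  co2 <- numeric(n)
  # first period starts at its own effective steady state
  o2_prev <- ep$o2[1] - depression
  co2_prev <- ep$co2[1]
  for (i in seq_len(nrow(ep))) {
    in_ep <- t >= starts[i] & t < starts[i] + ep$duration_s[i]
    rel <- t[in_ep] - starts[i]
    o2_target <- ep$o2[i] - depression
    co2_target <- ep$co2[i]
    if (tau > 0) {
      o2[in_ep] <- o2_target + (o2_prev - o2_target) * exp(-rel / tau)
      co2[in_ep] <- co2_target + (co2_prev - co2_target) * exp(-rel / tau)
    } else {
      o2[in_ep] <- o2_target
      co2[in_ep] <- co2_target
    }
    end_rel <- ep$duration_s[i]
    if (tau > 0) {
      o2_prev <- o2_target + (o2_prev - o2_target) * exp(-end_rel / tau)
      co2_prev <- co2_target + (co2_prev - co2_target) * exp(-end_rel / tau)
    } else {
      o2_prev <- o2_target
      co2_prev <- co2_target
    }
  }
  o2_pct <- o2 * 100
  co2_pct <- co2 * 100
  if (noise_sd > 0) {
    o2_pct <- o2_pct + rnorm(n, 0, noise_sd)
    co2_pct <- pmax(0, co2_pct + rnorm(n, 0, noise_sd))
  }
  tibble(time_s = t, o2_pct = o2_pct, co2_pct = co2_pct,
         chamber_temp_c = rep(protocol$chamber_temp, n))
}

#' Simulate a full adult plethysmography session
#'
#' Renders the breathing channel across the five-period gas protocol with a
#' per-period chemoreflex response (rate/amplitude multipliers applied while
#' each gas is flowing), overlays the simulated chamber gas channels, and
#' places a switch marker at the start of every period.
#'
#' @param params Baseline [breath_model()] (room-air breathing).
#' @param protocol An [adult_protocol()].
#' @param programmed_vo2 Whole-animal VO2, mL O2/min.
#' @param response Named list of `c(rate, amp)` multipliers per epoch label;
#'   labels missing from the list use `c(1, 1)`.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @param animal Optional [animal_meta()].
#' @param gas_noise_sd Analyser noise on the gas channels, percent units.
#' @return As [sim_breathing_trace()]: list of `recording` (channels
#'   `breath`, `o2_pct`, `co2_pct`, `chamber_temp_c`, with markers) and
#'   `truth` (breath/event ground truth plus `programmed_vo2`).
#' @export
sim_adult_session <- function(params = breath_model(), protocol = adult_protocol(),
                              programmed_vo2 = 0.9,
                              response = list(hypercapnia = c(rate = 1.35, amp = 1.5),
                                              hypoxia = c(rate = 1.2, amp = 1.15)),
                              sample_rate = 200, seed = 1, animal = NULL,
                              gas_noise_sd = 0.005) {
  stopifnot(inherits(params, "breath_model"), inherits(protocol, "adult_protocol"))
  local_seed(seed)
  ep <- protocol$epochs
  starts <- cumsum(c(0, ep$duration_s))[seq_len(nrow(ep))]
  total <- sum(ep$duration_s)

  mult_for <- function(time) {
    i <- findInterval(time, starts)
    lab <- ep$label[max(1L, i)]
    m <- response[[lab]]
    if (is.null(m)) c(rate = 1, amp = 1) else m
  }

  # sequential breath schedule with epoch-dependent rate/amplitude
  t_mean <- 60 / params$rate_mean
  n_cap <- ceiling(total / t_mean * 2) + 10
  onsets <- periods <- amps <- numeric(n_cap)
  z_per <- rnorm(n_cap); z_amp <- rnorm(n_cap)
  cur <- 0; k <- 0
  while (cur < total - t_mean) {
    k <- k + 1
    m <- mult_for(cur)
    onsets[k] <- cur
    periods[k] <- (t_mean / m[["rate"]]) * max(0.2, 1 + params$rate_cv * z_per[k])
    amps[k] <- (params$amp_mean * m[["amp"]]) *
      max(0.05, 1 + params$amp_cv * z_amp[k])
    cur <- cur + periods[k]
  }
  n_breaths <- k
  onsets <- onsets[seq_len(k)]; periods <- periods[seq_len(k)]
  amps <- amps[seq_len(k)]
  ev <- program_events(n_breaths, params$sigh_rate, params$apnea_rate)
  is_sigh <- seq_len(n_breaths) %in% ev$sigh
  is_apnea <- seq_len(n_breaths) %in% ev$apnea
  amps[is_sigh] <- params$sigh_amp_factor * params$amp_mean *
    vapply(onsets[is_sigh], function(x) mult_for(x)[["amp"]], 0)
  # apnea: stretch the IBI by shifting all later onsets
  if (any(is_apnea)) {
    for (k in which(is_apnea)) {
      # clamp the host period at the mean so the stretched IBI stays above
      # the relative calling threshold by construction
      periods[k] <- max(periods[k], t_mean)
      stretch <- (params$apnea_ibi_factor - 1) * periods[k]
      later <- seq_len(n_breaths) > k
      onsets[later] <- onsets[later] + stretch
    }
    keep <- onsets + periods <= total
    onsets <- onsets[keep]; periods <- periods[keep]; amps <- amps[keep]
    is_sigh <- is_sigh[keep]; is_apnea <- is_apnea[keep]
    n_breaths <- length(onsets)
    # an apnea on the final kept breath has no following breath to delimit it
    if (n_breaths && is_apnea[n_breaths]) is_apnea[n_breaths] <- FALSE
  }
  ibis <- c(diff(onsets), periods[n_breaths])

  n <- round(total * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- render_breath_cycles(t, onsets, periods, amps, ti_frac = params$ti_frac)
  if (params$cardiac_amp > 0) {
    y <- y + params$cardiac_amp * sin(2 * pi * params$hr_mean / 60 * t)
  }
  if (params$noise_sd > 0) y <- y + rnorm(n, 0, params$noise_sd)

  gas <- sim_gas_channels(protocol, programmed_vo2, sample_rate,
                          noise_sd = gas_noise_sd, seed = NULL)
  signals <- tibble(time_s = t, breath = y,
                    o2_pct = gas$o2_pct[seq_len(n)],
                    co2_pct = gas$co2_pct[seq_len(n)],
                    chamber_temp_c = gas$chamber_temp_c[seq_len(n)])
  markers <- tibble(time_s = starts, label = paste0("gas_", ep$label))
  rec <- trace_recording(signals, sample_rate, markers = markers,
                         animal = animal)
  breaths <- tibble(index = seq_len(n_breaths), onset_s = onsets,
                    period_s = periods, ibi_s = ibis, amp = amps,
                    is_sigh = is_sigh, is_apnea = is_apnea)
  event_log <- bind_rows(
    tibble(time_s = onsets[is_sigh], type = "sigh",
           breath_index = which(is_sigh)),
    tibble(time_s = onsets[is_apnea], type = "apnea",
           breath_index = which(is_apnea))
  ) |> arrange(.data$time_s)
  list(recording = rec,
       truth = list(breath_onsets = onsets, breaths = breaths,
                    event_log = event_log, programmed_vo2 = programmed_vo2,
                    params = params, protocol = protocol))
}
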