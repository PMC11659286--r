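#' Run the full adult chemoreflex analysis on one recording
#'
#' Convenience wrapper over the pipeline stages: breath detection, calm-breath
#' flagging, tidal-volume calibration, epoch assignment, apnea/sigh calling
#' per epoch (each epoch's inflow O2 fraction feeds the VO2 mass balance),
#' and per-condition summaries.
#'
#' @param rec A [trace_recording()] of an adult session (needs `animal`
#'   metadata for weight and temperatures).
#' @param protocol The [adult_protocol()] that was run.
#' @param inject_volume_ml,inject_deflection Tidal-volume calibration; `NULL`
#'   leaves VT in uncalibrated units.
#' @param breath_cfg Detection configuration.
#' @param min_breaths Per-epoch calm-breath quality threshold.
#' @param ... Further arguments to [assign_epochs()].
#' @return List: `breaths` (calm-flagged, calibrated), `epochs`, `calls`
#'   (event calls with epoch labels), `summaries` (one row per usable
#'   epoch), `percent_change`.
#' @export
summarize_adult_session <- function(rec, protocol = adult_protocol(),
                                    inject_volume_ml = NULL,
                                    inject_deflection = NULL,
                                    breath_cfg = pneumotrace::breath_cfg(),
                                    min_breaths = 20, ...) {
  stopifnot(inherits(rec, "trace_recording"))
  meta <- rec$animal
  if (is.null(meta)) abort("recording carries no animal metadata.")
  breaths <- detect_breaths(rec, breath_cfg) |>
    select_calm_breaths(rec) |>
    calibrate_tidal_volume(
      inject_volume_ml = inject_volume_ml,
      inject_deflection = inject_deflection,
      temp_pre_c = meta$temp_pre_c %||% 37,
      temp_post_c = meta$temp_post_c %||% 37,
      chamber_temp_c = protocol$chamber_temp,
      session_duration_s = rec_duration(rec)
    )
  epochs <- assign_epochs(rec, protocol, ...)
  calls <- list(); summaries <- list()
  for (i in seq_len(nrow(epochs))) {
    ep <- epochs[i, ]
    in_ep <- breaths$onset_s >= ep$start_s & breaths$onset_s < ep$end_s
    be <- breaths[in_ep, ]
    if (nrow(be) < 2) next
    ep_calls <- bind_rows(
      call_apneas(be, epoch_label = ep$label),
      call_sighs(be, epoch_label = ep$label)
    )
    calls[[i]] <- ep_calls
    vo2 <- if ("o2_pct" %in% names(rec$signals) && !is.na(meta$weight_g)) {
      compute_vo2(rec, ep, flow_ml_min = protocol$flow_rate,
                  weight_g = meta$weight_g, fio2 = ep$o2)
    } else NA_real_
    summaries[[i]] <- summarize_condition(be, ep_calls, ep, meta,
                                          vo2_ml_min_g = vo2,
                                          min_breaths = min_breaths)
  }
  calls <- list_rbind(calls)
  summaries <- list_rbind(summaries)
  pc <- if (nrow(summaries)) percent_change(summaries) else tibble()
  list(breaths = breaths, epochs = epochs, calls = calls,
       summaries = summaries, percent_change = pc)
}
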