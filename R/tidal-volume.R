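#' Barometric-plethysmography temperature/humidity correction
#'
#' The Drorbaugh-Fenn correction converts a chamber pressure deflection into
#' a tidal volume, accounting for the temperature and humidity difference
#' between chamber gas and alveolar gas:
#' \deqn{C = \frac{T_R (P_B - P_C)}{T_R (P_B - P_C) - T_C (P_B - P_R)}}
#' with body and chamber temperatures \eqn{T_R, T_C} in kelvin, barometric
#' pressure \eqn{P_B}, and \eqn{P_C, P_R} the saturated water vapour
#' pressures at chamber and body temperature (both gas streams assumed
#' saturated).
#'
#' @param body_temp_c Body (rectal) temperature, deg C.
#' @param chamber_temp_c Chamber temperature, deg C.
#' @param pressure_mmhg Barometric pressure, mmHg.
#' @return Dimensionless correction factor.
#' @export
drorbaugh_fenn_factor <- function(body_temp_c, chamber_temp_c = 30,
                                  pressure_mmhg = 760) {
  tr <- body_temp_c + 273.15
  tc <- chamber_temp_c + 273.15
  pr <- svp_mmhg(body_temp_c)
  pc <- svp_mmhg(chamber_temp_c)
  tr * (pressure_mmhg - pc) / (tr * (pressure_mmhg - pc) -
                                 tc * (pressure_mmhg - pr))
}

# saturated water vapour pressure, Magnus form, mmHg
svp_mmhg <- function(temp_c) {
  6.1094 * exp(17.625 * temp_c / (temp_c + 243.04)) * 0.750062
}

#' Calibrate tidal volume from breath deflections
#'
#' Converts each breath's peak deflection into a tidal volume using a known
#' injected-volume calibration and the Drorbaugh-Fenn correction:
#' `VT = inject_volume * (deflection / inject_deflection) * C`. Body
#' temperature for each breath is linearly interpolated between the pre- and
#' post-session rectal temperatures by session time. Without a calibration
#' the uncalibrated inspiratory integral is carried instead and flagged.
#'
#' @param breaths A `breath_tbl` from [detect_breaths()].
#' @param inject_volume_ml Injected calibration volume, mL.
#' @param inject_deflection Deflection produced by the injection, signal
#'   units (> 0). `NULL` marks the calibration as missing.
#' @param temp_pre_c,temp_post_c Rectal temperatures, deg C.
#' @param chamber_temp_c Chamber temperature, deg C.
#' @param pressure_mmhg Barometric pressure, mmHg.
#' @param session_duration_s Session length used for the temperature
#'   interpolation; defaults to the last breath offset.
#' @param correction Either `"drorbaugh-fenn"` or `"none"` (C = 1).
#' @return The breath tibble with `vt_ml` and `vt_calibrated` columns.
#' @export
calibrate_tidal_volume <- function(breaths, inject_volume_ml = NULL,
                                   inject_deflection = NULL,
                                   temp_pre_c = 37, temp_post_c = 37,
                                   chamber_temp_c = 30, pressure_mmhg = 760,
                                   session_duration_s = NULL,
                                   correction = c("drorbaugh-fenn", "none")) {
  correction <- match.arg(correction)
  if (is.null(inject_volume_ml) || is.null(inject_deflection)) {
    warn("no calibration supplied; `vt_ml` holds the uncalibrated inspiratory integral.")
    breaths$vt_ml <- breaths$integ_insp
    breaths$vt_calibrated <- FALSE
    return(breaths)
  }
  if (inject_deflection <= 0) abort("`inject_deflection` must be positive.")
  dur <- session_duration_s %||%
    (if (nrow(breaths)) max(breaths$offset_s) else 1)
  frac <- if (dur > 0) pmin(1, breaths$onset_s / dur) else 0
  body_temp <- temp_pre_c + (temp_post_c - temp_pre_c) * frac
  cf <- if (correction == "none") 1 else {
    drorbaugh_fenn_factor(body_temp, chamber_temp_c, pressure_mmhg)
  }
  breaths$vt_ml <- inject_volume_ml * (breaths$amp / inject_deflection) * cf
  breaths$vt_calibrated <- TRUE
  breaths
}
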