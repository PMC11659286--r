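#' Call apneas within one epoch
#'
#' An apnea is an interbreath interval at least `factor` (default 2) times
#' the average IBI, the comparison inclusive. The reference average is the
#' arithmetic mean IBI over the epoch's calm breaths; when no breath is calm
#' the mean over all breaths is used and a note is logged.
#'
#' @param breaths Breath tibble for one epoch (needs `ibi_s`, `offset_s`;
#'   `calm` optional).
#' @param factor Threshold multiple of the mean IBI (>= 1).
#' @param epoch_label Label attached to the calls.
#' @return Tibble: `type`, `time_s` (the breath's offset), `magnitude`
#'   (IBI / mean IBI), `breath_index`, `epoch_label`.
#' @export
call_apneas <- function(breaths, factor = 2, epoch_label = NA_character_) {
  if (nrow(breaths) < 2) abort("need at least 2 breaths to call apneas.")
  ibi <- breaths$ibi_s
  use <- event_reference_mask(breaths)
  ref <- mean(ibi[use], na.rm = TRUE)
  hit <- !is.na(ibi) & ibi >= factor * ref
  tibble(
    type = rep("apnea", sum(hit)),
    time_s = breaths$offset_s[hit],
    magnitude = ibi[hit] / ref,
    breath_index = breaths$index[hit],
    epoch_label = epoch_label
  )
}

#' Call sighs within one epoch
#'
#' A sigh is a breath whose amplitude is at least `factor` (default 2) times
#' the average breath amplitude, inclusive; the reference is the mean over
#' calm breaths (a sigh's own amplitude only drops out via its calm flag -
#' there is no second-pass re-averaging).
#'
#' @inheritParams call_apneas
#' @return Tibble as [call_apneas()], with `magnitude = amp / mean amp` and
#'   `time_s` the breath onset.
#' @export
call_sighs <- function(breaths, factor = 2, epoch_label = NA_character_) {
  if (nrow(breaths) < 2) abort("need at least 2 breaths to call sighs.")
  use <- event_reference_mask(breaths)
  ref <- mean(breaths$amp[use], na.rm = TRUE)
  hit <- breaths$amp >= factor * ref
  tibble(
    type = rep("sigh", sum(hit)),
    time_s = breaths$onset_s[hit],
    magnitude = breaths$amp[hit] / ref,
    breath_index = breaths$index[hit],
    epoch_label = epoch_label
  )
}

event_reference_mask <- function(breaths) {
  if ("calm" %in% names(breaths) && any(breaths$calm)) {
    breaths$calm
  } else {
    if ("calm" %in% names(breaths)) {
      inform("no calm breaths in epoch; reference falls back to all breaths.")
    }
    rep(TRUE, nrow(breaths))
  }
}

#' Event rates per total breaths
#'
#' Expresses apnea and sigh counts as events per 100 breaths (exact ratio),
#' with the square-root transform of each rate carried as a convenience
#' column for the statistics stage.
#'
#' @param calls Event-call tibble ([call_apneas()] / [call_sighs()] rows).
#' @param breaths Breath tibble for the same epoch.
#' @param epoch_label Label for the output row.
#' @return One-row tibble: `epoch_label`, `n_breaths`, `n_apneas`,
#'   `n_sighs`, `apnea_per100`, `sigh_per100`, `sqrt_apnea`, `sqrt_sigh`.
#'   Zero breaths give `NA` rates with a warning.
#' @export
event_rates <- function(calls, breaths, epoch_label = NA_character_) {
  n <- nrow(breaths)
  n_ap <- sum(calls$type == "apnea")
  n_si <- sum(calls$type == "sigh")
  if (n == 0) {
    warn("zero breaths in epoch; event rates undefined.")
    return(tibble(epoch_label = epoch_label, n_breaths = 0L,
                  n_apneas = n_ap, n_sighs = n_si,
                  apnea_per100 = NA_real_, sigh_per100 = NA_real_,
                  sqrt_apnea = NA_real_, sqrt_sigh = NA_real_))
  }
  ap <- 100 * n_ap / n
  si <- 100 * n_si / n
  tibble(epoch_label = epoch_label, n_breaths = as.integer(n),
         n_apneas = as.integer(n_ap), n_sighs = as.integer(n_si),
         apnea_per100 = ap, sigh_per100 = si,
         sqrt_apnea = sqrt(ap), sqrt_sigh = sqrt(si))
}
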