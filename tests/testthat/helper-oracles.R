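# shared oracles and fixture builders (everything generated in code)

# greedy 1-to-1 matching of detected to true event times within a tolerance
match_events <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  tp <- 0
  for (x in truth) {
    d <- abs(detected - x)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(recall = if (length(truth)) tp / length(truth) else NA_real_,
    precision = if (length(detected)) tp / length(detected) else NA_real_)
}

# independently coded barometric tidal-volume correction (Drorbaugh-Fenn
# form), kept deliberately separate from the package implementation
oracle_df_correction <- function(body_c, chamber_c, pb) {
  vap <- function(tc) {
    hpa <- 6.1094 * exp((17.625 * tc) / (243.04 + tc))
    hpa / 1.3332239
  }
  t_body_k <- 273.15 + body_c
  t_ch_k <- 273.15 + chamber_c
  num <- t_body_k * (pb - vap(chamber_c))
  den <- num - t_ch_k * (pb - vap(body_c))
  num / den
}

# hand-built breath table for event-calling worked examples
breath_table <- function(ibis, amps = rep(1, length(ibis)), calm = NULL) {
  onsets <- cumsum(c(0, ibis))[seq_along(ibis)]
  tb <- tibble::tibble(
    index = seq_along(ibis),
    onset_s = onsets,
    insp_end_s = onsets + 0.3 * ibis,
    offset_s = onsets + 0.8 * ibis,
    ti_s = 0.3 * ibis, te_s = 0.5 * ibis, tt_s = 0.8 * ibis,
    amp = amps,
    integ_insp = 0.1 * amps,
    ibi_s = ibis
  )
  if (!is.null(calm)) tb$calm <- calm
  tb
}

# quiet variants for pipeline calls whose logging is not under test
quiet_breaths <- function(rec, ...) {
  suppressMessages(detect_breaths(rec, ...))
}
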