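#' Breath-detection configuration
#'
#' @param channel Name of the breath channel.
#' @param highpass_hz High-pass cutoff (Hz) removing baseline drift before
#'   zero-crossing delimitation.
#' @param lowpass_hz Low-pass smoothing cutoff (Hz).
#' @param min_tt Minimum credible breath cycle duration, s; shorter candidate
#'   cycles are merged into their predecessor.
#' @param amp_floor_frac Relative amplitude floor: candidates below
#'   `amp_floor_frac` times the session's robust (95th percentile) candidate
#'   amplitude are treated as noise and merged. Relative thresholds make
#'   detection invariant to uniform gain.
#' @param refine_lowpass_hz Cutoff of the mild low-pass used by the
#'   onset-refinement fit (2nd order; the main `lowpass_hz` smoothing is for
#'   cycle delimitation only).
#' @param exp_end_frac Fraction of breath amplitude at which the expiratory
#'   lobe is considered finished (sets the breath offset when a pause
#'   follows).
#' @param invert Set `TRUE` when inspiration is the negative lobe.
#' @return List of class `breath_cfg`.
#' @export
breath_cfg <- function(channel = "breath", highpass_hz = 0.1, lowpass_hz = 20,
                       min_tt = 0.05, amp_floor_frac = 0.25,
                       refine_lowpass_hz = 25, exp_end_frac = 0.05,
                       invert = FALSE) {
  structure(as.list(environment()), class = "breath_cfg")
}

# zero-phase filtering with mirror padding to suppress edge transients
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

filter_breath_signal <- function(x, sample_rate, cfg, lowpass = TRUE) {
  ny <- sample_rate / 2
  pad <- round(3 * sample_rate)
  if (cfg$highpass_hz > 0) {
    hp <- signal::butter(2, cfg$highpass_hz / ny, type = "high")
    x <- filtfilt_padded(hp, x, pad)
  }
  if (lowpass && cfg$lowpass_hz > 0 && cfg$lowpass_hz < ny) {
    lp <- signal::butter(4, cfg$lowpass_hz / ny, type = "low")
    x <- filtfilt_padded(lp, x, pad)
  }
  x
}

# refine a coarse onset by fitting the canonical breath-cycle shape - a
# half-sinusoid inspiratory lobe followed by an exponentially damped
# sinusoidal expiratory lobe - to the lightly filtered signal around the
# candidate cycle: least squares over (inspiratory amplitude, expiratory
# amplitude, onset, Ti, Te) by Gauss-Newton. Fitting the whole cycle avoids
# the corner bias of the raw zero crossing and averages sample noise over
# every informative sample of the breath.
refine_onset <- function(coarse, amp, xf, xh, t, fs, max_pts = 120,
                         expir_decay = 3, prior = NULL) {
  fail <- list(t0 = coarse, pars = NULL, rms = NA_real_)
  ic <- round(coarse * fs) + 1
  n <- length(xh)
  lim <- min(n, ic + max_pts)
  # window from the smoothed signal: across the inspiratory lobe, then
  # across the negative expiratory lobe until it returns within 5% of amp
  j <- ic
  while (j < lim && xf[j] < 0.3 * amp) j <- j + 1
  while (j < lim && xf[j] >= 0.05 * amp) j <- j + 1
  insp_end <- j
  while (j < lim && xf[j] > -0.05 * amp) j <- j + 1
  trough <- j
  while (j < lim && xf[j] <= -0.05 * amp) j <- j + 1
  have_exp <- j > trough
  idx <- max(1, ic - 1):min(n, j)
  if (length(idx) < 5) return(fail)
  tt <- t[idx]; yy <- xh[idx]

  k <- expir_decay
  a <- amp
  b <- 0.6 * amp
  t0 <- coarse
  ti <- max(3 / fs, t[insp_end] - coarse)
  te <- if (have_exp) max(3 / fs, t[min(n, j)] - t[insp_end]) else 1.8 * ti
  fit_exp <- have_exp
  for (it in 1:12) {
    ph <- pi * (tt - t0) / ti
    ins <- ph > 0 & ph < pi
    u <- (tt - t0 - ti) / te
    exb <- fit_exp & u > 0 & u < 1
    m <- numeric(length(tt))
    m[ins] <- a * sin(ph[ins])
    m[exb] <- -b * sin(pi * u[exb]) * exp(-k * u[exb])
    r <- yy - m
    # analytic Jacobian
    d_a <- ifelse(ins, sin(ph), 0)
    cph <- ifelse(ins, cos(ph), 0)
    d_b <- ifelse(exb, -sin(pi * u) * exp(-k * u), 0)
    g <- ifelse(exb, -b * exp(-k * u) * (pi * cos(pi * u) - k * sin(pi * u)), 0)
    # dm/dt0: insp -a*pi/ti*cos(ph); exp: -g/te
    d_t0 <- -a * pi / ti * cph - g / te
    d_ti <- -a * pi * (tt - t0) / ti^2 * cph - g / te
    d_te <- ifelse(exb, -g * u / te, 0)
    J <- cbind(d_a, d_b, d_t0, d_ti, d_te)
    use <- if (fit_exp) 1:5 else c(1, 3, 4)
    lhs <- crossprod(J[, use]) + diag(1e-10, length(use))
    rhs <- crossprod(J[, use], r)
    if (!is.null(prior)) {
      # shrinkage toward session-typical shape: quadratic penalty on the
      # nuisance parameters (amplitudes relative to the candidate amplitude,
      # Ti and Te absolute), weighted by residual variance / prior variance
      th <- c(a, b, t0, ti, te)
      mu <- c(prior$rel_a * amp, prior$rel_b * amp, t0, prior$ti, prior$te)
      w <- prior$sigma2 / c(prior$var_a * amp^2, prior$var_b * amp^2, Inf,
                            prior$var_ti, prior$var_te)
      # the prior must inform, never dominate: cap each weight at a fraction
      # of the likelihood information for that parameter
      w_use <- pmin(w[use], 0.5 * diag(lhs))
      lhs <- lhs + diag(w_use, length(use))
      rhs <- rhs + w_use * (mu[use] - th[use])
    }
    step <- tryCatch(solve(lhs, rhs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    upd <- numeric(5); upd[use] <- step
    a <- a + upd[1]; b <- b + upd[2]; t0 <- t0 + upd[3]
    ti <- ti + upd[4]; te <- te + upd[5]
    if (!is.finite(ti) || ti < 2 / fs || ti > max_pts / fs || a <= 0 ||
        (fit_exp && (!is.finite(te) || te < 2 / fs || b < 0))) {
      return(fail)
    }
    if (abs(upd[3]) < 1e-5 && abs(upd[4]) < 1e-5 && abs(upd[5]) < 1e-5 &&
        abs(upd[1]) < 1e-4 * amp && abs(upd[2]) < 1e-4 * amp) {
      break
    }
  }
  if (!is.finite(t0) || abs(t0 - coarse) > 10 / fs) return(fail)
  ph <- pi * (tt - t0) / ti
  u <- (tt - t0 - ti) / te
  m <- ifelse(ph > 0 & ph < pi, a * sin(pmax(0, pmin(pi, ph))), 0)
  if (fit_exp) {
    exb <- u > 0 & u < 1
    m[exb] <- -b * sin(pi * u[exb]) * exp(-expir_decay * u[exb])
  }
  list(t0 = t0, pars = c(a = a, b = b, ti = ti, te = te),
       rms = sqrt(mean((yy - m)^2)))
}

# signed zero crossings with sub-sample linear interpolation; ties at an
# exact zero resolve to the earlier sample
zero_crossings <- function(x, t, up = TRUE) {
  if (up) {
    i <- which(x[-length(x)] <= 0 & x[-1] > 0)
  } else {
    i <- which(x[-length(x)] >= 0 & x[-1] < 0)
  }
  if (!length(i)) return(numeric())
  frac <- ifelse(x[i] == 0, 0, -x[i] / (x[i + 1] - x[i]))
  t[i] + frac * (t[i + 1] - t[i])
}

#' Detect breaths from a raw trace
#'
#' Breaths are delimited by upward zero crossings of the band-filtered breath
#' signal (inspiration positive by convention; set `invert` in the config
#' otherwise). Candidate cycles shorter than `min_tt` or with inspiratory
#' amplitude below the relative floor are merged into their predecessor. The
#' breath offset is the end of the expiratory lobe (signal magnitude back
#' within `exp_end_frac` of the breath amplitude), capped at the next onset,
#' so `TT = Ti + Te = offset - onset` while the interbreath interval
#' (onset-to-onset, `ibi_s`) may exceed `TT` across a pause.
#'
#' @param rec A [trace_recording()] with the breath channel present.
#' @param cfg A [breath_cfg()].
#' @return Tibble of class `breath_tbl`, one row per breath: `index`,
#'   `onset_s`, `insp_end_s`, `offset_s`, `ti_s`, `te_s`, `tt_s`, `amp`,
#'   `integ_insp`, `ibi_s`. Zero-variance input yields zero rows with a
#'   warning.
#' @export
detect_breaths <- function(rec, cfg = breath_cfg()) {
  stopifnot(inherits(rec, "trace_recording"))
  x <- rec_channel(rec, cfg$channel)
  fs <- rec$sample_rate
  if (length(x) < 2 * fs) abort("recording must be at least 2 s long.")
  empty <- tibble(
    index = integer(), onset_s = numeric(), insp_end_s = numeric(),
    offset_s = numeric(), ti_s = numeric(), te_s = numeric(),
    tt_s = numeric(), amp = numeric(), integ_insp = numeric(),
    ibi_s = numeric()
  )
  if (sd(x) == 0) {
    warn("breath channel has zero variance; no breaths detected.")
    return(new_breath_tbl(empty))
  }
  if (cfg$invert) x <- -x
  t <- rec$signals$time_s
  xf <- filter_breath_signal(x, fs, cfg)
  xh <- filter_breath_signal(x, fs, cfg, lowpass = FALSE)
  if (cfg$refine_lowpass_hz > 0 && cfg$refine_lowpass_hz < fs / 2) {
    rlp <- signal::butter(2, cfg$refine_lowpass_hz / (fs / 2), type = "low")
    xh <- filtfilt_padded(rlp, xh, round(3 * fs))
  }

  ups <- zero_crossings(xf, t, up = TRUE)
  downs <- zero_crossings(xf, t, up = FALSE)
  # a recording that opens mid-inspiration contributes its first breath
  if (length(ups) && length(downs) && downs[1] < ups[1] && xf[1] >= 0) {
    ups <- c(t[1], ups)
  }
  if (length(ups) < 2) {
    warn("fewer than two candidate cycles; no breaths detected.")
    return(new_breath_tbl(empty))
  }

  # candidate amplitude = inspiratory-lobe peak within each cycle
  ends <- c(ups[-1], t[length(t)])
  i_on <- findInterval(ups, t)
  i_end <- pmax(i_on + 1, findInterval(ends, t))
  cand_amp <- vapply(seq_along(ups), function(k) {
    max(xf[i_on[k]:i_end[k]])
  }, 0)
  ref_amp <- quantile(cand_amp, 0.95, names = FALSE)
  floor_amp <- cfg$amp_floor_frac * ref_amp
  keep <- cand_amp >= floor_amp
  # enforce the minimum cycle duration against the next *kept* onset
  kept_idx <- which(keep)
  if (length(kept_idx) >= 2) {
    ok <- c(diff(ups[kept_idx]) >= cfg$min_tt, TRUE)
    kept_idx <- kept_idx[ok]
  }
  if (!length(kept_idx)) {
    warn("no candidate cycles above the amplitude floor; no breaths detected.")
    return(new_breath_tbl(empty))
  }

  # two-pass onset refinement: free fits first, then re-fit with shrinkage
  # toward the session-typical cycle shape, which sharpens the onset
  # estimate without constraining it directly
  kept_amp <- cand_amp[kept_idx]
  fits <- lapply(seq_along(kept_idx), function(j) {
    refine_onset(ups[kept_idx[j]], kept_amp[j], xf, xh, t, fs)
  })
  pars <- do.call(rbind, lapply(fits, function(f) {
    if (is.null(f$pars)) rep(NA_real_, 4) else f$pars
  }))
  ok_fit <- rowSums(is.na(pars)) == 0
  if (sum(ok_fit) >= 10) {
    rel_a <- pars[ok_fit, 1] / kept_amp[ok_fit]
    rel_b <- pars[ok_fit, 2] / kept_amp[ok_fit]
    mad_v <- function(x) max(stats::mad(x), 1e-6)
    prior <- list(
      rel_a = median(rel_a), var_a = mad_v(rel_a)^2,
      rel_b = median(rel_b), var_b = mad_v(rel_b)^2,
      ti = median(pars[ok_fit, 3]), var_ti = mad_v(pars[ok_fit, 3])^2,
      te = median(pars[ok_fit, 4]), var_te = mad_v(pars[ok_fit, 4])^2,
      sigma2 = median(vapply(fits[ok_fit], `[[`, 0, "rms"))^2
    )
    fits <- lapply(seq_along(kept_idx), function(j) {
      refine_onset(ups[kept_idx[j]], kept_amp[j], xf, xh, t, fs,
                   prior = prior)
    })
  }
  onsets <- vapply(fits, `[[`, 0, "t0")
  onsets <- sort(onsets)
  n_b <- length(onsets)
  next_onset <- c(onsets[-1], t[length(t)])
  dt <- 1 / fs

  rows <- vector("list", n_b)
  for (k in seq_len(n_b)) {
    i0 <- findInterval(onsets[k], t) + 1
    i1 <- max(i0, findInterval(next_onset[k], t))
    seg <- xf[i0:i1]
    pk <- which.max(seg)
    amp <- seg[pk]
    jd <- findInterval(t[i0 + pk - 1], downs)
    insp_end <- if (jd < length(downs)) {
      min(downs[jd + 1], next_onset[k])
    } else next_onset[k]
    # expiratory end: after the post-inspiratory trough, first return within
    # exp_end_frac of the breath amplitude
    j0 <- findInterval(insp_end, t) + 1
    offset <- next_onset[k]
    if (j0 < i1) {
      eseg <- xf[j0:i1]
      tr <- which.min(eseg)
      if (eseg[tr] < 0) {
        back <- which(eseg[tr:length(eseg)] > -cfg$exp_end_frac * amp)
        if (length(back)) {
          offset <- min(t[j0 + tr - 1 + back[1] - 1], next_onset[k])
        }
      }
    }
    if (offset <= insp_end) offset <- min(insp_end + dt, next_onset[k])
    integ <- sum(pmax(xf[i0:max(i0, findInterval(insp_end, t))], 0)) * dt
    rows[[k]] <- c(onset = onsets[k], insp_end = insp_end, offset = offset,
                   amp = amp, integ = integ, next_onset = next_onset[k])
  }
  m <- do.call(rbind, rows)
  # a breath ends at the next onset unless a genuine pause follows the
  # expiratory lobe (gap longer than half the median IBI): then the offset
  # stays at the expiratory end and the IBI exceeds TT
  med_ibi <- median(diff(m[, "onset"]))
  if (is.finite(med_ibi)) {
    gap <- m[, "next_onset"] - m[, "offset"]
    no_pause <- gap <= 0.5 * med_ibi
    if (n_b > 1) no_pause[n_b] <- FALSE
    m[no_pause, "offset"] <- m[no_pause, "next_onset"]
  }
  out <- tibble(
    index = seq_len(n_b),
    onset_s = m[, "onset"],
    insp_end_s = m[, "insp_end"],
    offset_s = m[, "offset"],
    ti_s = m[, "insp_end"] - m[, "onset"],
    te_s = m[, "offset"] - m[, "insp_end"],
    tt_s = m[, "offset"] - m[, "onset"],
    amp = m[, "amp"],
    integ_insp = m[, "integ"],
    ibi_s = c(diff(m[, "onset"]), NA_real_)
  )
  new_breath_tbl(out)
}

new_breath_tbl <- function(x) {
  class(x) <- c("breath_tbl", class(x))
  x
}

#' Flag calm breaths
#'
#' A breath is calm iff, within a centred rolling window of `window` breaths,
#' both its cycle duration and its amplitude lie within `[1/k, k]` times the
#' window median, and it does not fall inside a movement-artifact span
#' (local signal RMS above `artifact_factor` times the session median RMS).
#' With fewer breaths than the window, whole-session medians are used.
#'
#' @param breaths A `breath_tbl` from [detect_breaths()].
#' @param rec Optional [trace_recording()]; when supplied, artifact spans are
#'   computed from the breath channel, otherwise that screen is skipped.
#' @param window Rolling window width in breaths (odd; default 21).
#' @param k Tolerance factor around the rolling median (default 2).
#' @param artifact_factor RMS multiple defining a movement artifact
#'   (default 3).
#' @param channel Channel used for the artifact screen.
#' @return The input tibble with a logical `calm` column added.
#' @export
select_calm_breaths <- function(breaths, rec = NULL, window = 21, k = 2,
                                artifact_factor = 3, channel = "breath") {
  if (!nrow(breaths)) abort("`breaths` must be nonempty.")
  if (window %% 2 == 0) window <- window + 1
  n <- nrow(breaths)
  if (n < window) {
    inform("fewer breaths than the rolling window; using session medians.")
    med_tt <- rep(median(breaths$tt_s), n)
    med_amp <- rep(median(breaths$amp), n)
  } else {
    med_tt <- stats::runmed(breaths$tt_s, window, endrule = "median")
    med_amp <- stats::runmed(breaths$amp, window, endrule = "median")
  }
  calm <- is.finite(breaths$tt_s) &
    breaths$tt_s >= med_tt / k & breaths$tt_s <= med_tt * k &
    breaths$amp >= med_amp / k & breaths$amp <= med_amp * k

  if (!is.null(rec) && is.finite(artifact_factor)) {
    x <- rec_channel(rec, channel)
    fs <- rec$sample_rate
    nwin <- max(1, floor(length(x) / fs))  # 1-s windows
    idx <- pmin(nwin, floor(seq_len(length(x)) / fs) + 1)
    rms <- sqrt(tapply(x^2, idx, mean))
    med_rms <- median(rms)
    bad <- which(rms > artifact_factor * med_rms)
    if (length(bad)) {
      breath_win <- pmin(nwin, floor(breaths$onset_s) + 1)
      calm <- calm & !(breath_win %in% bad)
    }
  }
  breaths$calm <- calm
  breaths
}
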