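sinusoid_rec <- function(freq = 2, duration = 60, fs = 200) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  trace_recording(tibble::tibble(time_s = t, breath = sin(2 * pi * freq * t)),
                  fs)
}

test_that("a pure 2 Hz sinusoid yields 120 symmetric breaths per minute", {
  b <- detect_breaths(sinusoid_rec())
  expect_equal(nrow(b), 120)
  expect_equal(mean(b$ti_s), 0.25, tolerance = 0.02)
  expect_equal(mean(b$te_s), 0.25, tolerance = 0.02)
  # onset < insp_end < offset and TT = offset - onset on every row
  expect_true(all(b$onset_s < b$insp_end_s & b$insp_end_s < b$offset_s))
  expect_equal(b$tt_s, b$offset_s - b$onset_s)
})

test_that("detected onsets match ground truth exactly at default noise", {
  for (seed in 1:3) {
    s <- sim_breathing_trace(breath_model(), 60, 100, seed = seed)
    b <- detect_breaths(s$recording)
    m <- match_events(b$onset_s, s$truth$breath_onsets, tol = 1 / 100)
    expect_equal(unname(m["recall"]), 1)
    expect_equal(unname(m["precision"]), 1)
  }
})

test_that("degenerate inputs warn instead of erroring", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  flat <- trace_recording(tibble::tibble(time_s = t, breath = rep(0, 1000)),
                          100)
  expect_warning(b <- detect_breaths(flat), "zero variance")
  expect_equal(nrow(b), 0)
  norec <- trace_recording(tibble::tibble(time_s = t, flow = rep(0, 1000)),
                           100)
  expect_error(detect_breaths(norec), "channel")
})

test_that("detection is invariant to uniform gain", {
  s <- sim_breathing_trace(breath_model(), 60, 100, seed = 6)
  b1 <- detect_breaths(s$recording)
  rec2 <- s$recording
  rec2$signals$breath <- 37.5 * rec2$signals$breath
  b2 <- detect_breaths(rec2)
  expect_equal(nrow(b1), nrow(b2))
  expect_true(max(abs(b1$onset_s - b2$onset_s)) <= 1 / 100)
})

test_that("Ti + Te of consecutive breaths tile a gap-free span", {
  p <- breath_model(apnea_rate = 0, sigh_rate = 0)
  s <- sim_breathing_trace(p, 60, 100, seed = 2)
  b <- detect_breaths(s$recording)
  inner <- b[2:(nrow(b) - 1), ]
  span <- b$onset_s[nrow(b)] - b$onset_s[2]
  expect_equal(sum(inner$ti_s + inner$te_s), span,
               tolerance = 2 / 100 / span * nrow(inner))
})

test_that("apneic pauses lengthen the IBI but not the breath itself", {
  p <- breath_model(rate_mean = 120, apnea_rate = 300 / 120, sigh_rate = 0,
                    apnea_ibi_factor = 2.5, noise_sd = 0)
  s <- sim_breathing_trace(p, 60, 100, seed = 3)
  b <- detect_breaths(s$recording)
  k <- s$truth$event_log$breath_index[s$truth$event_log$type == "apnea"]
  stretched <- b$ibi_s[k]
  expect_true(all(stretched > 2 * median(b$ibi_s, na.rm = TRUE)))
  expect_true(all(b$tt_s[k] < 1.5 * median(b$tt_s)))
  expect_true(all(b$ibi_s[k] >= b$tt_s[k] - 1 / 100))
})

test_that("calm flags follow the rolling-median rule", {
  # metronomic input: everything calm
  b <- select_calm_breaths(detect_breaths(sinusoid_rec()))
  expect_true(all(b$calm))

  # a single 5x-TT outlier is the only non-calm breath
  ibis <- rep(0.4, 60)
  tb <- breath_table(ibis)
  tb$tt_s[30] <- 5 * 0.32
  flagged <- select_calm_breaths(tb)
  expect_false(flagged$calm[30])
  expect_true(all(flagged$calm[-30]))

  # k -> Inf disables the filter
  tb2 <- breath_table(ibis, amps = runif(60, 0.5, 3))
  all_calm <- select_calm_breaths(tb2, k = Inf, artifact_factor = Inf)
  expect_true(all(all_calm$calm))
})

test_that("short sessions fall back to whole-session medians with a note", {
  tb <- breath_table(rep(0.4, 8))
  expect_message(out <- select_calm_breaths(tb, window = 21), "session median")
  expect_true(all(out$calm))
})
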