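# one scored default session is shared across blocks (scoring is pure)
scored_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ses <- sim_autoresus_session(seed = 3)
      cache <<- list(ses = ses,
                     scored = suppressMessages(score_session(ses$recording)))
    }
    cache
  }
})

test_that("recovery_latency finds grid crossings with interpolation", {
  grid <- tibble::tibble(time_s = seq(0, 100, by = 0.1))
  grid$hr_bpm <- 100 + (450 - 100) * (1 - exp(-grid$time_s / 20))
  lat <- recovery_latency(grid, 450, 0.63, t0 = 0)
  expect_equal(lat, recovery_latency_exact(450, 100, 20, 0.63),
               tolerance = 0.1)

  # already above threshold at t0 -> zero
  high <- tibble::tibble(time_s = seq(0, 10, 0.1), v = rep(400, 101))
  expect_equal(recovery_latency(high, 450, 0.63, t0 = 0), 0)

  # monotone-decreasing series -> undefined
  dec <- tibble::tibble(time_s = seq(0, 10, 0.1),
                        v = seq(300, 100, length.out = 101))
  expect_true(is.na(recovery_latency(dec, 450, 0.9, t0 = 0)))

  expect_error(recovery_latency(grid, -1, 0.63, 0), "positive")
})

test_that("baseline values recover the programmed physiology within 1%", {
  fx <- scored_fixture()
  base <- fx$scored$baseline
  expect_equal(base$vf, 180, tolerance = 0.01)
  expect_equal(base$hr, 450, tolerance = 0.01)
  expect_error(score_baseline(NULL, NULL, baseline_end = 0), "positive")
})

test_that("apnea onset detection recovers the programmed induction time", {
  fx <- scored_fixture()
  got <- fx$scored$trials$induction_s
  want <- fx$ses$truth$trials$induction_s
  expect_true(all(abs(got - want) <= 1))  # within ~2 breath periods

  # doubling the terminal gap leaves a clean cessation unchanged
  sc2 <- suppressMessages(score_session(fx$ses$recording,
                                        terminal_apnea_gap = 20))
  expect_equal(sc2$trials$induction_s, fx$scored$trials$induction_s,
               tolerance = 1e-6)

  # breathing that never ceases is unscoreable
  p <- breath_model(apnea_rate = 0, sigh_rate = 0)
  s <- sim_breathing_trace(p, 60, 100, seed = 1)
  b <- detect_breaths(s$recording)
  expect_warning(ap <- detect_apnea_onset(b, switch_time = 10,
                                          next_switch = 55), "unscoreable")
  expect_true(is.na(ap$induction_s))
})

test_that("gasp metrics follow the programmed gasp train", {
  fx <- scored_fixture()
  tr <- fx$scored$trials
  tru <- fx$ses$truth$trials
  ok <- tru$recovers
  expect_true(all(abs(tr$gasp_latency_s[ok] - tru$gasp_latency_s[ok]) <= 1))
  expect_true(all(abs(tr$inter_gasp_s[ok] - tru$inter_gasp_s[ok]) <= 0.5))
  expect_equal(tr$gasps_per_min[ok], 60 / tr$inter_gasp_s[ok])
  # terminal trial: one gasp -> latency defined, interval undefined
  expect_true(is.na(tr$inter_gasp_s[!ok]))
  expect_false(is.na(tr$gasp_latency_s[!ok]))
})

test_that("a five-trial session scores four survived episodes", {
  fx <- scored_fixture()
  expect_equal(nrow(fx$scored$trials), 5)
  expect_equal(fx$scored$episodes_survived, 4)
  expect_false(fx$scored$trials$survived[5])
})

test_that("faster HR than VF recovery gives negative decoupling on every trial", {
  fx <- scored_fixture()
  tr <- fx$scored$trials[fx$scored$trials$survived, ]
  expect_true(all(tr$decoupling_s < 0))
  # the ledger identity holds exactly
  expect_equal(tr$decoupling_s, tr$lat_hr63_s - tr$lat_vf50_s)
})

test_that("latencies match truth within the breathing-jitter bound", {
  fx <- scored_fixture()
  tr <- fx$scored$trials[fx$scored$trials$survived, ]
  tru <- fx$ses$truth$trials[fx$ses$truth$trials$recovers, ]
  # VF is tracked through interbreath intervals, so the crossing time moves
  # by the period jitter translated through the recovery slope:
  # 3 sigma_cv * threshold / slope, plus one breath period and a grid step
  vf_thr <- 0.5 * 180
  trial <- autoresus_trial()
  slope <- (180 - trial$vf_floor) / trial$vf_recovery_tau *
    exp(-tru$lat_vf50_s[1] / trial$vf_recovery_tau)   # breaths/min per s
  tol_vf <- 0.1 + 60 / vf_thr + 3 * 0.04 * vf_thr / slope
  expect_true(all(abs(tr$lat_vf50_s - tru$lat_vf50_s) <= tol_vf))
  # HR rides on a clean dedicated channel: one grid step plus beat spacing
  expect_true(all(abs(tr$lat_hr63_s - tru$lat_hr63_s) <= 0.5))
})

test_that("per-trial timing invariants hold on every scored trial", {
  fx <- scored_fixture()
  tr <- fx$scored$trials
  expect_true(all(tr$apnea_onset_s > tr$switch_s, na.rm = TRUE))
  expect_true(all(tr$gasp_latency_s > 0, na.rm = TRUE))
  expect_true(all(tr$lat_hr63_s >= 0, na.rm = TRUE))
  expect_true(all(tr$lat_vf50_s >= 0, na.rm = TRUE))
})

test_that("scoring is invariant to appended post-terminal silence", {
  fx <- scored_fixture()
  rec <- fx$ses$recording
  fs <- rec$sample_rate
  extra <- tibble::tibble(
    time_s = max(rec$signals$time_s) + seq_len(30 * fs) / fs,
    breath = 0, cardiac = 0
  )
  rec2 <- trace_recording(dplyr::bind_rows(rec$signals, extra), fs,
                          markers = rec$markers, animal = rec$animal)
  sc2 <- suppressMessages(suppressWarnings(score_session(rec2)))
  expect_equal(sc2$episodes_survived, fx$scored$episodes_survived)
  expect_equal(sc2$trials$induction_s, fx$scored$trials$induction_s,
               tolerance = 0.05)
})

test_that("tidy and glance expose the session tables", {
  fx <- scored_fixture()
  expect_identical(tidy(fx$scored), fx$scored$trials)
  g <- glance(fx$scored)
  expect_equal(g$episodes_survived, 4)
  expect_equal(g$n_trials, 5)
})
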