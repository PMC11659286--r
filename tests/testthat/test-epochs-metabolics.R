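gas_only_rec <- function(proto, vo2 = 0, fs = 5) {
  gas <- sim_gas_channels(proto, programmed_vo2 = vo2, sample_rate = fs)
  trace_recording(
    tibble::tibble(time_s = gas$time_s,
                   breath = sin(2 * pi * 2.5 * gas$time_s),
                   o2_pct = gas$o2_pct, co2_pct = gas$co2_pct,
                   chamber_temp_c = gas$chamber_temp_c),
    fs
  )
}

test_that("a marker-driven session produces the seven analysis epochs", {
  proto <- adult_protocol()
  rec <- gas_only_rec(proto)
  rec$markers <- tibble::tibble(
    time_s = seq(0, 4800, by = 1200),
    label = paste0("gas_", proto$epochs$label)
  )
  eps <- assign_epochs(rec, proto)
  expect_equal(eps$label, c("room_air_1", "cap_reflex", "cap_ss",
                            "room_air_2", "hyp_reflex", "hyp_ss",
                            "room_air_3"))
  expect_true(all(eps$end_s > eps$start_s))
  # half-open epochs must not overlap within each gas period
  ra <- eps[grepl("room_air", eps$label), ]
  expect_true(all(ra$end_s - ra$start_s == 300))
  expect_true(all(eps$usable))
})

test_that("the 90%-of-target crossing matches the closed form", {
  # tau = 2 min, switch at t = 1200 s: t90 = 1200 + tau * ln 10
  proto <- adult_protocol(
    epochs = tibble::tibble(
      label = c("room_air_1", "hypoxia", "room_air_2"),
      o2 = c(0.2095, 0.10, 0.2095), co2 = c(0, 0, 0),
      duration_s = c(1200, 1200, 1200)),
    flow_rate = 198, chamber_volume = 198 * 2
  )
  rec <- gas_only_rec(proto)
  rec$markers <- tibble::tibble(time_s = c(0, 1200, 2400),
                                label = paste0("gas_", proto$epochs$label))
  eps <- assign_epochs(rec, proto)
  t90 <- eps$start_s[eps$label == "hyp_reflex"]
  expect_equal(t90, 1200 + 120 * log(10), tolerance = 0.5)
})

test_that("disordered markers raise an input error naming the marker", {
  proto <- adult_protocol()
  rec <- gas_only_rec(proto)
  rec$markers <- tibble::tibble(
    time_s = c(0, 2400, 1200, 3600, 4800),
    label = paste0("gas_", proto$epochs$label)
  )
  expect_error(assign_epochs(rec, proto), "out of order")
})

test_that("switches are detected from gas channels when markers are absent", {
  proto <- adult_protocol(chamber_volume = 100)
  rec <- gas_only_rec(proto)
  eps <- assign_epochs(rec, proto)
  expect_equal(nrow(eps), 7)
  # detected hypercapnic switch is near the true 1200 s switch
  expect_lt(abs(eps$start_s[eps$label == "cap_ss"] - 2100), 60)
})

test_that("VO2 follows the flow-through mass balance", {
  proto <- adult_protocol(
    epochs = tibble::tibble(label = "room_air_1", o2 = 0.2095, co2 = 0,
                            duration_s = 1200))
  rec <- gas_only_rec(proto, vo2 = 0)
  ep <- tibble::tibble(label = "x", start_s = 600, end_s = 1200)
  expect_equal(compute_vo2(rec, ep, 198, 25), 0, tolerance = 1e-10)

  # arithmetic case: flow 198, dO2 0.45%, 25 g
  rec2 <- rec
  rec2$signals$o2_pct <- rep(20.50, nrow(rec2$signals))
  got <- compute_vo2(rec2, ep, 198, 25, fio2 = 0.2095)
  expect_equal(got, 198 * 0.0045 / 25, tolerance = 1e-12)
  expect_equal(got, 0.03564, tolerance = 1e-6)

  # inverted gradient is surfaced, not clipped
  rec3 <- rec
  rec3$signals$o2_pct <- rep(21.5, nrow(rec3$signals))
  expect_warning(neg <- compute_vo2(rec3, ep, 198, 25), "negative VO2")
  expect_lt(neg, 0)
})

test_that("programmed VO2 is recovered within 2% at steady state", {
  errs <- vapply(1:10, function(seed) {
    vo2 <- withr::with_seed(seed, runif(1, 0.5, 1.5))
    proto <- adult_protocol(
      epochs = tibble::tibble(label = "room_air_1", o2 = 0.2095, co2 = 0,
                              duration_s = 2400))
    gas <- sim_gas_channels(proto, programmed_vo2 = vo2, sample_rate = 5,
                            noise_sd = 0.01, seed = seed)
    rec <- trace_recording(gas, 5)
    ep <- tibble::tibble(label = "ss", start_s = 2100, end_s = 2400)
    got <- compute_vo2(rec, ep, 198, 25, fio2 = 0.2095) * 25
    abs(got - vo2) / vo2
  }, 0)
  expect_true(all(errs <= 0.02))
})

test_that("condition summaries satisfy VE = Vf x VT and the exclusion rule", {
  meta <- animal_meta("a1", "GF", "F", weight_g = 25)
  tb <- breath_table(rep(0.4, 100), amps = rep(1, 100))
  tb$tt_s <- 0.4  # gap-free metronomic breathing: TT equals the IBI
  tb$calm <- TRUE
  tb$vt_ml <- 0.15
  ep <- tibble::tibble(label = "room_air_1", start_s = 0, end_s = 50)
  calls <- call_apneas(tb, epoch_label = "room_air_1")
  row <- summarize_condition(tb, calls, ep, meta)
  expect_equal(row$vf, 150)
  expect_equal(row$ve_ml_min, 22.5)
  expect_equal(row$ve_ml_min, row$vf * row$vt_ml)
  expect_equal(row$ve_ml_min_g, row$ve_ml_min / 25)

  # five calm breaths under min_breaths = 20: no row, logged
  few <- tb[1:5, ]
  expect_message(out <- summarize_condition(few, calls, ep, meta), "excluded")
  expect_null(out)
})

test_that("percent change uses the immediately preceding room-air reference", {
  summaries <- dplyr::bind_rows(
    tibble::tibble(animal_id = "a1", epoch_label = "room_air_1", vf = 100,
                   ve_ml_min = 20),
    tibble::tibble(animal_id = "a1", epoch_label = "cap_ss", vf = 150,
                   ve_ml_min = 30),
    tibble::tibble(animal_id = "a1", epoch_label = "room_air_2", vf = 110,
                   ve_ml_min = 22),
    tibble::tibble(animal_id = "a1", epoch_label = "hyp_ss", vf = 110,
                   ve_ml_min = 22)
  )
  pc <- percent_change(summaries, variables = c("vf", "ve_ml_min"))
  cap_ve <- pc$value[pc$challenge == "hypercapnia" & pc$variable == "ve_ml_min"]
  expect_equal(cap_ve, 50)
  hyp_vf <- pc$value[pc$challenge == "hypoxia" & pc$variable == "vf"]
  expect_equal(hyp_vf, 0)

  # per-gram and absolute ventilation give identical percent changes
  summaries$ve_ml_min_g <- summaries$ve_ml_min / 25
  pc2 <- percent_change(summaries, variables = c("ve_ml_min", "ve_ml_min_g"))
  wide <- tidyr::pivot_wider(pc2, names_from = "variable",
                             values_from = "value")
  expect_equal(wide$ve_ml_min, wide$ve_ml_min_g)
})

test_that("positive shifts give positive percent changes for every animal", {
  withr::with_seed(3, {
    summaries <- tidyr::expand_grid(
      animal_id = paste0("a", 1:6),
      epoch_label = c("room_air_1", "cap_ss", "room_air_2", "hyp_ss")
    ) |>
      dplyr::mutate(ve_ml_min = runif(dplyr::n(), 10, 20))
    summaries$ve_ml_min[summaries$epoch_label %in% c("cap_ss", "hyp_ss")] <-
      summaries$ve_ml_min[summaries$epoch_label %in% c("cap_ss", "hyp_ss")] + 15
  })
  pc <- percent_change(summaries, variables = "ve_ml_min")
  expect_true(all(pc$value > 0))
})
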