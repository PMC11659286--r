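test_that("the 10-IBI worked example yields exactly one apnea", {
  tb <- breath_table(c(rep(0.25, 9), 0.60))
  # brute-force oracle over the ten IBIs
  ref <- mean(tb$ibi_s)
  expect_equal(ref, 0.285)
  oracle_hits <- which(tb$ibi_s >= 2 * ref)
  calls <- call_apneas(tb)
  expect_equal(nrow(calls), 1)
  expect_equal(length(oracle_hits), 1)
  expect_equal(calls$breath_index, tb$index[oracle_hits])
  expect_gte(calls$magnitude, 2)
})

test_that("constant IBIs produce no apneas and equal amps no sighs", {
  tb <- breath_table(rep(0.25, 20))
  expect_equal(nrow(call_apneas(tb)), 0)
  expect_equal(nrow(call_sighs(tb)), 0)
})

test_that("the comparison boundary is inclusive", {
  # one IBI exactly 2x the mean of all IBIs: x = 2(19*a + x)/20
  a <- 0.3
  x <- 2 * 19 * a / 18
  tb <- breath_table(c(rep(a, 19), x))
  expect_equal(x, 2 * mean(tb$ibi_s))
  expect_equal(nrow(call_apneas(tb)), 1)
})

test_that("the 20-amplitude worked example yields exactly one sigh", {
  tb <- breath_table(rep(0.25, 20), amps = c(rep(1, 19), 2.5))
  ref <- mean(tb$amp)
  expect_equal(ref, 1.075)
  calls <- call_sighs(tb)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$breath_index, 20L)
})

test_that("sigh calls are invariant to uniform gain", {
  amps <- c(rep(1, 19), 2.5)
  a1 <- call_sighs(breath_table(rep(0.25, 20), amps = amps))
  a2 <- call_sighs(breath_table(rep(0.25, 20), amps = 10 * amps))
  expect_equal(a1$breath_index, a2$breath_index)
  expect_equal(a1$magnitude, a2$magnitude)
})

test_that("raising the factor never increases the number of calls", {
  withr::with_seed(1, {
    tb <- breath_table(runif(100, 0.2, 0.6), amps = runif(100, 0.5, 2.5))
  })
  factors <- c(1.2, 1.5, 2, 2.5, 3)
  n_ap <- vapply(factors, function(f) nrow(call_apneas(tb, factor = f)), 0L)
  n_si <- vapply(factors, function(f) nrow(call_sighs(tb, factor = f)), 0L)
  expect_true(all(diff(n_ap) <= 0))
  expect_true(all(diff(n_si) <= 0))
})

test_that("calm flags scope the reference mean", {
  tb <- breath_table(c(rep(0.25, 9), 0.60), calm = c(rep(TRUE, 9), FALSE))
  ref <- mean(tb$ibi_s[tb$calm])
  calls <- call_apneas(tb)
  expect_equal(calls$magnitude, 0.60 / ref)
  # an all-non-calm table falls back to all breaths with a note
  tb$calm <- FALSE
  expect_message(calls2 <- call_apneas(tb), "falls back")
  expect_equal(nrow(calls2), 1)
})

test_that("event rates are exact ratios per 100 breaths", {
  tb <- breath_table(rep(0.1, 600))
  calls <- tibble::tibble(type = rep("apnea", 3), time_s = c(1, 2, 3),
                          magnitude = 2.5, breath_index = 1:3,
                          epoch_label = "x")
  r <- event_rates(calls, tb, epoch_label = "x")
  expect_equal(r$apnea_per100, 0.5)
  expect_equal(r$sqrt_apnea, sqrt(0.5))
  expect_equal(r$sigh_per100, 0)
  expect_equal(r$sqrt_sigh, 0)
  expect_warning(r0 <- event_rates(calls, tb[0, ]), "zero breaths")
  expect_true(is.na(r0$apnea_per100))
})

test_that("pipeline calls equal programmed events on noise-free traces", {
  # programmed factors (2.5) exceed the calling factor (2) by >= 0.25
  for (seed in 1:3) {
    p <- breath_model(rate_mean = 150, sigh_rate = 2, apnea_rate = 2,
                      noise_sd = 0, cardiac_amp = 0)
    s <- sim_breathing_trace(p, 120, 100, seed = seed)
    b <- select_calm_breaths(detect_breaths(s$recording), s$recording)
    ap <- call_apneas(b)
    si <- call_sighs(b)
    log <- s$truth$event_log
    expect_equal(nrow(ap), sum(log$type == "apnea"))
    expect_equal(nrow(si), sum(log$type == "sigh"))
    m <- match_events(si$time_s, log$time_s[log$type == "sigh"], tol = 0.05)
    expect_equal(unname(m["recall"]), 1)
  }
})
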