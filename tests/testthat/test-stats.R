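null_table <- function(seed = 1, n_per_cell = 6) {
  sim_outcome_table(cohort_design(n_per_cell = n_per_cell, seed = seed),
                    n_obs = 5)
}

test_that("identical constant outcomes give a zero estimate and p near 1", {
  tab <- tidyr::expand_grid(animal_id = sprintf("a%02d", 1:12),
                            obs = 1:3) |>
    dplyr::mutate(group = rep(c("SPF", "GF"), each = 18),
                  outcome = 5)
  fit <- suppressWarnings(fit_lmem(tab, "outcome", fixed = "group"))
  expect_equal(fit$contrasts$estimate, 0, tolerance = 1e-10)
  expect_gt(fit$contrasts$p_tukey, 0.99)
})

test_that("the single-contrast case degenerates to the pooled t test", {
  withr::with_seed(4, {
    tab <- tibble::tibble(
      animal_id = sprintf("a%02d", 1:16),
      group = rep(c("SPF", "GF"), each = 8),
      outcome = rnorm(16, mean = rep(c(10, 11), each = 8))
    )
  })
  fit <- suppressWarnings(fit_lmem(tab, "outcome", fixed = "group"))
  tt <- t.test(outcome ~ group, data = tab, var.equal = TRUE)
  expect_equal(fit$contrasts$p_tukey, tt$p.value, tolerance = 1e-9)
  expect_equal(fit$contrasts$p_unadjusted, tt$p.value, tolerance = 1e-9)
  expect_equal(abs(fit$contrasts$estimate),
               unname(abs(diff(tt$estimate))), tolerance = 1e-9)
})

test_that("Tukey-adjusted p never falls below the unadjusted p", {
  for (seed in 1:5) {
    fit <- fit_lmem(null_table(seed), "outcome")
    expect_true(all(fit$contrasts$p_tukey >=
                      fit$contrasts$p_unadjusted - 1e-12))
  }
})

test_that("transform validation names the offending rows", {
  tab <- null_table(2)
  tab$outcome[3] <- -1
  expect_error(fit_lmem(tab, "outcome", transform = "log10"), "rows")
  expect_error(fit_lmem(tab, "outcome", transform = "sqrt"), "rows")
  expect_error(fit_lmem(tab, "outcome", alpha = 1.5), "alpha")
  expect_error(fit_lmem(tab[tab$animal_id == "SPF_F_01", ], "outcome"),
               "2 animals")
})

test_that("preset transforms follow the per-outcome reporting table", {
  expect_equal(choose_transform(NULL, "ti_s")$transform, "sqrt")
  expect_equal(choose_transform(NULL, "vt_ml")$transform, "sqrt")
  expect_equal(choose_transform(NULL, "apnea_per100")$transform, "sqrt")
  expect_equal(choose_transform(NULL, "sigh_per100")$transform, "sqrt")
  for (o in c("te_s", "tt_s", "vf", "ve_ml_min", "vo2_ml_min_g",
              "ve_over_vo2")) {
    expect_equal(choose_transform(NULL, o)$transform, "log10")
  }
  expect_equal(choose_transform(NULL, "weight_g")$transform, "raw")
})

test_that("automatic selection finds the normalising transform", {
  # log-normal outcome: log10 has the highest residual QQ correlation
  d <- cohort_design(n_per_cell = 8, animal_sd = 0, residual_sd = 0.5,
                     grand_mean = 2, seed = 6)
  tab <- sim_outcome_table(d, n_obs = 10)
  tab$outcome <- 10^tab$outcome
  pick <- suppressWarnings(choose_transform(tab, "outcome", mode = "auto"))
  expect_equal(pick$transform, "log10")
  expect_equal(nrow(pick$diagnostics), 3)

  # already-normal residuals keep the raw scale
  tab2 <- null_table(7)
  tab2$outcome <- tab2$outcome + 10  # keep strictly positive
  pick2 <- suppressWarnings(choose_transform(tab2, "outcome", mode = "auto"))
  expect_equal(pick2$transform, "raw")
})

test_that("zero alpha rejects nothing", {
  d <- cohort_design(n_per_cell = 4, seed = 3)
  out <- type1_error_suite(d, n_reps = 5, seed = 1, alpha = 1e-12)
  expect_equal(out$rejection_fraction, 0)
  expect_error(
    type1_error_suite(cohort_design(group_effect = 1), n_reps = 2),
    "zero"
  )
})

test_that("rejection is nondecreasing in the programmed effect size", {
  frac <- vapply(c(0, 1.2), function(eff) {
    d <- cohort_design(n_per_cell = 6, group_effect = eff, animal_sd = 0.5,
                       residual_sd = 0.5, seed = 2)
    hits <- vapply(1:15, function(r) {
      tab <- sim_outcome_table(d, n_obs = 5, seed = 1000 + r)
      fit <- suppressWarnings(fit_lmem(tab, "outcome"))
      any(fit$contrasts$p_tukey[grepl("GF", fit$contrasts$contrast) &
                                  grepl("SPF", fit$contrasts$contrast)] < 0.05)
    }, TRUE)
    mean(hits)
  }, 0)
  expect_lte(frac[1], frac[2])
  expect_gt(frac[2], 0.5)
})

test_that("reports are deterministic and match brute-force cell means", {
  tab <- null_table(9)
  fit <- fit_lmem(tab, "outcome")
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r1 <- render_report(list(fit), tab, d1)
  r2 <- render_report(list(fit), tab, d2)
  for (f in seq_along(r1$files)) {
    expect_identical(readLines(r1$files[f]), readLines(r2$files[f]))
  }
  # brute-force aggregation oracle
  want <- aggregate(outcome ~ group + sex, data = tab, FUN = mean)
  got <- r1$cell_means
  for (i in seq_len(nrow(want))) {
    row <- got[got$group == want$group[i] & got$sex == want$sex[i], ]
    expect_equal(row$mean, want$outcome[i], tolerance = 1e-12)
  }
  # empty contrast table still renders
  fit0 <- fit
  fit0$contrasts <- fit$contrasts[0, ]
  r0 <- render_report(list(fit0), tab, file.path(tempdir(), "rep0"))
  expect_true(any(grepl("no contrasts", readLines(r0$files[4]))))
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- fit_lmem(null_table(10), "outcome")
  expect_identical(tidy(fit), fit$contrasts)
  g <- glance(fit)
  expect_equal(g$df_method, "satterthwaite")
  expect_s3_class(autoplot(fit), "ggplot")
})
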