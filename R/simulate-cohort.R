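#' Cohort design for synthetic group/sex studies
#'
#' Generates per-animal outcome parameters as
#' `grand_mean + group_effect * [GF] + sex_effect * [M] + animal intercept`,
#' with per-observation residual noise added wherever repeated measures are
#' drawn. Used both to drive the trace generators and to feed the
#' mixed-model stage with data of known structure.
#'
#' @param n_per_cell Animals per group x sex cell (>= 2).
#' @param group_effect Additive shift for the GF group, outcome units.
#' @param sex_effect Additive shift for males, outcome units.
#' @param animal_sd SD of the per-animal random intercept.
#' @param residual_sd SD of per-observation residual noise.
#' @param grand_mean Outcome grand mean (SPF female cell mean).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_cell = 6, group_effect = 0, sex_effect = 0,
                          animal_sd = 0.5, residual_sd = 0.5,
                          grand_mean = 30, seed = 1) {
  if (n_per_cell < 2) {
    abort("`n_per_cell` must be >= 2 (the model is unidentifiable below that).")
  }
  if (animal_sd < 0 || residual_sd < 0) abort("SDs must be non-negative.")
  structure(as.list(environment()), class = "cohort_design")
}

cohort_animals <- function(design) {
  cells <- tidyr::expand_grid(group = c("SPF", "GF"), sex = c("F", "M"))
  animals <- cells[rep(seq_len(nrow(cells)), each = design$n_per_cell), ]
  animals$animal_id <- sprintf("%s_%s_%02d", animals$group, animals$sex,
                               sequence(rep(design$n_per_cell, nrow(cells))))
  animals$group <- factor(animals$group, levels = c("SPF", "GF"))
  animals$sex <- factor(animals$sex, levels = c("F", "M"))
  animals$intercept <- rnorm(nrow(animals), 0, design$animal_sd)
  animals$param_value <- design$grand_mean +
    design$group_effect * (animals$group == "GF") +
    design$sex_effect * (animals$sex == "M") +
    animals$intercept
  as_tibble(animals)
}

#' Simulate a cohort of recordings with known group/sex structure
#'
#' For the adult paradigm each animal's breathing-rate parameter, and for the
#' neonate paradigm each animal's apnea-induction time, is drawn from the
#' cohort design; one recording per animal is rendered with a per-animal seed
#' substream.
#'
#' @param design A [cohort_design()].
#' @param paradigm `"adult"` (plethysmography breathing trace) or
#'   `"neonate"` (autoresuscitation session).
#' @param duration Adult trace length, s (ignored for neonates).
#' @param n_trials Trials per neonate session (ignored for adults).
#' @param sample_rate Hz.
#' @return List with `metadata` (tibble: animal_id, group, sex, weight_g,
#'   param_value) and `sessions` (named list of `recording`/`truth` pairs).
#' @export
sim_cohort <- function(design, paradigm = c("adult", "neonate"),
                       duration = 60, n_trials = 3, sample_rate = 200) {
  stopifnot(inherits(design, "cohort_design"))
  paradigm <- match.arg(paradigm)
  local_seed(design$seed)
  animals <- cohort_animals(design)
  animals$weight_g <- if (paradigm == "adult") {
    rnorm(nrow(animals), 25, 2) + 2 * (animals$sex == "M")
  } else {
    rnorm(nrow(animals), 4.5, 0.4) + 0.5 * (animals$sex == "M")
  }
  # per-animal substreams from a stable hash of the animal id
  sub_seeds <- vapply(animals$animal_id, stable_seed, 0L,
                      base = sample.int(2^20, 1))
  sessions <- vector("list", nrow(animals))
  names(sessions) <- animals$animal_id
  for (i in seq_len(nrow(animals))) {
    meta <- animal_meta(
      id = animals$animal_id[i], group = as.character(animals$group[i]),
      sex = as.character(animals$sex[i]), weight_g = animals$weight_g[i],
      temp_pre_c = 37, temp_post_c = 37
    )
    if (paradigm == "adult") {
      pars <- breath_model(rate_mean = clamp(animals$param_value[i], 11, 899))
      sessions[[i]] <- sim_breathing_trace(
        pars, duration = duration, sample_rate = sample_rate,
        seed = sub_seeds[i], animal = meta
      )
    } else {
      trs <- c(
        lapply(seq_len(max(1, n_trials - 1)), function(k) {
          autoresus_trial(
            induction_time = max(5, animals$param_value[i] +
                                   rnorm(1, 0, design$residual_sd)))
        }),
        list(autoresus_trial(
          induction_time = max(5, animals$param_value[i] +
                                 rnorm(1, 0, design$residual_sd)),
          gasp_intervals = c(42), recovers = FALSE))
      )
      sessions[[i]] <- sim_autoresus_session(
        trs, sample_rate = sample_rate, seed = sub_seeds[i], animal = meta
      )
    }
  }
  list(
    metadata = animals |>
      select("animal_id", "group", "sex", "weight_g", "param_value"),
    sessions = sessions
  )
}

#' Simulate an outcome table with known fixed and random effects
#'
#' Draws `n_obs` repeated measures per animal:
#' `y_ij = grand_mean + group_effect*[GF] + sex_effect*[M] + b_i + e_ij`
#' with `b_i ~ N(0, animal_sd^2)`, `e_ij ~ N(0, residual_sd^2)`. This is the
#' outcome-level view of a cohort, used for statistical parameter-recovery
#' and type-I-error simulations where rendering full waveforms would add
#' nothing.
#'
#' @param design A [cohort_design()].
#' @param n_obs Observations (e.g. trials or epochs) per animal.
#' @param seed Optional override of `design$seed`.
#' @return Tibble: `animal_id`, `group`, `sex`, `obs`, `outcome`.
#' @export
sim_outcome_table <- function(design, n_obs = 5, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  local_seed(seed %||% design$seed)
  animals <- cohort_animals(design)
  tidyr::expand_grid(animal_id = animals$animal_id, obs = seq_len(n_obs)) |>
    left_join(animals, by = "animal_id") |>
    mutate(outcome = .data$param_value +
             rnorm(dplyr::n(), 0, design$residual_sd)) |>
    select("animal_id", "group", "sex", "obs", "outcome")
}

stable_seed <- function(id, base = 0) {
  codes <- as.numeric(utf8ToInt(as.character(id)))
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(base) + h * 2654435) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
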