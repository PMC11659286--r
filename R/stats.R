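#' Fit the study's linear mixed-effects model with Tukey HSD contrasts
#'
#' Restricted-maximum-likelihood fit of a (possibly transformed) outcome on
#' the group x sex (x timepoint, when a `timepoint` column is present) fixed
#' effects with a random intercept per animal, followed by Tukey-adjusted
#' pairwise contrasts over all cells of the fixed-effect design (Satterthwaite
#' degrees of freedom). Unadjusted contrasts are carried alongside, so the
#' guarantee `p_tukey >= p_unadjusted` is inspectable per contrast. A
#' singular random-effect fit falls back to a fixed-effects-only linear
#' model with a prominent warning.
#'
#' @param data Tibble with `animal_id`, the fixed-effect columns, and the
#'   outcome.
#' @param outcome Name of the outcome column.
#' @param transform `"raw"`, `"log10"` (positive values only) or `"sqrt"`
#'   (non-negative values only).
#' @param fixed Fixed-effect factor columns; default: whichever of `group`,
#'   `sex`, `timepoint` are present.
#' @param covariates Optional numeric covariate columns added to the fixed
#'   part.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `lmem_result` with elements `outcome`,
#'   `transform`, `model`, `fixed_effects`, `contrasts` (tibble: contrast,
#'   estimate, SE, df, `p_tukey`, `p_unadjusted`), `diagnostics`
#'   (residual QQ correlation and skewness), `singular_fallback`, `alpha`.
#' @export
fit_lmem <- function(data, outcome, transform = c("raw", "log10", "sqrt"),
                     fixed = NULL, covariates = NULL, alpha = 0.05) {
  transform <- match.arg(transform)
  data <- as_tibble(data)
  if (!outcome %in% names(data)) abort(paste0("no column `", outcome, "`."))
  if (!"animal_id" %in% names(data)) abort("`data` needs an `animal_id` column.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  fixed <- fixed %||% intersect(c("group", "sex", "timepoint"), names(data))
  if (!length(fixed)) abort("no fixed-effect columns found.")

  y <- data[[outcome]]
  bad <- switch(transform,
    raw = integer(),
    log10 = which(!is.na(y) & y <= 0),
    sqrt = which(!is.na(y) & y < 0)
  )
  if (length(bad)) {
    abort(paste0("transform `", transform, "` undefined for rows: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..."))
  }
  data$.y <- switch(transform, raw = y, log10 = log10(y), sqrt = sqrt(y))
  data <- data |> filter(!is.na(.data$.y))

  cells <- data |> distinct(across(all_of(c(fixed, "animal_id"))))
  per_cell <- cells |> count(across(all_of(fixed)))
  if (any(per_cell$n < 2)) {
    abort("need at least 2 animals per cell of the fixed-effect design.")
  }

  fixed_part <- paste(fixed, collapse = " * ")
  if (!is.null(covariates)) {
    fixed_part <- paste(c(fixed_part, covariates), collapse = " + ")
  }
  repeated <- any(data |> count(.data$animal_id) |> pull(.data$n) > 1)
  singular_fallback <- FALSE
  model <- NULL
  if (repeated) {
    fml <- stats::as.formula(paste(".y ~", fixed_part, "+ (1 | animal_id)"))
    model <- tryCatch(
      suppressMessages(lmerTest::lmer(fml, data = data)),
      error = function(e) NULL
    )
    if (!is.null(model) && lme4::isSingular(model, tol = 1e-4)) model <- NULL
  }
  if (is.null(model)) {
    singular_fallback <- TRUE
    warn(paste0("random-intercept fit for `", outcome, "` is singular or ",
                "unidentifiable; falling back to a fixed-effects-only model."))
    fml <- stats::as.formula(paste(".y ~", fixed_part))
    model <- stats::lm(fml, data = data)
  }

  spec_fml <- stats::as.formula(paste("~", fixed_part))
  emm <- emmeans::emmeans(model, spec_fml, lmer.df = "satterthwaite")
  tuk <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  raw_p <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  p_tuk <- pmin(1, tuk$p.value)
  p_raw <- raw_p$p.value[match(tuk$contrast, raw_p$contrast)]
  # a saturated, zero-variance fit carries no evidence of a difference
  degen <- !is.finite(p_tuk) | (tuk$SE < 1e-12 & abs(tuk$estimate) < 1e-12)
  p_tuk[degen] <- 1
  p_raw[degen] <- 1
  contrasts <- tibble(
    contrast = tuk$contrast, estimate = tuk$estimate, se = tuk$SE,
    df = tuk$df, p_tukey = p_tuk,
    p_unadjusted = p_raw,
    significant = p_tuk < alpha
  )

  res <- residuals(model)
  fe <- summary(model)$coefficients
  fe_df <- if ("df" %in% colnames(fe)) fe[, "df"] else
    rep(stats::df.residual(model), nrow(fe))
  structure(
    list(
      outcome = outcome, transform = transform, model = model,
      fixed = fixed,
      fixed_effects = tibble(term = rownames(fe), estimate = fe[, 1],
                             se = fe[, 2], df = fe_df),
      contrasts = contrasts,
      diagnostics = residual_diagnostics(res),
      singular_fallback = singular_fallback,
      alpha = alpha, n_obs = nrow(data),
      n_animals = dplyr::n_distinct(data$animal_id),
      df_method = if (singular_fallback) "residual (lm)" else "satterthwaite"
    ),
    class = "lmem_result"
  )
}

residual_diagnostics <- function(res) {
  res <- res[is.finite(res)]
  qq <- cor(sort(res), qnorm(ppoints(length(res))))
  m <- mean(res); s <- sd(res)
  skew <- if (s > 0) mean((res - m)^3) / s^3 else 0
  tibble(qq_correlation = qq, abs_skewness = abs(skew))
}

#' @export
print.lmem_result <- function(x, ...) {
  cat("<lmem_result> outcome `", x$outcome, "` (", x$transform,
      " scale), ", x$n_obs, " obs / ", x$n_animals, " animals\n", sep = "")
  if (x$singular_fallback) cat("  ! fixed-effects-only fallback\n")
  print(x$contrasts)
  invisible(x)
}

#' Tukey HSD contrast table of a fitted model
#' @param x An `lmem_result`.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts with Tukey-adjusted and unadjusted
#'   p-values.
#' @export
tidy.lmem_result <- function(x, ...) x$contrasts

#' One-row model summary
#' @param x An `lmem_result`.
#' @param ... Unused.
#' @return One-row tibble: outcome, transform, sizes, diagnostics, df
#'   method.
#' @export
glance.lmem_result <- function(x, ...) {
  bind_cols(
    tibble(outcome = x$outcome, transform = x$transform, n_obs = x$n_obs,
           n_animals = x$n_animals, singular_fallback = x$singular_fallback,
           df_method = x$df_method,
           n_significant = sum(x$contrasts$significant)),
    x$diagnostics
  )
}

#' Choose an outcome transform
#'
#' In `"preset"` mode the reporting transform is taken from the study's
#' per-outcome table (inspiratory duration and tidal volume square-root
#' transformed; expiratory/breath-cycle duration, ventilatory frequency,
#' ventilation, oxygen consumption and ventilatory equivalents log10
#' transformed; apnea and sigh rates square-root transformed), regardless of
#' the data. In `"auto"` mode each candidate is fitted and the one with the
#' highest residual QQ correlation wins, ties broken toward `"raw"`;
#' candidates undefined for the data (e.g. log10 with non-positive values)
#' are skipped with a note.
#'
#' @param data Outcome table as for [fit_lmem()].
#' @param outcome Outcome column name.
#' @param mode `"preset"` or `"auto"`.
#' @param candidates Transforms considered in auto mode.
#' @param ... Passed to [fit_lmem()].
#' @return List: `transform` (character) and `diagnostics` (per-candidate
#'   tibble; empty in preset mode).
#' @export
choose_transform <- function(data, outcome, mode = c("preset", "auto"),
                             candidates = c("raw", "log10", "sqrt"), ...) {
  mode <- match.arg(mode)
  if (mode == "preset") {
    return(list(transform = preset_transform(outcome),
                diagnostics = tibble(transform = character(),
                                     qq_correlation = numeric(),
                                     abs_skewness = numeric())))
  }
  diags <- list()
  for (tr in candidates) {
    fit <- tryCatch(
      suppressWarnings(fit_lmem(data, outcome, transform = tr, ...)),
      error = function(e) {
        inform(paste0("candidate `", tr, "` skipped: ",
                      conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    diags[[tr]] <- fit$diagnostics |> mutate(transform = tr, .before = 1)
  }
  if (!length(diags)) abort("no candidate transform is applicable.")
  diags <- list_rbind(diags)
  best <- diags |> arrange(desc(.data$qq_correlation))
  top <- best$transform[abs(best$qq_correlation - best$qq_correlation[1]) < 1e-12]
  chosen <- if ("raw" %in% top) "raw" else top[1]
  list(transform = chosen, diagnostics = diags)
}

preset_transform <- function(outcome) {
  o <- tolower(outcome)
  if (grepl("apnea|sigh", o)) return("sqrt")
  if (grepl("^ti(_|$)|inspiratory", o)) return("sqrt")
  if (grepl("^vt|tidal", o)) return("sqrt")
  if (grepl("^te(_|$)|^tt(_|$)|^vf|^ve|^vo2|ventilat|oxygen|cycle|expiratory", o)) {
    return("log10")
  }
  "raw"
}

#' Type-I-error simulation of the LMEM + Tukey stack
#'
#' Simulates repeated cohorts under the global null (zero group and sex
#' effects), fits the mixed model on each, and reports the fraction of
#' replicates in which any Tukey-adjusted pairwise contrast is significant
#' at `alpha`.
#'
#' @param design A [cohort_design()] whose `group_effect` and `sex_effect`
#'   are 0.
#' @param n_reps Number of replicates.
#' @param n_obs Observations per animal per replicate.
#' @param seed Integer seed for the suite.
#' @param alpha Significance level.
#' @return List: `rejection_fraction`, `n_reps`, `alpha`, and the per-rep
#'   logical vector `rejected`.
#' @export
type1_error_suite <- function(design, n_reps = 500, n_obs = 5, seed = 1,
                              alpha = 0.05) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$group_effect != 0 || design$sex_effect != 0) {
    abort("`design` must have zero group and sex effects for a null suite.")
  }
  local_seed(seed)
  rep_seeds <- sample.int(2^31 - 1, n_reps)
  rejected <- vapply(seq_len(n_reps), function(r) {
    tab <- sim_outcome_table(design, n_obs = n_obs, seed = rep_seeds[r])
    fit <- suppressWarnings(suppressMessages(
      fit_lmem(tab, "outcome", transform = "raw", alpha = alpha)
    ))
    any(fit$contrasts$p_tukey < alpha)
  }, TRUE)
  list(rejection_fraction = mean(rejected), n_reps = n_reps, alpha = alpha,
       rejected = rejected)
}

#' Render a deterministic analysis report
#'
#' Writes, for each fitted outcome, the cell means and SDs on the analysis
#' scale, the Tukey contrast table, the transform used and configuration
#' provenance - as TSV + JSON (machine-readable) and a plain-text summary.
#' Regenerating from identical inputs produces byte-identical files.
#'
#' @param results List of `lmem_result` objects.
#' @param data The outcome table the models were fitted on.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `cell_means`, `contrasts`, and the file
#'   paths written.
#' @export
render_report <- function(results, data, out_dir) {
  if (!length(results)) abort("at least one fitted result is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- as_tibble(data)

  cm <- list(); ct <- list()
  for (res in results) {
    fixed <- res$fixed
    y <- data[[res$outcome]]
    ty <- switch(res$transform, raw = y, log10 = log10(y), sqrt = sqrt(y))
    cm[[res$outcome]] <- data |>
      mutate(.ty = ty) |>
      group_by(across(all_of(fixed))) |>
      summarise(mean = mean(.data$.ty, na.rm = TRUE),
                sd = sd(.data$.ty, na.rm = TRUE),
                n = sum(!is.na(.data$.ty)), .groups = "drop") |>
      mutate(outcome = res$outcome, transform = res$transform, .before = 1)
    ct[[res$outcome]] <- res$contrasts |>
      mutate(outcome = res$outcome, transform = res$transform, .before = 1)
  }
  cell_means <- list_rbind(cm)
  contrasts <- list_rbind(ct)

  f_means <- file.path(out_dir, "cell_means.tsv")
  f_contr <- file.path(out_dir, "contrasts.tsv")
  f_json <- file.path(out_dir, "report.json")
  f_txt <- file.path(out_dir, "report.txt")
  readr::write_tsv(cell_means, f_means)
  readr::write_tsv(contrasts, f_contr)
  jsonlite::write_json(
    list(
      provenance = list(
        package = "pneumotrace",
        df_method = unique(vapply(results, `[[`, "", "df_method")),
        alpha = unique(vapply(results, `[[`, 0, "alpha"))
      ),
      cell_means = cell_means, contrasts = contrasts
    ),
    f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  lines <- c("Mixed-model report", "==================", "")
  for (res in results) {
    lines <- c(lines,
               paste0("Outcome: ", res$outcome, "  [", res$transform,
                      " scale, df: ", res$df_method, "]"))
    if (!nrow(res$contrasts)) {
      lines <- c(lines, "  no contrasts", "")
    } else {
      lines <- c(lines, utils::capture.output(
        as.data.frame(res$contrasts[, c("contrast", "estimate", "p_tukey")])
      ), "")
    }
  }
  writeLines(lines, f_txt)
  invisible(list(cell_means = cell_means, contrasts = contrasts,
                 files = c(f_means, f_contr, f_json, f_txt)))
}
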