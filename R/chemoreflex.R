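#' Segment an adult session into analysis epochs
#'
#' Produces the seven analysis epochs of the five-period gas protocol:
#' the last `room_air_window` seconds of each room-air period
#' (`room_air_1..3`), and for each challenge the initial reflex window
#' (`cap_reflex` / `hyp_reflex`, starting when the chamber gas reaches
#' `target_frac` of its step toward the new target) plus the steady state
#' (`cap_ss` / `hyp_ss`, the last `ss_window` seconds of the challenge).
#' Switch times come from `gas_<label>` markers when present, otherwise from
#' the first halfway crossing of the chamber gas toward its new target.
#'
#' @param rec A [trace_recording()] with gas channels and/or switch markers.
#' @param protocol The [adult_protocol()] that was run.
#' @param reflex_window Reflex epoch length, s (default 120).
#' @param ss_window Steady-state window, s (default 300).
#' @param room_air_window Room-air analysis window, s (default 300).
#' @param target_frac Fraction of the gas step defining "at target"
#'   (default 0.9).
#' @return Tibble of class `epoch_tbl`: `label`, `start_s`, `end_s`, `o2`,
#'   `co2`, `usable`. Epochs are half-open `[start, end)`, time-ordered and
#'   non-overlapping.
#' @export
assign_epochs <- function(rec, protocol, reflex_window = 120, ss_window = 300,
                          room_air_window = 300, target_frac = 0.9) {
  stopifnot(inherits(rec, "trace_recording"), inherits(protocol, "adult_protocol"))
  ep <- protocol$epochs
  n_p <- nrow(ep)
  dur <- rec_duration(rec)

  mk <- rec$markers
  have_markers <- nrow(mk) >= n_p &&
    all(paste0("gas_", ep$label) %in% mk$label)
  if (have_markers) {
    starts <- vapply(paste0("gas_", ep$label), function(l) {
      mk$time_s[match(l, mk$label)]
    }, 0)
    if (any(diff(starts) <= 0)) {
      bad <- ep$label[which(diff(starts) <= 0) + 1]
      abort(paste0("markers out of order or overlapping at `gas_", bad[1], "`."))
    }
  } else {
    starts <- detect_gas_switches(rec, ep)
  }
  ends <- c(starts[-1], dur)

  o2 <- rec_channel(rec, "o2_pct", required = FALSE)
  co2 <- rec_channel(rec, "co2_pct", required = FALSE)
  t <- rec$signals$time_s

  rows <- list()
  ra_count <- 0
  for (i in seq_len(n_p)) {
    is_ra <- ep$co2[i] == 0 & ep$o2[i] > 0.15
    if (is_ra) {
      ra_count <- ra_count + 1
      s <- max(starts[i], ends[i] - room_air_window)
      rows[[length(rows) + 1]] <- tibble(
        label = paste0("room_air_", ra_count), start_s = s, end_s = ends[i],
        o2 = ep$o2[i], co2 = ep$co2[i], usable = TRUE)
    } else {
      stem <- if (ep$co2[i] >= 0.02) "cap" else "hyp"
      # time the chamber gas reaches target_frac of the step
      chan <- if (stem == "cap") co2 else o2
      target <- if (stem == "cap") ep$co2[i] * 100 else ep$o2[i] * 100
      t90 <- NA_real_
      if (!is.null(chan)) {
        in_p <- t >= starts[i] & t < ends[i]
        prev <- chan[which(in_p)[1]]
        thr <- prev + target_frac * (target - prev)
        crossed <- if (target > prev) chan[in_p] >= thr else chan[in_p] <= thr
        if (any(crossed)) t90 <- t[in_p][which(crossed)[1]]
      } else {
        t90 <- starts[i]
      }
      usable <- !is.na(t90)
      if (!usable) t90 <- starts[i]
      rows[[length(rows) + 1]] <- tibble(
        label = paste0(stem, "_reflex"), start_s = t90,
        end_s = min(t90 + reflex_window, ends[i]),
        o2 = ep$o2[i], co2 = ep$co2[i], usable = usable)
      rows[[length(rows) + 1]] <- tibble(
        label = paste0(stem, "_ss"), start_s = max(starts[i], ends[i] - ss_window),
        end_s = ends[i], o2 = ep$o2[i], co2 = ep$co2[i], usable = usable)
    }
  }
  out <- list_rbind(rows)
  if (any(out$end_s <= out$start_s)) abort("degenerate epoch produced; check windows.")
  out
}

# first halfway crossing of the relevant gas channel toward each new target
detect_gas_switches <- function(rec, ep) {
  t <- rec$signals$time_s
  o2 <- rec_channel(rec, "o2_pct", required = FALSE)
  co2 <- rec_channel(rec, "co2_pct", required = FALSE)
  if (is.null(o2) && is.null(co2)) {
    abort("neither switch markers nor gas channels are present.")
  }
  n_p <- nrow(ep)
  starts <- numeric(n_p)
  starts[1] <- 0
  cursor <- 1
  for (i in 2:n_p) {
    d_o2 <- abs(ep$o2[i] - ep$o2[i - 1])
    d_co2 <- abs(ep$co2[i] - ep$co2[i - 1])
    use_co2 <- !is.null(co2) && d_co2 >= d_o2
    chan <- if (use_co2) co2 else o2
    target <- if (use_co2) ep$co2[i] * 100 else ep$o2[i] * 100
    prev <- chan[cursor]
    thr <- prev + 0.5 * (target - prev)
    later <- seq(cursor, length(t))
    crossed <- if (target > prev) chan[later] >= thr else chan[later] <= thr
    if (!any(crossed)) {
      abort(paste0("no gas transition found for period `", ep$label[i], "`."))
    }
    idx <- later[which(crossed)[1]]
    starts[i] <- t[idx]
    cursor <- idx
  }
  starts
}

#' Oxygen consumption by flow-through mass balance
#'
#' `VO2 = flow * (FiO2 - FeO2) / weight` with `FeO2` the mean chamber O2
#' fraction over the epoch and `FiO2` the inflow fraction; valid at gas
#' steady state. A negative value (inflow below chamber O2) is returned
#' with a warning rather than clipped, since it signals analyser or
#' calibration drift. An optional one-point respiratory-exchange-ratio
#' correction divides by `1 - FeO2 * (1 - rer)`.
#'
#' @param rec A [trace_recording()] with an `o2_pct` channel.
#' @param epoch One-row epoch tibble (`start_s`, `end_s`).
#' @param flow_ml_min Chamber flow, mL/min (> 0).
#' @param weight_g Animal weight, g (> 0).
#' @param fio2 Inflow O2 fraction (default room air 0.2095).
#' @param rer Optional respiratory exchange ratio for the correction;
#'   `NULL` (default) disables it.
#' @return VO2 in mL O2/min/g.
#' @export
compute_vo2 <- function(rec, epoch, flow_ml_min, weight_g, fio2 = 0.2095,
                        rer = NULL) {
  if (flow_ml_min <= 0) abort("`flow_ml_min` must be positive.")
  if (weight_g <= 0) abort("`weight_g` must be positive.")
  o2 <- rec_channel(rec, "o2_pct")
  t <- rec$signals$time_s
  in_ep <- t >= epoch$start_s & t < epoch$end_s
  if (!any(in_ep)) abort("epoch contains no samples.")
  feo2 <- mean(o2[in_ep]) / 100
  delta <- fio2 - feo2
  if (!is.null(rer)) delta <- delta / (1 - feo2 * (1 - rer))
  vo2 <- flow_ml_min * delta / weight_g
  if (vo2 < 0) {
    warn("negative VO2: chamber O2 exceeds inflow; check analyser calibration.")
  }
  vo2
}

#' Per-animal, per-epoch condition summary
#'
#' Aggregates calm breaths within one epoch into the study's outcome set:
#' ventilatory frequency `Vf = 60 / mean(TT)`, mean calibrated tidal volume
#' `VT`, minute ventilation `VE = Vf * VT` (identically, so `VE = Vf * VT`
#' holds on every row), their per-gram variants, timing means, VO2 and
#' `VE/VO2`, and the epoch's apnea/sigh rates. Epochs with fewer than
#' `min_breaths` calm breaths are omitted (a `NULL` return) with a logged
#' reason, mirroring per-condition quality exclusion.
#'
#' @param breaths Calm-flagged, VT-calibrated breath tibble for the session.
#' @param calls Event calls for the session (may span epochs).
#' @param epoch One-row epoch tibble.
#' @param meta [animal_meta()] for the animal.
#' @param vo2_ml_min_g Optional VO2 for the epoch (mL O2/min/g).
#' @param min_breaths Minimum calm breaths required (default 20).
#' @return One-row tibble or `NULL` when the epoch is excluded.
#' @export
summarize_condition <- function(breaths, calls, epoch, meta,
                                vo2_ml_min_g = NA_real_, min_breaths = 20) {
  in_ep <- breaths$onset_s >= epoch$start_s & breaths$onset_s < epoch$end_s
  b <- breaths[in_ep, ]
  calm <- if ("calm" %in% names(b)) b[b$calm, ] else b
  if (nrow(calm) < min_breaths) {
    inform(paste0("epoch `", epoch$label, "` excluded: ", nrow(calm),
                  " calm breaths < ", min_breaths, "."))
    return(NULL)
  }
  vf <- 60 / mean(calm$tt_s)
  vt <- mean(calm$vt_ml)
  ve <- vf * vt
  w <- meta$weight_g
  ep_calls <- calls[calls$time_s >= epoch$start_s & calls$time_s < epoch$end_s, ]
  rates <- event_rates(ep_calls, b, epoch_label = epoch$label)
  tibble(
    animal_id = meta$id, group = meta$group, sex = meta$sex,
    epoch_label = epoch$label,
    n_breaths = nrow(b), n_calm = nrow(calm),
    vf = vf, vt_ml = vt, vt_ml_g = vt / w,
    ve_ml_min = ve, ve_ml_min_g = ve / w,
    ti_s = mean(calm$ti_s), te_s = mean(calm$te_s), tt_s = mean(calm$tt_s),
    vo2_ml_min_g = vo2_ml_min_g,
    ve_over_vo2 = if (!is.na(vo2_ml_min_g) && vo2_ml_min_g > 0) {
      ve / (vo2_ml_min_g * w)
    } else NA_real_,
    apnea_per100 = rates$apnea_per100, sigh_per100 = rates$sigh_per100
  )
}

#' Percent change of steady-state outcomes from room air
#'
#' `100 * (steady_state - room_air) / room_air` per animal and variable.
#' Hypercapnia is referenced to the first room-air period and hypoxia to the
#' second (the room-air period immediately preceding each challenge).
#' Animals missing a reference epoch contribute no row.
#'
#' @param summaries Condition-summary tibble ([summarize_condition()] rows,
#'   several animals/epochs).
#' @param variables Outcome columns to contrast.
#' @return Tibble: `animal_id`, `variable`, `challenge`, `value` (percent).
#' @export
percent_change <- function(summaries,
                           variables = c("vf", "vt_ml", "ve_ml_min",
                                         "ve_ml_min_g", "vo2_ml_min_g",
                                         "ve_over_vo2")) {
  variables <- intersect(variables, names(summaries))
  pairs <- tibble(
    challenge = c("hypercapnia", "hypoxia"),
    ss = c("cap_ss", "hyp_ss"),
    ref = c("room_air_1", "room_air_2")
  )
  long <- summaries |>
    select("animal_id", "epoch_label", all_of(variables)) |>
    pivot_longer(all_of(variables), names_to = "variable")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ss <- long |> filter(.data$epoch_label == pairs$ss[i])
    ref <- long |> filter(.data$epoch_label == pairs$ref[i])
    j <- inner_join(ss, ref, by = c("animal_id", "variable"),
                    suffix = c("_ss", "_ref")) |>
      filter(!is.na(.data$value_ref), .data$value_ref != 0,
             !is.na(.data$value_ss)) |>
      transmute(.data$animal_id, .data$variable,
                challenge = pairs$challenge[i],
                value = 100 * (.data$value_ss - .data$value_ref) /
                  .data$value_ref)
    out[[i]] <- j
  }
  miss <- setdiff(unique(long$animal_id), unique(list_rbind(out)$animal_id))
  if (length(miss)) {
    inform(paste0("no percent-change rows for: ",
                  paste(miss, collapse = ", "), " (missing reference epoch)."))
  }
  list_rbind(out)
}
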