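#' Assemble a multichannel trace recording
#'
#' A `trace_recording` bundles uniformly sampled physiological channels with
#' the event markers and animal metadata needed downstream. The first column
#' of `signals` must be `time_s`; every other column is a channel (breath
#' pressure/flow in arbitrary signal units, `o2_pct` and `co2_pct` in percent,
#' `chamber_temp_c` in degrees Celsius, `cardiac` in signal units).
#'
#' @param signals Tibble/data frame with a `time_s` column followed by one or
#'   more channel columns, sampled on a uniform grid.
#' @param sample_rate Sampling rate in Hz; must match the `time_s` grid.
#' @param markers Optional tibble with columns `time_s`, `label` describing
#'   protocol events (gas switches, trial starts).
#' @param animal Optional [animal_meta()] list.
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(signals, sample_rate, markers = NULL, animal = NULL) {
  signals <- as_tibble(signals)
  if (!"time_s" %in% names(signals) || names(signals)[1] != "time_s") {
    abort("`signals` must have `time_s` as its first column.")
  }
  if (ncol(signals) < 2) abort("`signals` must contain at least one channel.")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be a positive number (Hz).")
  }
  dur <- if (nrow(signals)) max(signals$time_s) else 0
  if (is.null(markers)) {
    markers <- tibble(time_s = numeric(), label = character())
  } else {
    markers <- as_tibble(markers)
    if (!all(c("time_s", "label") %in% names(markers))) {
      abort("`markers` needs columns `time_s` and `label`.")
    }
    if (any(markers$time_s < 0 | markers$time_s > dur + 1 / sample_rate)) {
      abort("marker times must lie within the recording span.")
    }
  }
  structure(
    list(signals = signals, sample_rate = sample_rate,
         markers = markers, animal = animal),
    class = "trace_recording"
  )
}

#' Animal metadata
#'
#' @param id Animal identifier.
#' @param group Experimental group, `"GF"` (germ-free) or `"SPF"`
#'   (specific-pathogen-free control).
#' @param sex `"F"` or `"M"`.
#' @param weight_g Body weight in grams (> 0).
#' @param temp_pre_c,temp_post_c Rectal temperature (deg C) taken before and
#'   after the session; used for body-temperature interpolation during
#'   tidal-volume calibration.
#' @param age_days Age in days.
#' @return A named list of class `animal_meta`.
#' @export
animal_meta <- function(id, group = c("SPF", "GF"), sex = c("F", "M"),
                        weight_g = NA_real_, temp_pre_c = NA_real_,
                        temp_post_c = NA_real_, age_days = NA_real_) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  if (!is.na(weight_g) && weight_g <= 0) abort("`weight_g` must be positive.")
  structure(
    list(id = as.character(id), group = group, sex = sex, weight_g = weight_g,
         temp_pre_c = temp_pre_c, temp_post_c = temp_post_c,
         age_days = age_days),
    class = "animal_meta"
  )
}

#' @export
print.trace_recording <- function(x, ...) {
  chans <- setdiff(names(x$signals), "time_s")
  cat("<trace_recording> ", nrow(x$signals), " samples @ ", x$sample_rate,
      " Hz (", round(rec_duration(x), 1), " s)\n", sep = "")
  cat("  channels: ", paste(chans, collapse = ", "), "\n", sep = "")
  if (nrow(x$markers)) cat("  markers:  ", nrow(x$markers), "\n", sep = "")
  if (!is.null(x$animal)) {
    cat("  animal:   ", x$animal$id, " (", x$animal$group, ", ",
        x$animal$sex, ")\n", sep = "")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `trace_recording`.
#' @return Length of the recording in seconds.
#' @export
rec_duration <- function(rec) {
  nrow(rec$signals) / rec$sample_rate
}

rec_channel <- function(rec, name, required = TRUE) {
  if (!name %in% names(rec$signals)) {
    if (required) abort(paste0("channel `", name, "` not found in recording."))
    return(NULL)
  }
  rec$signals[[name]]
}

#' Write / read a trace recording as delimited text
#'
#' The on-disk form is a tab-separated samples file (header of channel names,
#' first column `time_s`), a sidecar `key: value` metadata file, and - when
#' ground truth accompanies a synthetic recording - a TSV event table.
#'
#' @param rec A `trace_recording`.
#' @param path Path of the samples file; the sidecar is written next to it
#'   with extension `.meta`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `trace_recording`.
#' @export
write_trace <- function(rec, path) {
  readr::write_tsv(rec$signals, path)
  meta_path <- paste0(path, ".meta")
  kv <- c(sample_rate = rec$sample_rate)
  if (!is.null(rec$animal)) {
    an <- rec$animal
    kv <- c(kv, id = an$id, group = an$group, sex = an$sex,
            weight_g = an$weight_g, temp_pre_c = an$temp_pre_c,
            temp_post_c = an$temp_post_c, age_days = an$age_days)
  }
  lines <- paste0(names(kv), ": ", unname(kv))
  if (nrow(rec$markers)) {
    lines <- c(lines, paste0("marker: ", rec$markers$time_s, " ",
                             rec$markers$label))
  }
  writeLines(lines, meta_path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  signals <- readr::read_tsv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta")
  animal <- NULL
  markers <- NULL
  sample_rate <- NA_real_
  if (file.exists(meta_path)) {
    lines <- readLines(meta_path)
    kv <- strsplit(lines, ": ", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
    sample_rate <- as.numeric(vals[keys == "sample_rate"][1])
    if ("id" %in% keys) {
      g <- function(k) vals[keys == k][1]
      animal <- animal_meta(
        id = g("id"), group = g("group"), sex = g("sex"),
        weight_g = as.numeric(g("weight_g")),
        temp_pre_c = as.numeric(g("temp_pre_c")),
        temp_post_c = as.numeric(g("temp_post_c")),
        age_days = as.numeric(g("age_days"))
      )
    }
    mk <- vals[keys == "marker"]
    if (length(mk)) {
      parts <- strsplit(mk, " ", fixed = TRUE)
      markers <- tibble(
        time_s = as.numeric(vapply(parts, `[`, "", 1)),
        label = vapply(parts, function(x) paste(x[-1], collapse = " "), "")
      )
    }
  }
  if (is.na(sample_rate)) {
    sample_rate <- 1 / median(diff(signals$time_s))
  }
  trace_recording(signals, sample_rate, markers = markers, animal = animal)
}
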