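#' Plot a stretch of raw trace with detected breath onsets
#'
#' @param rec A [trace_recording()].
#' @param breaths Optional breath tibble; onsets are marked when given.
#' @param from,to Window to display, s.
#' @param channel Channel to draw.
#' @return A ggplot object.
#' @export
plot_trace <- function(rec, breaths = NULL, from = 0, to = 10,
                       channel = "breath") {
  sig <- rec$signals |>
    filter(.data$time_s >= from, .data$time_s < to)
  p <- ggplot2::ggplot(sig, ggplot2::aes(.data$time_s, .data[[channel]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = channel) +
    ggplot2::theme_minimal()
  if (!is.null(breaths)) {
    on <- breaths |> filter(.data$onset_s >= from, .data$onset_s < to)
    p <- p + ggplot2::geom_vline(
      data = on, ggplot2::aes(xintercept = .data$onset_s),
      colour = "steelblue", alpha = 0.5, linetype = 2
    )
  }
  p
}

#' Breath-table overview plot
#'
#' Cycle duration and amplitude over the session, calm breaths
#' distinguished when flagged.
#'
#' @param object A `breath_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breath_tbl <- function(object, ...) {
  d <- object |>
    mutate(calm = if ("calm" %in% names(object)) .data$calm else TRUE) |>
    select("onset_s", "tt_s", "amp", "calm") |>
    pivot_longer(c("tt_s", "amp"), names_to = "feature")
  ggplot2::ggplot(d, ggplot2::aes(.data$onset_s, .data$value,
                                  colour = .data$calm)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "calm") +
    ggplot2::theme_minimal()
}

#' Recovery-latency plot of a scored autoresuscitation session
#'
#' Heart-rate (63%) versus ventilatory-frequency (50%) recovery latency per
#' trial with the line of identity: points below the line recovered heart
#' rate faster than breathing (decoupling < 0).
#'
#' @param object An `autoresus_session` from [score_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.autoresus_session <- function(object, ...) {
  d <- object$trials |> filter(.data$survived)
  ggplot2::ggplot(d, ggplot2::aes(.data$lat_hr63_s, .data$lat_vf50_s)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$trial)), size = 2) +
    ggplot2::labs(x = "latency to HR recovery (s, 63% of baseline)",
                  y = "latency to VF recovery (s, 50% of baseline)",
                  colour = "trial") +
    ggplot2::theme_minimal()
}

#' Contrast plot for a fitted mixed model
#'
#' Tukey-adjusted pairwise contrasts with approximate 95% intervals.
#'
#' @param object An `lmem_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmem_result <- function(object, ...) {
  d <- object$contrasts |>
    mutate(lo = .data$estimate - 1.96 * .data$se,
           hi = .data$estimate + 1.96 * .data$se)
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                          colour = .data$significant)) +
    ggplot2::labs(x = paste0("contrast (", object$transform, " scale)"),
                  y = NULL, title = object$outcome) +
    ggplot2::theme_minimal()
}

#' Event-rate plot across conditions
#'
#' Square-root-scale apnea and sigh rates per epoch and group.
#'
#' @param summaries Condition-summary tibble with `epoch_label`, `group`,
#'   `apnea_per100`, `sigh_per100`.
#' @return A ggplot object.
#' @export
plot_event_rates <- function(summaries) {
  d <- summaries |>
    select("animal_id", "group", "epoch_label",
           "apnea_per100", "sigh_per100") |>
    pivot_longer(c("apnea_per100", "sigh_per100"), names_to = "event") |>
    mutate(sqrt_rate = sqrt(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch_label, .data$sqrt_rate,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~event, ncol = 1) +
    ggplot2::labs(x = NULL, y = "sqrt(events per 100 breaths)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
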