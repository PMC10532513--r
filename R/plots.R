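#' Plot the distribution of every scored index
#'
#' Histograms of the session-level index scores, faceted by index on free
#' scales — the usual first look at a scored cohort.
#'
#' @param object An `antivea_scores` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.antivea_scores <- function(object, ...) {
  tidy(object) |>
    filter(.data$index %in% index_names()) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = NULL, y = "sessions",
                  title = "Distribution of session-level indexes")
}

#' Plot split-half reliability coefficients
#'
#' @param object An `antivea_reliability` object.
#' @param ... Unused.
#' @return A ggplot: Spearman-Brown corrected coefficient per index.
#' @export
autoplot.antivea_reliability <- function(object, ...) {
  as_tibble(object) |>
    mutate(index = factor(.data$index, levels = rev(.data$index))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$r_sb, y = .data$index)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.75, linetype = 2) +
    ggplot2::xlim(min(0, min(object$r_sb, na.rm = TRUE)), 1) +
    ggplot2::labs(x = expression(r[SB]), y = NULL,
                  title = "Split-half reliability (Spearman-Brown)")
}

#' Plot the vigilance decrement across blocks
#'
#' Per-block cohort means of the vigilance outcomes: executive-vigilance
#' hits and false alarms (percent), and arousal-vigilance mean RT and
#' lapses. The characteristic decrement appears as falling hit/false-alarm
#' rates and rising RT/lapses over time-on-task.
#'
#' @param trials Clean trial tibble (e.g. `score_dataset(...)$trials`).
#' @return A ggplot of block means with one panel per outcome.
#' @export
plot_vigilance_decrement <- function(trials) {
  ev <- trials |>
    filter(.data$kind == "EV", .data$expected_response == "spacebar") |>
    group_by(.data$subject_id, .data$session_number, .data$block) |>
    summarise(value = 100 * mean(.data$response_class == "spacebar"),
              .groups = "drop") |>
    mutate(outcome = "EV hits (%)")
  fa <- trials |>
    filter(.data$kind == "ANTI", !is.na(.data$fa_difficult),
           .data$fa_difficult) |>
    group_by(.data$subject_id, .data$session_number, .data$block) |>
    summarise(value = 100 * mean(.data$response_class == "spacebar"),
              .groups = "drop") |>
    mutate(outcome = "False alarms (%)")
  av <- trials |>
    filter(.data$kind == "AV", .data$expected_response == "any_key") |>
    group_by(.data$subject_id, .data$session_number, .data$block) |>
    summarise(mean_rt = mean(.data$rt_ms, na.rm = TRUE),
              lapses = 100 * mean(.data$response_class == "none" |
                                    (!is.na(.data$rt_ms) & .data$rt_ms > LAPSE_MS)),
              .groups = "drop") |>
    tidyr::pivot_longer(c("mean_rt", "lapses"), names_to = "outcome",
                        values_to = "value") |>
    mutate(outcome = ifelse(.data$outcome == "mean_rt",
                            "AV mean RT (ms)", "AV lapses (%)"))
  bind_rows(ev, fa, av) |>
    group_by(.data$outcome, .data$block) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$block, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "block", y = NULL,
                  title = "Vigilance outcomes across time-on-task")
}
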