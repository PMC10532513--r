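#' Tidy a scored dataset into long format
#'
#' @param x An `antivea_scores` object from [score_dataset()].
#' @param ... Unused.
#' @return A long tibble: one row per (session, index) with the score.
#' @export
tidy.antivea_scores <- function(x, ...) {
  if (nrow(x$participants) == 0) {
    return(tibble(subject_id = character(), session_number = integer(),
                  index = character(), value = numeric()))
  }
  x$participants |>
    select("subject_id", "session_number",
           all_of(c(index_names(),
                    "dprime", "criterion", "ev_mean_rt_ms", "ev_sd_rt_ms",
                    "tp_mean_rating"))) |>
    tidyr::pivot_longer(-c("subject_id", "session_number"),
                        names_to = "index", values_to = "value")
}

#' One-row summary of a scored dataset
#'
#' @param x An `antivea_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: session tallies and headline cohort means.
#' @export
glance.antivea_scores <- function(x, ...) {
  s <- x$report$index_summary
  pick_mean <- function(ix) {
    v <- s$mean[s$index == ix]
    if (length(v) == 1) v else NA_real_
  }
  tibble(
    n_sessions = x$report$n_sessions,
    n_scored = x$report$n_scored,
    n_excluded = x$report$n_excluded,
    mean_overall_rt_ms = pick_mean("overall_rt_ms"),
    mean_hits_pct = pick_mean("hits_pct"),
    mean_fa_pct = pick_mean("fa_pct"),
    mean_av_mean_rt_ms = pick_mean("av_mean_rt_ms"),
    mean_lapses_pct = pick_mean("lapses_pct")
  )
}

#' Tidy a reliability table
#'
#' @param x An `antivea_reliability` object from [split_half()].
#' @param ... Unused.
#' @return The underlying tibble (already tidy).
#' @export
tidy.antivea_reliability <- function(x, ...) {
  as_tibble(x)
}
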