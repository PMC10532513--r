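#' Preprocessing options for raw trial tables
#'
#' Mirrors the standard analysis options of the task's analysis app:
#' practice trials are always dropped; sessions can be excluded for
#' incomplete blocks, for leaving full-screen mode, or for poor flanker
#' performance; flanker RTs outside 200-1500 ms (or incorrect responses)
#' are excluded from RT indexes only.
#'
#' @param administered_blocks Blocks the sessions were supposed to run
#'   (`NULL` = take each session's own config echo).
#' @param minimal_blocks_completed Sessions with fewer complete blocks are
#'   excluded (`NULL` = same as administered).
#' @param screen_policy `"full_only"` excludes sessions that were minimized;
#'   `"any"` retains them.
#' @param validity_policy `"valid_only"` excludes sessions whose flanker
#'   error rate exceeds `max_anti_error_pct`; `"any"` retains them.
#' @param max_anti_error_pct Poor-performance threshold (default 25).
#' @param rt_lower_ms,rt_upper_ms RT filter bounds for flanker RT indexes.
#' @param extra_sessions_policy `"keep_all"` or `"keep_first"` (earliest
#'   session per participant code).
#' @return A list of class `antivea_options`.
#' @export
preprocess_options <- function(administered_blocks = NULL,
                               minimal_blocks_completed = NULL,
                               screen_policy = c("full_only", "any"),
                               validity_policy = c("valid_only", "any"),
                               max_anti_error_pct = 25,
                               rt_lower_ms = 200,
                               rt_upper_ms = 1500,
                               extra_sessions_policy = c("keep_all", "keep_first")) {
  stopifnot(rt_lower_ms > 0, rt_lower_ms < rt_upper_ms,
            max_anti_error_pct > 0, max_anti_error_pct <= 100)
  if (!is.null(administered_blocks) && !is.null(minimal_blocks_completed) &&
      minimal_blocks_completed > administered_blocks) {
    abort("minimal_blocks_completed cannot exceed administered_blocks")
  }
  structure(
    list(administered_blocks = administered_blocks,
         minimal_blocks_completed = minimal_blocks_completed,
         screen_policy = match.arg(screen_policy),
         validity_policy = match.arg(validity_policy),
         max_anti_error_pct = max_anti_error_pct,
         rt_lower_ms = rt_lower_ms,
         rt_upper_ms = rt_upper_ms,
         extra_sessions_policy = match.arg(extra_sessions_policy)),
    class = "antivea_options"
  )
}

# ANTI rows that carry the flanker task for scoring purposes.
anti_rows <- function(trials) {
  trials$kind == "ANTI" & trials$expected_response == "direction_key"
}

#' Preprocess a raw trial table
#'
#' Drops practice rows, computes per-session quality control (complete
#' blocks, minimization, flanker error rate), applies the exclusion
#' policies, and marks which flanker rows enter RT-index computation
#' (`rt_included`: correct and inside the RT filter). Error-rate indexes
#' and the false-alarm denominator keep all flanker rows.
#'
#' @param trials Raw trial tibble (the CSV dialect).
#' @param options A [preprocess_options()].
#' @return A list with `trials` (clean rows of retained sessions, plus an
#'   `rt_included` column) and `qc` (one row per session: QC fields,
#'   `excluded`, comma-separated `exclusion_reasons`).
#' @export
preprocess_trials <- function(trials, options = preprocess_options()) {
  stopifnot(inherits(options, "antivea_options"))
  if (nrow(trials) == 0) abort("empty trial table")
  exp_trials <- filter(trials, .data$phase == "experimental")
  if (nrow(exp_trials) == 0) abort("no experimental trials after practice removal")

  qc <- exp_trials |>
    group_by(.data$subject_id, .data$session_number) |>
    summarise(
      participant_code = .data$participant_code[1],
      session_date = .data$session_date[1],
      task_type = .data$task_type[1],
      administered_blocks = .data$n_blocks[1],
      complete_blocks = {
        expected <- sum(block_kind_counts(.data$task_type[1]))
        sum(table(.data$block[.data$kind != "TP"]) == expected)
      },
      was_minimized = any(!.data$screen_full),
      anti_error_pct = if (any(anti_rows(pick(everything())))) {
        100 * mean(!.data$correct[anti_rows(pick(everything()))])
      } else NA_real_,
      .groups = "drop"
    )

  minimal <- options$minimal_blocks_completed %||%
    options$administered_blocks
  qc <- qc |>
    mutate(minimal_required = minimal %||% .data$administered_blocks)

  reasons <- purrr::pmap(
    list(qc$complete_blocks, qc$minimal_required, qc$was_minimized,
         qc$anti_error_pct),
    function(cb, mb, min_, err) {
      r <- character()
      if (cb < mb) r <- c(r, "incomplete_blocks")
      if (min_ && options$screen_policy == "full_only") r <- c(r, "minimized")
      if (!is.na(err) && err > options$max_anti_error_pct &&
          options$validity_policy == "valid_only") {
        r <- c(r, "poor_performance")
      }
      r
    })

  if (options$extra_sessions_policy == "keep_first") {
    first <- qc |>
      arrange(.data$session_date, .data$subject_id, .data$session_number) |>
      distinct(.data$participant_code, .keep_all = TRUE)
    is_first <- paste(qc$subject_id, qc$session_number) %in%
      paste(first$subject_id, first$session_number)
    reasons <- purrr::map2(reasons, is_first,
                           function(r, keep) if (keep) r else c(r, "extra_session"))
  }

  qc$exclusion_reasons <- purrr::map_chr(reasons, paste, collapse = ",")
  qc$excluded <- nchar(qc$exclusion_reasons) > 0
  qc$minimal_required <- NULL

  kept <- qc |> filter(!.data$excluded)
  clean <- exp_trials |>
    semi_join(kept, by = c("subject_id", "session_number")) |>
    mutate(rt_included = anti_rows(pick(everything())) &
             !is.na(.data$correct) & .data$correct &
             !is.na(.data$rt_ms) &
             .data$rt_ms >= options$rt_lower_ms &
             .data$rt_ms <= options$rt_upper_ms)
  list(trials = clean, qc = qc)
}

# OLS slope of per-block values on the block number.
block_slope <- function(block, value) {
  ok <- !is.na(value)
  if (sum(ok) < 2) return(NA_real_)
  b <- block[ok]; v <- value[ok]
  sum((b - mean(b)) * (v - mean(v))) / sum((b - mean(b))^2)
}

rt_diff <- function(rt, flag_hi, flag_lo) {
  hi <- rt[flag_hi]; lo <- rt[flag_lo]
  if (length(hi) == 0 || length(lo) == 0) return(NA_real_)
  mean(hi) - mean(lo)
}

#' Signal-detection scores from hit and false-alarm percentages
#'
#' Sensitivity `d' = z(H) - z(FA)` and response criterion
#' `c = -(z(H) + z(FA)) / 2`, with the log-linear correction
#' `(x + 0.5) / (n + 1)` applied to both proportions so the scores stay
#' finite at 0% and 100%.
#'
#' @param hits_pct,fa_pct Hit and false-alarm percentages (0-100).
#' @param n_ev Number of executive-vigilance (signal) trials.
#' @param n_fa_difficult Number of fa-difficult flanker (noise) trials.
#' @return A tibble with columns `dprime` and `criterion`.
#' @export
#' @examples
#' sdt_scores(90, 10, 96, 120)
sdt_scores <- function(hits_pct, fa_pct, n_ev, n_fa_difficult) {
  bad <- is.na(hits_pct) | is.na(fa_pct) |
    is.na(n_ev) | is.na(n_fa_difficult) | n_ev <= 0 | n_fa_difficult <= 0
  h <- (hits_pct / 100 * n_ev + 0.5) / (n_ev + 1)
  f <- (fa_pct / 100 * n_fa_difficult + 0.5) / (n_fa_difficult + 1)
  out <- tibble(dprime = qnorm(h) - qnorm(f),
                criterion = -(qnorm(h) + qnorm(f)) / 2)
  out$dprime[bad] <- NA_real_
  out$criterion[bad] <- NA_real_
  out
}

#' Compute the core indexes of one clean session
#'
#' The 18 core indexes: flanker overall RT and errors; alerting (no-tone
#' minus tone, no-cue trials only), orienting (invalid minus valid), and
#' congruency (incongruent minus congruent) effects on RT and errors;
#' executive-vigilance hits and false alarms (fa-difficult denominator) and
#' their per-block OLS slopes; arousal-vigilance mean RT, SD of RT, and
#' lapses (RT > 600 ms or omission) with their slopes. Extensions:
#' signal-detection d' and criterion, executive-vigilance mean/SD RT over
#' hits, and the mean thought-probe rating.
#'
#' RT indexes use correct responses inside the RT filter only
#' (`rt_included`); error indexes use all flanker trials; the false-alarm
#' denominator keeps all fa-difficult flanker trials regardless of RT
#' validity.
#'
#' @param session Clean trial tibble of a single session (see
#'   [preprocess_trials()]); if `rt_included` is absent it is derived with
#'   the default filter.
#' @return A one-row tibble (the index set).
#' @export
compute_core_indexes <- function(session) {
  if (!"rt_included" %in% names(session)) {
    session$rt_included <- anti_rows(session) & !is.na(session$correct) &
      session$correct & !is.na(session$rt_ms) &
      session$rt_ms >= RT_LOWER_MS & session$rt_ms <= RT_UPPER_MS
  }
  anti <- session[anti_rows(session), ]
  rtok <- anti[anti$rt_included, ]
  ev <- session[session$kind == "EV" &
                  session$expected_response == "spacebar", ]
  av <- session[session$kind == "AV" &
                  session$expected_response == "any_key", ]

  has_anti <- nrow(anti) > 0
  nc <- rtok[rtok$cue == "none", ]
  nc_err <- anti[anti$cue == "none", ]

  err_pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(!x)
  err_diff <- function(df, hi, lo) {
    a <- err_pct(df$correct[hi]); b <- err_pct(df$correct[lo])
    a - b
  }

  # executive vigilance
  n_ev <- nrow(ev)
  hit <- ev$response_class == "spacebar"
  hits_pct <- if (n_ev > 0) 100 * mean(hit) else NA_real_
  ev_by_block <- if (n_ev > 0) {
    ev |> group_by(.data$block) |>
      summarise(v = 100 * mean(.data$response_class == "spacebar"),
                .groups = "drop")
  } else tibble(block = integer(), v = numeric())

  # false alarms on the fa-difficult flanker subset
  fad <- anti[!is.na(anti$fa_difficult) & anti$fa_difficult, ]
  n_fad <- nrow(fad)
  if (has_anti && n_fad == 0) {
    warn("no fa-difficult flanker trials: false-alarm indexes set to NA")
  }
  fa_pct <- if (n_fad > 0) 100 * mean(fad$response_class == "spacebar") else NA_real_
  fa_by_block <- if (n_fad > 0) {
    fad |> group_by(.data$block) |>
      summarise(v = 100 * mean(.data$response_class == "spacebar"),
                .groups = "drop")
  } else tibble(block = integer(), v = numeric())

  # arousal vigilance
  responded <- av[!is.na(av$rt_ms), ]
  lapse <- av$response_class == "none" |
    (!is.na(av$rt_ms) & av$rt_ms > LAPSE_MS)
  av_block <- if (nrow(av) > 0) {
    av |> group_by(.data$block) |>
      summarise(
        mean_rt = if (any(!is.na(.data$rt_ms))) mean(.data$rt_ms, na.rm = TRUE) else NA_real_,
        sd_rt = if (sum(!is.na(.data$rt_ms)) >= 2) sd(.data$rt_ms, na.rm = TRUE) else NA_real_,
        lapses = 100 * mean(.data$response_class == "none" |
                              (!is.na(.data$rt_ms) & .data$rt_ms > LAPSE_MS)),
        .groups = "drop")
  } else tibble(block = integer(), mean_rt = numeric(), sd_rt = numeric(),
                lapses = numeric())

  ev_hit_rt <- ev$rt_ms[hit]
  tp <- session[session$kind == "TP", ]

  sdt <- sdt_scores(hits_pct, fa_pct, n_ev, n_fad)

  tibble(
    overall_rt_ms = if (nrow(rtok) > 0) mean(rtok$rt_ms) else NA_real_,
    overall_errors_pct = err_pct(anti$correct),
    alerting_rt_ms = rt_diff(nc$rt_ms, !nc$tone, nc$tone),
    alerting_errors_pct = if (nrow(nc_err) > 0) {
      err_diff(nc_err, !nc_err$tone, nc_err$tone)
    } else NA_real_,
    orienting_rt_ms = rt_diff(rtok$rt_ms, rtok$cue == "invalid",
                              rtok$cue == "valid"),
    orienting_errors_pct = if (has_anti) {
      err_diff(anti, anti$cue == "invalid", anti$cue == "valid")
    } else NA_real_,
    congruency_rt_ms = rt_diff(rtok$rt_ms, rtok$congruency == "incongruent",
                               rtok$congruency == "congruent"),
    congruency_errors_pct = if (has_anti) {
      err_diff(anti, anti$congruency == "incongruent",
               anti$congruency == "congruent")
    } else NA_real_,
    hits_pct = hits_pct,
    hits_slope_pct_per_block = block_slope(ev_by_block$block, ev_by_block$v),
    fa_pct = fa_pct,
    fa_slope_pct_per_block = block_slope(fa_by_block$block, fa_by_block$v),
    av_mean_rt_ms = if (nrow(responded) > 0) mean(responded$rt_ms) else NA_real_,
    av_mean_rt_slope = block_slope(av_block$block, av_block$mean_rt),
    av_sd_rt_ms = if (nrow(responded) >= 2) sd(responded$rt_ms) else NA_real_,
    av_sd_rt_slope = block_slope(av_block$block, av_block$sd_rt),
    lapses_pct = if (nrow(av) > 0) 100 * mean(lapse) else NA_real_,
    lapses_slope = block_slope(av_block$block, av_block$lapses),
    dprime = sdt$dprime,
    criterion = sdt$criterion,
    ev_mean_rt_ms = if (length(ev_hit_rt) > 0) mean(ev_hit_rt) else NA_real_,
    ev_sd_rt_ms = if (length(ev_hit_rt) >= 2) sd(ev_hit_rt) else NA_real_,
    tp_mean_rating = if (nrow(tp) > 0) {
      mean(tp$probe_rating, na.rm = TRUE)
    } else NA_real_
  )
}

index_names <- function() {
  c("overall_rt_ms", "overall_errors_pct", "alerting_rt_ms",
    "alerting_errors_pct", "orienting_rt_ms", "orienting_errors_pct",
    "congruency_rt_ms", "congruency_errors_pct", "hits_pct",
    "hits_slope_pct_per_block", "fa_pct", "fa_slope_pct_per_block",
    "av_mean_rt_ms", "av_mean_rt_slope", "av_sd_rt_ms", "av_sd_rt_slope",
    "lapses_pct", "lapses_slope")
}

#' Score a raw dataset into participant- and trial-level tables
#'
#' The full pipeline: preprocess (practice removal, QC, exclusions, RT
#' filter), score every retained session with [compute_core_indexes()],
#' and assemble the two standard outputs — a participant-level table (one
#' row per session: identity, config echo, QC, all indexes) and a
#' trial-level table (clean rows plus inclusion flags) — together with a
#' technical report of exclusion tallies and per-index summary statistics.
#'
#' @param trials Raw trial tibble (the CSV dialect), any number of sessions.
#' @param options A [preprocess_options()].
#' @return An object of class `antivea_scores`: a list with `participants`,
#'   `trials`, `qc`, `report`, and `options`. Supports [tidy()],
#'   [glance()], and [ggplot2::autoplot()].
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_preset("inlab_reference"),
#'                        task_config(participant_code = "1234", n_blocks = 2),
#'                        n = 4, seed = 7)
#' scores <- score_dataset(sim$trials,
#'                         preprocess_options(validity_policy = "any"))
#' scores$participants[, c("subject_id", "overall_rt_ms", "hits_pct")]
#' }
score_dataset <- function(trials, options = preprocess_options()) {
  pre <- preprocess_trials(trials, options)
  sessions <- pre$trials |>
    group_by(.data$subject_id, .data$session_number)
  keys <- group_keys(sessions)
  if (nrow(keys) > 0) {
    idx <- sessions |>
      group_split() |>
      purrr::map(compute_core_indexes) |>
      bind_rows()
    id_cols <- pre$trials |>
      distinct(.data$subject_id, .data$session_number, .data$session_date,
               .data$participant_code, .data$experiment, .data$group,
               .data$task_type, .data$noise, .data$difficulty,
               .data$target_duration_ms, .data$n_blocks,
               .data$probes_per_block)
    participants <- keys |>
      left_join(id_cols, by = c("subject_id", "session_number")) |>
      left_join(pre$qc |>
                  select("subject_id", "session_number", "complete_blocks",
                         "was_minimized", "anti_error_pct"),
                by = c("subject_id", "session_number")) |>
      bind_cols(idx)
  } else {
    participants <- tibble()
  }

  summ <- if (nrow(participants) > 0) {
    participants |>
      select(all_of(index_names())) |>
      tidyr::pivot_longer(everything(), names_to = "index") |>
      group_by(.data$index) |>
      summarise(mean = mean(.data$value, na.rm = TRUE),
                sd = sd(.data$value, na.rm = TRUE), .groups = "drop") |>
      arrange(match(.data$index, index_names()))
  } else {
    tibble(index = character(), mean = numeric(), sd = numeric())
  }

  report <- structure(
    list(n_sessions = nrow(pre$qc),
         n_scored = nrow(participants),
         n_excluded = sum(pre$qc$excluded),
         exclusions = pre$qc |>
           filter(.data$excluded) |>
           count(.data$exclusion_reasons, name = "n_sessions"),
         index_summary = summ,
         options = unclass(options)),
    class = "antivea_report"
  )

  structure(list(participants = participants, trials = pre$trials,
                 qc = pre$qc, report = report, options = options),
            class = "antivea_scores")
}

#' @export
print.antivea_report <- function(x, ...) {
  cat("ANTI-Vea scoring report\n")
  cat(sprintf("  sessions: %d in, %d scored, %d excluded\n",
              x$n_sessions, x$n_scored, x$n_excluded))
  if (nrow(x$exclusions) > 0) {
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("    excluded (%s): %d\n",
                  x$exclusions$exclusion_reasons[i],
                  x$exclusions$n_sessions[i]))
    }
  }
  if (x$n_scored == 0) {
    cat("  zero valid sessions; no indexes computed\n")
    return(invisible(x))
  }
  cat("  core indexes, M (SD) over scored sessions:\n")
  for (i in seq_len(nrow(x$index_summary))) {
    cat(sprintf("    %-26s %8.2f (%.2f)\n", x$index_summary$index[i],
                x$index_summary$mean[i], x$index_summary$sd[i]))
  }
  invisible(x)
}

#' @export
print.antivea_scores <- function(x, ...) {
  print(x$report)
  invisible(x)
}
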