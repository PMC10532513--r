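#' Split-half reliability with Spearman-Brown correction
#'
#' Estimates the internal consistency of any core index over a scored
#' dataset. Within each participant, trials are partitioned into two halves
#' stratified by trial kind, block, and (for flanker trials) the
#' tone x cue x congruency cell and the fa-difficult flag, so both halves
#' support every index. Each half is scored with [compute_core_indexes()];
#' `r_half` is the across-participant Pearson correlation of the two
#' half-scores and `r_sb = 2 r / (1 + r)` is the Spearman-Brown corrected
#' (full-length) reliability.
#'
#' Difference-score indexes (alerting, orienting, congruency) are expected
#' to be markedly less reliable than overall RT: subtracting two noisy
#' means removes most of the stable between-person variance while keeping
#' the trial noise.
#'
#' @param trials Clean trial tibble (e.g. the `trials` element of
#'   [score_dataset()] or [preprocess_trials()]).
#' @param indexes Character vector of index columns to assess (defaults to
#'   the 18 core indexes).
#' @param scheme `"odd_even"` (deterministic alternation within strata) or
#'   `"random"` (averaged over `n_splits` seeded random partitions).
#' @param n_splits Number of random splits (ignored for odd-even).
#' @param seed Integer seed for the random scheme.
#' @return A tibble of class `antivea_reliability`: one row per index with
#'   `r_half`, `r_sb`, `n_participants`, `n_splits`, and (for random
#'   splits) the SD of `r_sb` over splits. `r_sb` always satisfies the
#'   prophecy identity with the reported `r_half`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_preset("inlab_reference"),
#'                        task_config(participant_code = "1234", n_blocks = 2),
#'                        n = 10, seed = 3)
#' scores <- score_dataset(sim$trials,
#'                         preprocess_options(validity_policy = "any"))
#' split_half(scores$trials, indexes = c("overall_rt_ms", "alerting_rt_ms"))
#' }
split_half <- function(trials,
                       indexes = index_names(),
                       scheme = c("odd_even", "random"),
                       n_splits = 10,
                       seed = 1) {
  scheme <- match.arg(scheme)
  n_subj <- n_distinct(paste(trials$subject_id, trials$session_number))
  if (n_subj < 3) abort("split-half reliability needs >= 3 participants")
  if (scheme == "odd_even") n_splits <- 1L

  splits <- purrr::map(seq_len(n_splits), function(s) {
    halves <- split_trials(trials, scheme,
                           seed = as.integer(seed) + s - 1L)
    score_halves(halves, indexes)
  })

  out <- purrr::map(indexes, function(ix) {
    rs <- purrr::map_dbl(splits, function(sp) {
      x <- sp[[paste0(ix, "_h1")]]
      y <- sp[[paste0(ix, "_h2")]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) return(NA_real_)
      cor(x[ok], y[ok])
    })
    n_used <- purrr::map_int(splits, function(sp) {
      sum(stats::complete.cases(sp[[paste0(ix, "_h1")]],
                                sp[[paste0(ix, "_h2")]]))
    })
    dropped <- n_subj - min(n_used)
    if (dropped > 0) {
      inform(sprintf("index '%s': %d participant(s) dropped (index not computable on a half)",
                     ix, dropped))
    }
    r_half <- mean(rs, na.rm = TRUE)
    r_sb_splits <- 2 * rs / (1 + rs)
    tibble(index = ix, scheme = scheme,
           n_participants = as.integer(min(n_used)),
           n_splits = n_splits,
           r_half = r_half,
           r_sb = 2 * r_half / (1 + r_half),
           r_sb_sd = if (n_splits > 1) sd(r_sb_splits, na.rm = TRUE) else NA_real_)
  }) |> bind_rows()

  structure(out, class = c("antivea_reliability", class(out)))
}

# Assign each trial to half 1 or 2, stratified so both halves support all
# indexes: strata are kind x block x (ANTI cell, fa-difficult flag).
split_trials <- function(trials, scheme, seed) {
  strata <- paste(trials$subject_id, trials$session_number, trials$kind,
                  trials$block, trials$tone, trials$cue, trials$congruency,
                  trials$fa_difficult)
  ord <- order(strata, trials$trial_index)
  trials <- trials[ord, ]
  strata <- strata[ord]
  pos <- stats::ave(seq_along(strata), strata, FUN = seq_along)
  if (scheme == "odd_even") {
    half <- 2L - (pos %% 2L)  # 1st, 3rd, ... of each stratum -> half 1
  } else {
    half <- integer(length(strata))
    withr::with_seed(seed, {
      for (ii in split(seq_along(strata), strata)) {
        half[ii] <- sample(rep(1:2, length.out = length(ii)))
      }
    })
  }
  trials$split_half <- half
  trials
}

score_halves <- function(trials, indexes) {
  h1 <- trials |>
    filter(.data$split_half == 1L) |>
    group_by(.data$subject_id, .data$session_number)
  h2 <- trials |>
    filter(.data$split_half == 2L) |>
    group_by(.data$subject_id, .data$session_number)
  score_group <- function(g, suffix) {
    keys <- group_keys(g)
    idx <- g |> group_split() |>
      purrr::map(function(s) {
        suppressWarnings(compute_core_indexes(s))
      }) |>
      bind_rows()
    idx <- idx[intersect(indexes, names(idx))]
    names(idx) <- paste0(names(idx), suffix)
    bind_cols(keys, idx)
  }
  inner_join(score_group(h1, "_h1"), score_group(h2, "_h2"),
             by = c("subject_id", "session_number"))
}

#' @export
print.antivea_reliability <- function(x, ...) {
  cat("Split-half reliability (Spearman-Brown corrected)\n")
  NextMethod()
}
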