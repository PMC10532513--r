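# Shared fixtures: built in code, kept small.

toy_path <- function() {
  system.file("extdata", "toy_session.csv", package = "antivea")
}

# Frozen hand-computed values for the toy session (see the fixture README).
toy_expected <- list(
  overall_rt_ms = 588.75,
  overall_errors_pct = 100 * 2 / 12,
  alerting_rt_ms = 45,
  alerting_errors_pct = 100 * (1 / 3 - 0),
  orienting_rt_ms = 40,
  orienting_errors_pct = -25,
  congruency_rt_ms = 82.5,
  congruency_errors_pct = 100 * (1 / 5 - 1 / 7),
  hits_pct = 75,
  hits_slope_pct_per_block = 50,
  fa_pct = 25,
  fa_slope_pct_per_block = -50,
  av_mean_rt_ms = 570,
  av_mean_rt_slope = 70,
  av_sd_rt_ms = sqrt(49400 / 3),
  av_sd_rt_slope = 190 / sqrt(2) - 230 / sqrt(2),
  lapses_pct = 50,
  lapses_slope = 0,
  dprime = qnorm(0.7) - qnorm(0.3),
  criterion = -(qnorm(0.7) + qnorm(0.3)) / 2,
  ev_mean_rt_ms = 750,
  ev_sd_rt_ms = 50,
  tp_mean_rating = NA_real_
)

# A cohort with zero between-person variation (every participant is the
# identified mean participant).
mean_cohort <- function(version = "inlab") {
  targets <- reference_index_targets(version)
  targets$sd <- NULL
  suppressMessages(calibrate_preset(targets, preset = "mean_participant"))
}

quick_config <- function(n_blocks = 2, ...) {
  task_config(participant_code = "1234", n_blocks = n_blocks, ...)
}

# Small simulated raw dataset reused across scoring/reliability tests.
small_sim <- local({
  cache <- NULL
  function(n = 8, n_blocks = 2, seed = 42) {
    key <- paste(n, n_blocks, seed)
    if (!is.null(cache) && cache$key == key) return(cache$sim)
    sim <- suppressMessages(
      simulate_cohort(cohort_preset("inlab_reference"),
                      quick_config(n_blocks = n_blocks), n = n, seed = seed))
    cache <<- list(key = key, sim = sim)
    sim
  }
})
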