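toy_options <- function(...) {
  preprocess_options(minimal_blocks_completed = 0, ...)
}

test_that("the hand-computed toy session is reproduced exactly", {
  tt <- read_trials(toy_path())
  sc <- score_dataset(tt, toy_options())
  expect_equal(nrow(sc$participants), 1)
  for (ix in names(toy_expected)) {
    expect_equal(sc$participants[[ix]], toy_expected[[ix]],
                 tolerance = 1e-10, label = ix)
  }
})

test_that("indexes are invariant to trial order within blocks", {
  tt <- read_trials(toy_path())
  perm <- withr::with_seed(8, tt[sample.int(nrow(tt)), ])
  perm$trial_index <- tt$trial_index  # keep key uniqueness semantics
  a <- score_dataset(tt, toy_options())$participants
  b <- score_dataset(perm, toy_options())$participants
  expect_equal(as.data.frame(a[, -(1:2)]), as.data.frame(b[, -(1:2)]))
})

test_that("RT filter removes fast/slow trials from RT indexes only", {
  tt <- read_trials(toy_path())
  sc <- score_dataset(tt, toy_options())
  # trials 14 (100 ms) and 15 (1600 ms) are correct, so they count for the
  # error denominator but are filtered from every RT mean
  expect_equal(sc$participants$overall_errors_pct, 100 * 2 / 12)
  expect_equal(sc$participants$overall_rt_ms, 588.75)
  # tightening the filter to exclude 660/640/650 changes the RT indexes
  sc2 <- score_dataset(tt, preprocess_options(minimal_blocks_completed = 0,
                                              rt_upper_ms = 630))
  expect_lt(sc2$participants$overall_rt_ms, 588.75)
  expect_equal(sc2$participants$overall_errors_pct, 100 * 2 / 12)
})

test_that("practice trials never reach the scorer", {
  sim <- suppressMessages(
    simulate_cohort(mean_cohort(), quick_config(1, do_practice = TRUE),
                    n = 2, seed = 5))
  pre <- preprocess_trials(sim$trials,
                           preprocess_options(minimal_blocks_completed = 0))
  expect_true(all(pre$trials$phase == "experimental"))
})

test_that("each exclusion rule fires with its named reason", {
  sim <- small_sim()
  trials <- sim$trials
  subjects <- unique(trials$subject_id)

  # poor performance: flip most flanker responses of subject 1 to errors
  s1 <- subjects[1]
  i1 <- which(trials$subject_id == s1 & trials$kind == "ANTI")
  flip <- i1[seq_len(ceiling(0.4 * length(i1)))]
  trials$correct[flip] <- FALSE
  trials$response_class[flip] <-
    ifelse(trials$target_direction[flip] == "left",
           "direction_right", "direction_left")
  trials$rt_ms[flip] <- 500

  # minimization: subject 2 drops out of full screen once
  s2 <- subjects[2]
  trials$screen_full[which(trials$subject_id == s2)[5]] <- FALSE

  # incomplete blocks: subject 3 loses the tail of the last block
  s3 <- subjects[3]
  drop <- which(trials$subject_id == s3 &
                  trials$block == max(trials$block))
  trials <- trials[-drop[(length(drop) - 9):length(drop)], ]

  pre <- preprocess_trials(trials, preprocess_options(
    minimal_blocks_completed = 2))
  qc <- pre$qc
  get_reason <- function(s) qc$exclusion_reasons[qc$subject_id == s]
  expect_match(get_reason(s1), "poor_performance")
  expect_match(get_reason(s2), "minimized")
  expect_match(get_reason(s3), "incomplete_blocks")
  expect_equal(sum(qc$excluded), 3)
  expect_false(any(pre$trials$subject_id %in% c(s1, s2, s3)))

  # retention policies keep the flagged sessions
  pre2 <- preprocess_trials(trials, preprocess_options(
    minimal_blocks_completed = 1, screen_policy = "any",
    validity_policy = "any"))
  expect_equal(sum(pre2$qc$excluded), 0)
})

test_that("a clean session passes QC with no reasons", {
  sim <- small_sim()
  pre <- preprocess_trials(sim$trials, preprocess_options())
  expect_true(all(!pre$qc$excluded))
  expect_true(all(pre$qc$complete_blocks == 2))
  expect_true(all(!pre$qc$was_minimized))
  expect_error(preprocess_trials(sim$trials[0, ], preprocess_options()),
               "empty")
})

test_that("keep_first retains only each participant's earliest session", {
  sim <- small_sim()
  t1 <- sim$trials
  t2 <- t1 |>
    dplyr::mutate(session_number = 2L,
                  session_date = sub("^2023", "2024", session_date))
  both <- dplyr::bind_rows(t1, t2)
  pre <- preprocess_trials(both, preprocess_options(
    extra_sessions_policy = "keep_first"))
  expect_true(all(pre$trials$session_number == 1))
  expect_equal(sum(grepl("extra_session", pre$qc$exclusion_reasons)),
               dplyr::n_distinct(t1$subject_id))
})

test_that("signal-detection scores match the closed-form oracle", {
  # symmetric case
  sym <- sdt_scores(50, 50, 100, 100)
  expect_equal(sym$dprime, 0, tolerance = 1e-6)
  expect_equal(sym$criterion, 0, tolerance = 1e-6)
  # large-n case approaches the uncorrected z arithmetic
  big <- sdt_scores(90, 10, 1e6, 1e6)
  expect_equal(big$dprime, qnorm(0.9) - qnorm(0.1), tolerance = 1e-4)
  expect_equal(big$criterion, 0, tolerance = 1e-4)
  # exact log-linear value at the toy counts
  toy <- sdt_scores(75, 25, 4, 4)
  expect_equal(toy$dprime, qnorm(3.5 / 5) - qnorm(1.5 / 5))
  # criterion strictly increases as hits fall with false alarms fixed
  h <- seq(90, 30, by = -10)
  cs <- sdt_scores(h, rep(10, length(h)), 96, 120)$criterion
  expect_true(all(diff(cs) > 0))
  # extremes stay finite thanks to the correction
  ext <- sdt_scores(c(0, 100), c(0, 100), 96, 120)
  expect_true(all(is.finite(ext$dprime)))
})

test_that("boundary sessions score without degeneracies", {
  tt <- read_trials(toy_path())
  none <- tt
  ev_rows <- none$kind == "EV"
  none$response_class[ev_rows] <- "none"
  none$rt_ms[ev_rows] <- NA_real_
  none$correct[ev_rows] <- FALSE
  sc <- score_dataset(none, toy_options())
  expect_equal(sc$participants$hits_pct, 0)
  expect_true(is.finite(sc$participants$dprime))

  fast <- tt
  av_rows <- fast$kind == "AV"
  fast$rt_ms[av_rows] <- 400
  sc2 <- score_dataset(fast, toy_options())
  expect_equal(sc2$participants$lapses_pct, 0)

  # no fa-difficult trials: FA indexes go missing with a warning
  nofa <- tt
  nofa$fa_difficult[nofa$kind == "ANTI"] <- FALSE
  expect_warning(sc3 <- score_dataset(nofa, toy_options()), "fa-difficult")
  expect_true(is.na(sc3$participants$fa_pct))
})

test_that("dataset-level outputs have the documented shape", {
  sim <- small_sim()
  trials <- sim$trials
  # force two poor-performance sessions
  for (s in unique(trials$subject_id)[1:2]) {
    ii <- which(trials$subject_id == s & trials$kind == "ANTI")
    flip <- ii[seq_len(ceiling(0.3 * length(ii)))]
    trials$correct[flip] <- FALSE
    trials$response_class[flip] <- "direction_left"
    trials$rt_ms[flip] <- 500
  }
  sc <- score_dataset(trials, preprocess_options())
  expect_s3_class(sc, "antivea_scores")
  expect_equal(sc$report$n_sessions, 8)
  expect_equal(sc$report$n_scored, 6)
  expect_equal(sc$report$n_excluded, 2)
  expect_equal(nrow(sc$participants), 6)
  expect_equal(nrow(sc$report$index_summary), 18)
  expect_true(all(c("subject_id", "complete_blocks", "overall_rt_ms",
                    "lapses_slope") %in% names(sc$participants)))
  expect_output(print(sc$report), "excluded \\(poor_performance\\): 2")

  # everything excluded: report says so, nothing crashes
  all_bad <- dplyr::filter(trials,
                           subject_id %in% unique(trials$subject_id)[1:2])
  sc2 <- score_dataset(all_bad, preprocess_options())
  expect_equal(sc2$report$n_scored, 0)
  expect_output(print(sc2$report), "zero valid sessions")

  # tidiers
  td <- tidy(sc)
  expect_true(all(c("index", "value") %in% names(td)))
  expect_equal(nrow(td), 6 * 23)
  gl <- glance(sc)
  expect_equal(gl$n_excluded, 2)
})

test_that("autoplot methods return ggplot objects", {
  sim <- small_sim()
  sc <- score_dataset(sim$trials, preprocess_options())
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  expect_s3_class(plot_vigilance_decrement(sc$trials), "ggplot")
})
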