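test_that("settings dialect applies the standard defaults and validates ranges", {
  cfg <- parse_task_settings(c(pc = "1234"))
  expect_s3_class(cfg, "antivea_config")
  expect_equal(cfg$noise, 2L)
  expect_equal(cfg$difficulty, 2L)
  expect_equal(cfg$target_duration_ms, 200L)
  expect_equal(cfg$n_blocks, 6L)
  expect_equal(cfg$probes_per_block, 0L)
  expect_false(cfg$do_practice)
  expect_equal(cfg$task_type, "ANTI_VEA")

  expect_error(parse_task_settings(list()), "participant code required")
  expect_error(parse_task_settings(c(pc = "abc")), "participant code required")
  expect_error(parse_task_settings(c(pc = "1234", B = "9")), "'B'")
  expect_error(parse_task_settings(c(pc = "1234", no = "7")), "'no'")
  expect_error(parse_task_settings(c(pc = "1234", probes = "5")), "probes")
  expect_error(parse_task_settings(c(pc = "1", type = "FOO")), "task version")
  expect_error(parse_task_settings(c(pc = "1", bogus = "x")), "unknown setting")

  # platform spellings of version names normalize
  expect_equal(parse_task_settings(c(pc = "1", type = "ANTI-Only"))$task_type,
               "ANTI_ONLY")
  expect_equal(parse_task_settings(c(pc = "1", type = "SART-PVT"))$task_type,
               "SART_PVT")
})

test_that("standard schedule has the documented composition, balance, and duration", {
  sched <- build_session(quick_config(n_blocks = 6), seed = 1)
  expect_equal(nrow(sched), 480)
  expect_equal(schedule_duration(sched), 1968000)

  comp <- block_composition(sched) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n_trials")
  expect_equal(comp$ANTI, rep(48L, 6))
  expect_equal(comp$EV, rep(16L, 6))
  expect_equal(comp$AV, rep(16L, 6))

  # ANTI factorial: exactly 4 per tone x cue x congruency cell per block,
  # location and direction balanced
  anti <- dplyr::filter(sched, kind == "ANTI")
  cells <- dplyr::count(anti, block, tone, cue, congruency)
  expect_true(all(cells$n == 4))
  expect_equal(nrow(cells), 6 * 12)
  expect_true(all(dplyr::count(anti, block, target_location)$n == 24))
  expect_true(all(dplyr::count(anti, block, target_direction)$n == 24))

  # EV displacement: 8 up, 8 down per block, magnitude from difficulty 2
  ev <- dplyr::filter(sched, kind == "EV")
  expect_true(all(abs(ev$target_displacement_px) ==
                    difficulty_displacement_px(2)))
  signs <- dplyr::count(ev, block, sign(target_displacement_px))
  expect_true(all(signs$n == 8))

  # AV trials carry the not-applicable sentinel on manipulation fields
  av <- dplyr::filter(sched, kind == "AV")
  expect_true(all(is.na(av$tone) & is.na(av$cue) & is.na(av$congruency)))
  expect_true(all(av$expected_response == "any_key"))

  # onsets advance in exact 4100 ms steps
  expect_equal(sched$onset_ms, 4100 * (seq_len(480) - 1))
})

test_that("four-block and one-block variants match the stated durations", {
  expect_equal(schedule_duration(build_session(quick_config(4), seed = 2)),
               1312000)
  expect_equal(schedule_duration(build_session(quick_config(1), seed = 2)),
               328000)
  expect_equal(schedule_duration(build_session(
    quick_config(0, do_practice = TRUE), seed = 2)), 0)
})

test_that("schedules are a pure function of config and seed", {
  a <- build_session(quick_config(3, probes_per_block = 4), seed = 7)
  b <- build_session(quick_config(3, probes_per_block = 4), seed = 7)
  c <- build_session(quick_config(3, probes_per_block = 4), seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("jitter law and fa-difficult flag follow the > 2 px adjacency rule", {
  sched <- build_session(quick_config(2, noise = 3), seed = 5)
  vis <- sched[sched$kind %in% c("ANTI", "EV"), ]
  jit <- as.matrix(vis[paste0("jitter_px_", 1:5)])
  expect_true(all(jit >= -3 & jit <= 3))
  anti <- vis[vis$kind == "ANTI", ]
  expect_equal(anti$fa_difficult,
               abs(anti$jitter_px_3 - anti$jitter_px_2) > 2 |
                 abs(anti$jitter_px_3 - anti$jitter_px_4) > 2)

  # hand cases: [0, 1, 4, 1, 0] is difficult (|4 - 1| = 3); zeros are not
  trials <- tibble::tibble(kind = c("ANTI", "ANTI"))
  out <- withr::with_seed(1, add_trial_jitter(trials, noise = 2, difficulty = 2))
  out$jitter_px_1 <- c(0L, 0L); out$jitter_px_2 <- c(1L, 0L)
  out$jitter_px_3 <- c(4L, 0L); out$jitter_px_4 <- c(1L, 0L)
  out$jitter_px_5 <- c(0L, 0L)
  flag <- abs(out$jitter_px_3 - out$jitter_px_2) > 2 |
    abs(out$jitter_px_3 - out$jitter_px_4) > 2
  expect_equal(flag, c(TRUE, FALSE))

  # noise = 1 can never exceed the 2 px threshold
  s1 <- build_session(quick_config(1, noise = 1), seed = 3)
  expect_false(any(s1$fa_difficult[s1$kind == "ANTI"]))
  expect_equal(fa_difficult_fraction(1), 0)
  # shared-target enumeration: P(neither side differs by > 2 px) =
  # mean over target jitter x of [P(|x - flanker| <= 2)]^2 = 75/125
  expect_equal(fa_difficult_fraction(2), 1 - 75 / 125)
})

test_that("difficulty maps monotonically to displacement", {
  d <- difficulty_displacement_px(1:5)
  expect_true(all(diff(d) > 0))
  expect_error(difficulty_displacement_px(0))
})

test_that("thought probes keep five task trials between them for many seeds", {
  block <- tibble::tibble(kind = rep("ANTI", 80), phase = "experimental")
  for (s in 1:400) {
    out <- withr::with_seed(s, place_probes(block, 12))
    expect_equal(nrow(out), 92)
    tp_pos <- which(out$kind == "TP")
    gaps <- diff(tp_pos) - 1L  # non-TP rows between consecutive TPs
    expect_true(all(gaps >= 5))
  }
  expect_identical(withr::with_seed(1, place_probes(block, 0)), block)
  expect_error(withr::with_seed(1, place_probes(block[1:10, ], 12)),
               class = "antivea_probe_error")
})

test_that("probe trials are untimed and carry the rating response", {
  with_tp <- build_session(quick_config(2, probes_per_block = 4), seed = 4)
  without <- build_session(quick_config(2), seed = 4)
  expect_equal(nrow(with_tp), nrow(without) + 8)
  expect_equal(schedule_duration(with_tp), schedule_duration(without))
  tp <- with_tp[with_tp$kind == "TP", ]
  expect_true(all(tp$expected_response == "probe_rating"))
  # a TP shares its onset with the next timed trial
  non_tp <- with_tp$kind != "TP"
  expect_equal(with_tp$onset_ms[non_tp], 4100 * (seq_len(sum(non_tp)) - 1))
})

test_that("sub-task versions keep per-kind counts and remap responses", {
  anti_only <- build_session(quick_config(2, task_type = "ANTI_ONLY"), seed = 1)
  expect_equal(sort(unique(anti_only$kind)), "ANTI")
  expect_equal(nrow(anti_only), 2 * 48)

  pvt_only <- build_session(quick_config(2, task_type = "PVT_ONLY"), seed = 1)
  expect_equal(sort(unique(pvt_only$kind)), "AV")
  expect_equal(nrow(pvt_only), 2 * 16)

  # full-stimulus single/dual tasks: same stream, responses remapped
  sart <- build_session(quick_config(2, task_type = "SART"), seed = 1)
  expect_equal(nrow(sart), 160)
  expect_true(all(sart$expected_response[sart$kind == "EV"] == "spacebar"))
  expect_true(all(sart$expected_response[sart$kind %in% c("ANTI", "AV")] == "none"))

  dual <- build_session(quick_config(2, task_type = "SART_PVT"), seed = 1)
  expect_true(all(dual$expected_response[dual$kind == "AV"] == "any_key"))
  expect_true(all(dual$expected_response[dual$kind == "ANTI"] == "none"))

  # distractor version extends each block by 8 scheduled slots
  d <- build_session(quick_config(2, task_type = "ANTI_VEA_D"), seed = 1)
  expect_equal(nrow(d), 2 * 88)
  expect_equal(sum(d$kind == "DISTRACTOR"), 16)

  nogo <- build_session(quick_config(1, task_type = "SART_ONLY_NOGO"), seed = 1)
  expect_true(all(nogo$expected_response[nogo$kind == "ANTI"] == "any_key"))
  expect_true(all(nogo$expected_response[nogo$kind == "EV"] == "none"))
})

test_that("practice phase emits four structural scaled-down blocks", {
  sched <- build_session(quick_config(2, do_practice = TRUE), seed = 9)
  prac <- sched[sched$phase == "practice", ]
  expect_equal(length(unique(prac$block)), 4)
  comp <- dplyr::count(prac, block, kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n")
  expect_equal(comp$ANTI, rep(12L, 4))
  expect_equal(comp$EV, rep(4L, 4))
  expect_equal(comp$AV, rep(4L, 4))
  # practice is untimed for the session duration
  expect_equal(schedule_duration(sched),
               schedule_duration(build_session(quick_config(2), seed = 9)))
})
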