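#' Task configuration for an ANTI-Vea session
#'
#' A validated set of session parameters mirroring the settings the task
#' platform accepts. The standard session is six experimental blocks of 80
#' trials (48 flanker/ANTI, 16 executive-vigilance, 16 arousal-vigilance),
#' each trial occupying a fixed 4100 ms envelope.
#'
#' @param task_type Task version. `"ANTI_VEA"` (the full task) by default;
#'   sub-task versions keep the full stimulus stream but remap which trials
#'   require a response (`"ANTI"`, `"SART"`, `"PVT"`, `"SART_PVT"`), or
#'   present only the relevant trial kinds (`"ANTI_ONLY"`, `"SART_ONLY_GO"`,
#'   `"SART_ONLY_NOGO"`, `"PVT_ONLY"`). `"ANTI_VEA_D"` adds 8 distractor
#'   trial slots per block.
#' @param participant_code Digit string identifying the participant. Required.
#' @param experiment,group Free-text experiment and group labels.
#' @param noise Spatial jitter half-range in pixels (1-6, default 2). Each of
#'   the five arrows gets an independent uniform integer vertical offset in
#'   `[-noise, noise]` px.
#' @param difficulty Perceptual salience of the vigilance target, 1 (hardest)
#'   to 5 (easiest), default 2. Maps to the vertical displacement of the
#'   target on executive-vigilance trials; see [difficulty_displacement_px()].
#' @param target_duration_ms Target display duration in ms (0-1700,
#'   default 200).
#' @param do_practice Emit the four structural practice blocks first?
#' @param n_blocks Number of experimental blocks (0-8, default 6; 0 means
#'   practice only).
#' @param probes_per_block Thought probes inserted per block: 0, 4, 8, or 12.
#' @param language Instruction-language tag; metadata only.
#'
#' @return An object of class `antivea_config` (a named list).
#' @seealso [parse_task_settings()] for the URL-parameter dialect,
#'   [build_session()] to turn a configuration into a trial schedule.
#' @export
#' @examples
#' cfg <- task_config(participant_code = "1234")
#' cfg$n_blocks
task_config <- function(task_type = "ANTI_VEA",
                        participant_code,
                        experiment = "Power_ANTI-Vea",
                        group = "Exp",
                        noise = 2L,
                        difficulty = 2L,
                        target_duration_ms = 200L,
                        do_practice = FALSE,
                        n_blocks = 6L,
                        probes_per_block = 0L,
                        language = "en") {
  task_type <- match.arg(task_type, TASK_TYPES)
  if (missing(participant_code) || length(participant_code) != 1L ||
      is.na(participant_code) || !grepl("^[0-9]+$", as.character(participant_code))) {
    abort("participant code required (pc must be a non-empty digit string)",
          class = "antivea_config_error")
  }
  check_range <- function(x, nm, lo, hi) {
    if (length(x) != 1L || is.na(suppressWarnings(as.numeric(x))) ||
        as.numeric(x) %% 1 != 0 || as.numeric(x) < lo || as.numeric(x) > hi) {
      abort(sprintf("parameter '%s' out of range: must be an integer in [%s, %s]",
                    nm, lo, hi),
            class = "antivea_config_error")
    }
    as.integer(x)
  }
  noise <- check_range(noise, "no", 1, 6)
  difficulty <- check_range(difficulty, "dif", 1, 5)
  target_duration_ms <- check_range(target_duration_ms, "st", 0, 1700)
  n_blocks <- check_range(n_blocks, "B", 0, 8)
  probes_per_block <- check_range(probes_per_block, "probes", 0, 12)
  if (!probes_per_block %in% c(0L, 4L, 8L, 12L)) {
    abort("parameter 'probes' out of range: must be one of 0, 4, 8, 12",
          class = "antivea_config_error")
  }
  structure(
    list(
      task_type = task_type,
      participant_code = as.character(participant_code),
      experiment = as.character(experiment),
      group = as.character(group),
      noise = noise,
      difficulty = difficulty,
      target_duration_ms = target_duration_ms,
      do_practice = isTRUE(do_practice) || identical(do_practice, "true"),
      n_blocks = n_blocks,
      probes_per_block = probes_per_block,
      language = as.character(language)
    ),
    class = "antivea_config"
  )
}

#' @export
print.antivea_config <- function(x, ...) {
  cat("<antivea_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Parse the platform's URL-parameter settings dialect
#'
#' The task platform configures a session through short URL parameters
#' (`lang`, `type`, `pc`, `exp`, `gr`, `no`, `dif`, `st`, `dP`, `B`,
#' `probes`), all given as strings. This parses such a key-value set,
#' applies the standard defaults for absent keys, and validates ranges.
#'
#' @param settings Named list or character vector of raw string settings.
#'   `pc` (participant code) is the only mandatory key.
#' @return A validated [task_config()] object.
#' @export
#' @examples
#' parse_task_settings(c(pc = "1234", B = "4"))
parse_task_settings <- function(settings = list()) {
  settings <- as.list(settings)
  known <- c("lang", "type", "pc", "exp", "gr", "no", "dif", "st", "dP",
             "B", "probes")
  extra <- setdiff(names(settings), known)
  if (length(extra) > 0) {
    abort(paste0("unknown setting key(s): ", paste(extra, collapse = ", ")),
          class = "antivea_config_error")
  }
  if (is.null(settings$pc)) {
    abort("participant code required (pc must be a non-empty digit string)",
          class = "antivea_config_error")
  }
  type <- settings$type %||% "ANTI_VEA"
  type <- toupper(gsub("-", "_", type))
  if (!type %in% TASK_TYPES) {
    abort(sprintf("parameter 'type' out of range: unknown task version '%s'",
                  settings$type),
          class = "antivea_config_error")
  }
  task_config(
    task_type = type,
    participant_code = settings$pc,
    experiment = settings$exp %||% "Power_ANTI-Vea",
    group = settings$gr %||% "Exp",
    noise = settings$no %||% 2L,
    difficulty = settings$dif %||% 2L,
    target_duration_ms = settings$st %||% 200L,
    do_practice = identical(tolower(as.character(settings$dP %||% "false")), "true"),
    n_blocks = settings$B %||% 6L,
    probes_per_block = settings$probes %||% 0L,
    language = settings$lang %||% "en"
  )
}

#' Displacement (px) of the vigilance target by difficulty level
#'
#' The executive-vigilance target is the central arrow displaced vertically
#' out of alignment with the flankers. The platform documents difficulty
#' only as an ordinal 1 (hardest) to 5 (easiest) scale; this package fixes a
#' documented monotone map from difficulty to displacement magnitude.
#'
#' @param difficulty Integer vector in 1..5.
#' @return Integer displacement magnitude in pixels.
#' @export
#' @examples
#' difficulty_displacement_px(1:5)
difficulty_displacement_px <- function(difficulty) {
  stopifnot(all(difficulty %in% 1:5))
  c(6L, 8L, 10L, 12L, 14L)[difficulty]
}

# Per-block trial-kind composition for a task version.
block_kind_counts <- function(task_type, phase = "experimental") {
  full <- c(ANTI = 48L, EV = 16L, AV = 16L)
  counts <- switch(task_type,
    ANTI_VEA = , ANTI = , SART = , PVT = , SART_PVT = full,
    ANTI_VEA_D = c(full, DISTRACTOR = 8L),
    ANTI_ONLY = full["ANTI"],
    PVT_ONLY = full["AV"],
    SART_ONLY_GO = , SART_ONLY_NOGO = full[c("ANTI", "EV")]
  )
  if (phase == "practice") counts <- counts %/% 4L
  counts
}

# Which response each trial kind requires under each task version.
expected_response_for <- function(kind, task_type) {
  resp <- rep("none", length(kind))
  anti_map <- switch(task_type,
    ANTI_VEA = , ANTI_VEA_D = , ANTI = , ANTI_ONLY = "direction_key",
    SART_ONLY_NOGO = "any_key",
    "none"
  )
  ev_map <- switch(task_type,
    ANTI_VEA = , ANTI_VEA_D = , SART = , SART_PVT = , SART_ONLY_GO = "spacebar",
    "none"
  )
  av_map <- switch(task_type,
    ANTI_VEA = , ANTI_VEA_D = , PVT = , SART_PVT = , PVT_ONLY = "any_key",
    "none"
  )
  resp[kind == "ANTI"] <- anti_map
  resp[kind == "EV"] <- ev_map
  resp[kind == "AV"] <- av_map
  resp[kind == "TP"] <- "probe_rating"
  resp
}

# 12-cell factorial of the ANTI manipulations.
anti_cells <- function() {
  tidyr::crossing(
    tone = c(TRUE, FALSE),
    cue = c("valid", "invalid", "none"),
    congruency = c("congruent", "incongruent")
  )
}

# One block's worth of trial rows (conditions only; jitter added later).
# Consumes the RNG stream: EV cell rotation/signs, then position shuffle.
build_block <- function(task_type, phase) {
  counts <- block_kind_counts(task_type, phase)
  cells <- anti_cells()
  pieces <- list()

  if (!is.na(counts["ANTI"])) {
    n_rep <- counts[["ANTI"]] %/% 12L
    anti <- cells
    if (n_rep == 4L) {
      # each cell gets the full location x direction sub-factorial
      anti <- tidyr::crossing(cells,
                              target_location = c("up", "down"),
                              target_direction = c("left", "right"))
    } else {
      anti <- anti[rep(seq_len(12L), n_rep), ]
      anti$target_location <- sample(rep(c("up", "down"), length.out = nrow(anti)))
      anti$target_direction <- sample(rep(c("left", "right"), length.out = nrow(anti)))
    }
    anti$kind <- "ANTI"
    pieces$anti <- anti
  }

  if (!is.na(counts["EV"])) {
    n_ev <- counts[["EV"]]
    base <- cells[seq_len(min(12L, n_ev)), ]
    if (n_ev > 12L) {
      # 16 trials cannot cover 12 cells evenly: 12 cells once, plus 4 by
      # seeded rotation so the surplus cells vary across blocks/sessions
      start <- sample.int(12L, 1L)
      extra <- cells[((start + 0:(n_ev - 12L - 1L) - 1L) %% 12L) + 1L, ]
      base <- bind_rows(base, extra)
    }
    ev <- base
    ev$kind <- "EV"
    ev$target_location <- sample(rep(c("up", "down"), length.out = n_ev))
    ev$target_direction <- sample(rep(c("left", "right"), length.out = n_ev))
    # sign of the vertical displacement: half upward, half downward
    ev$displacement_sign <- sample(rep(c(1L, -1L), length.out = n_ev))
    pieces$ev <- ev
  }

  if (!is.na(counts["AV"])) {
    pieces$av <- tibble(kind = rep("AV", counts[["AV"]]))
  }
  if (!is.na(counts["DISTRACTOR"])) {
    pieces$d <- tibble(kind = rep("DISTRACTOR", counts[["DISTRACTOR"]]))
  }

  block <- bind_rows(pieces)
  if (!"displacement_sign" %in% names(block)) {
    block$displacement_sign <- rep(NA_integer_, nrow(block))
  }
  block <- block[sample.int(nrow(block)), ]
  block$phase <- phase
  block
}

#' Add per-arrow pixel jitter and vigilance flags to scheduled trials
#'
#' Each of the five arrows receives an independent uniform integer vertical
#' jitter in `[-noise, +noise]` px. Executive-vigilance (EV) trials
#' additionally receive their signed target displacement from the difficulty
#' map. Flanker (ANTI) trials are flagged `fa_difficult` when the jitter
#' distance between the target (arrow 3) and at least one adjacent flanker
#' (arrows 2 or 4) exceeds 2 px; only these trials enter the false-alarm
#' denominator, which avoids a floor effect in the false-alarm rate.
#'
#' Consumes the current RNG stream; wrap in [withr::with_seed()] for
#' reproducibility (as [build_session()] does internally).
#'
#' @param trials A tibble of trial rows with `kind`; only `ANTI` and `EV`
#'   rows are jittered.
#' @param noise Jitter half-range in px (1-6).
#' @param difficulty Difficulty level 1-5 (EV displacement magnitude).
#' @return `trials` with `jitter_px_1` .. `jitter_px_5`,
#'   `target_displacement_px`, and `fa_difficult` columns filled in.
#' @export
add_trial_jitter <- function(trials, noise, difficulty) {
  n <- nrow(trials)
  jit <- matrix(NA_integer_, n, 5)
  vis <- trials$kind %in% c("ANTI", "EV")
  if (any(!trials$kind %in% c("ANTI", "EV", "AV", "TP", "DISTRACTOR"))) {
    abort("unknown trial kind in schedule")
  }
  jit[vis, ] <- sample(seq(-noise, noise), 5 * sum(vis), replace = TRUE)
  colnames(jit) <- paste0("jitter_px_", 1:5)
  trials <- bind_cols(trials[setdiff(names(trials), colnames(jit))],
                      as_tibble(jit))
  disp <- rep(NA_integer_, n)
  disp[trials$kind == "ANTI"] <- 0L
  is_ev <- trials$kind == "EV"
  sign <- if ("displacement_sign" %in% names(trials)) {
    trials$displacement_sign
  } else {
    rep(1L, n)
  }
  disp[is_ev] <- sign[is_ev] * difficulty_displacement_px(difficulty)
  trials$target_displacement_px <- disp
  fa <- rep(NA, n)
  is_anti <- trials$kind == "ANTI"
  fa[is_anti] <- (abs(trials$jitter_px_3 - trials$jitter_px_2) > 2 |
                    abs(trials$jitter_px_3 - trials$jitter_px_4) > 2)[is_anti]
  trials$fa_difficult <- fa
  trials
}

#' Insert thought-probe trials into a block
#'
#' Thought probes (TPs) ask participants to rate, on a -1 (fully on-task) to
#' +1 (fully off-task) scale, where their attention was just before the
#' question. Probes are placed pseudo-randomly with at least five task
#' trials between consecutive probes, and are self-paced (they do not
#' advance the timed schedule).
#'
#' Consumes the current RNG stream; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param block_trials Tibble of one block's task trials (no TP rows).
#' @param n_probes Number of probes to insert (0, 4, 8, or 12).
#' @return The block with TP rows inserted.
#' @export
place_probes <- function(block_trials, n_probes) {
  if (n_probes == 0) return(block_trials)
  stopifnot(n_probes %in% c(4L, 8L, 12L))
  n <- nrow(block_trials)
  min_gap <- 5L
  if (n < min_gap * (n_probes - 1L) + 1L || n < 6L * n_probes) {
    abort(sprintf(
      "cannot place %d probes with >= %d task trials between them in a %d-trial block",
      n_probes, min_gap, n),
      class = "antivea_probe_error")
  }
  # positions = number of task trials preceding each probe; sampling sorted
  # offsets then re-adding the mandatory gaps keeps all gaps >= 5
  slack <- n - min_gap * (n_probes - 1L)
  u <- sort(sample.int(slack + 1L, n_probes, replace = TRUE) - 1L)
  pos <- u + min_gap * (seq_len(n_probes) - 1L)
  tp <- block_trials[rep(NA_integer_, n_probes), ]
  tp$kind <- "TP"
  tp$phase <- block_trials$phase[1]
  out <- block_trials
  # insert from the last position so earlier indices stay valid
  for (i in rev(seq_len(n_probes))) {
    at <- pos[i]
    out <- bind_rows(out[seq_len(at), ], tp[i, ],
                     if (at < nrow(out)) out[(at + 1):nrow(out), ])
  }
  out
}

#' Build a deterministic, seeded session schedule
#'
#' Expands a [task_config()] into the full ordered trial list of a session.
#' Every experimental block of the full task holds 48 ANTI trials covering
#' the 2 (tone) x 3 (cue) x 2 (congruency) factorial exactly four times
#' (once per target location x direction), 16 executive-vigilance trials
#' (8 upward / 8 downward displacement, cells balanced as evenly as 16
#' allows), and 16 arousal-vigilance trials, uniformly shuffled. Identical
#' `(config, seed)` pairs reproduce identical schedules.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the single pseudo-random stream of the session.
#' @return A tibble of class `antivea_schedule`, one row per trial, with the
#'   configuration and seed stored as attributes.
#' @export
#' @examples
#' sched <- build_session(task_config(participant_code = "1234"), seed = 1)
#' nrow(sched)                 # 480 trials
#' schedule_duration(sched)    # 1,968,000 ms = 32 min 48 s
build_session <- function(config, seed) {
  stopifnot(inherits(config, "antivea_config"))
  seed <- as.integer(seed)
  schedule <- withr::with_seed(seed, {
    blocks <- list()
    if (config$do_practice) {
      for (b in 1:4) {
        blk <- build_block(config$task_type, "practice")
        blk <- add_trial_jitter(blk, config$noise, config$difficulty)
        blk$block <- b
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
    if (config$n_blocks > 0) {
      for (b in seq_len(config$n_blocks)) {
        blk <- build_block(config$task_type, "experimental")
        blk <- add_trial_jitter(blk, config$noise, config$difficulty)
        if (config$probes_per_block > 0) {
          blk <- place_probes(blk, config$probes_per_block)
        }
        blk$block <- b
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
    bind_rows(blocks)
  })
  if (nrow(schedule) == 0) {
    schedule <- tibble(kind = character(), phase = character(),
                       block = integer())
  }
  schedule$expected_response <- expected_response_for(schedule$kind,
                                                      config$task_type)
  # TP trials are self-paced: they do not advance the timed schedule
  timed <- schedule$kind != "TP"
  schedule$onset_ms <- TRIAL_MS * (cumsum(timed) - as.integer(timed))
  schedule$trial_index <- seq_len(nrow(schedule)) - 1L
  cols <- c("trial_index", "block", "phase", "kind", "tone", "cue",
            "congruency", "target_location", "target_direction",
            "target_displacement_px", paste0("jitter_px_", 1:5),
            "fa_difficult", "onset_ms", "expected_response")
  for (cc in setdiff(cols, names(schedule))) schedule[[cc]] <- NA
  schedule <- as_tibble(schedule[cols])
  structure(schedule,
            config = config, seed = seed,
            class = c("antivea_schedule", class(schedule)))
}

#' Expected fraction of fa-difficult flanker trials
#'
#' Exact enumeration over the (flanker, target, flanker) jitter triple of
#' the probability that the target's jitter differs by more than 2 px from
#' at least one adjacent flanker, under the independent uniform integer
#' jitter law. The two comparisons share the target's jitter, so they are
#' *not* independent; at the default `noise = 2` the enumerated value is
#' exactly 0.4.
#'
#' @param noise Jitter half-range in px (1-6).
#' @return Expected proportion of flanker trials flagged fa-difficult.
#' @export
#' @examples
#' fa_difficult_fraction(2)
fa_difficult_fraction <- function(noise) {
  stopifnot(all(noise %in% 1:6))
  vapply(noise, function(no) {
    v <- seq(-no, no)
    g <- expand.grid(j2 = v, j3 = v, j4 = v)
    mean(abs(g$j3 - g$j2) > 2 | abs(g$j3 - g$j4) > 2)
  }, numeric(1))
}

#' Per-block trial-kind composition of a schedule
#'
#' @param schedule An `antivea_schedule` or any trial tibble with `phase`,
#'   `block`, and `kind` columns.
#' @return A tibble with one row per (phase, block, kind) and its count.
#' @export
block_composition <- function(schedule) {
  as_tibble(schedule) |>
    count(.data$phase, .data$block, .data$kind, name = "n_trials")
}

#' Total timed duration of the experimental phase, in milliseconds
#'
#' Each non-probe trial occupies a fixed 4100 ms envelope; thought probes
#' are self-paced and practice trials are excluded. The standard six-block
#' session lasts 1,968,000 ms (32 min 48 s); the four-block variant
#' 1,312,000 ms (21 min 52 s).
#'
#' @param schedule An `antivea_schedule` (or compatible trial tibble).
#' @return Duration in ms (numeric scalar).
#' @export
schedule_duration <- function(schedule) {
  sum(schedule$phase == "experimental" & schedule$kind != "TP") * TRIAL_MS
}
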