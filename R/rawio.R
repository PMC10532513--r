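# The trial-level CSV dialect. The task platform documents its own export
# columns in an external codebook; this package defines and documents its
# own dialect, and read_trials() takes a user column map so real platform
# exports can be adapted.

codebook_def <- function() {
  tibble::tribble(
    ~column, ~type, ~allowed, ~description,
    "subject_id", "c", NA, "System-generated unique identifier of the task execution",
    "session_number", "i", NA, "Session counter for the subject (1-based)",
    "session_date", "c", NA, "Session start, 'yyyy-mm-dd hh:mm:ss'",
    "participant_code", "c", NA, "Digit code entered at the start (pc)",
    "experiment", "c", NA, "Experiment label (exp)",
    "group", "c", NA, "Group label (gr)",
    "task_type", "c", paste(TASK_TYPES, collapse = "|"), "Task version",
    "noise", "i", "1:6", "Arrow jitter half-range in px (no)",
    "difficulty", "i", "1:5", "EV displacement difficulty (dif)",
    "target_duration_ms", "i", "0:1700", "Target display duration (st)",
    "n_blocks", "i", "0:8", "Experimental blocks administered (B)",
    "probes_per_block", "i", "0|4|8|12", "Thought probes per block (probes)",
    "trial_index", "i", NA, "0-based row index within the session",
    "block", "i", NA, "1-based block within its phase",
    "phase", "c", "practice|experimental", "Session phase",
    "kind", "c", "ANTI|EV|AV|TP|DISTRACTOR", "Trial kind",
    "tone", "l", NA, "Warning tone present (NA outside ANTI/EV)",
    "cue", "c", "valid|invalid|none", "Visual cue validity (NA outside ANTI/EV)",
    "congruency", "c", "congruent|incongruent", "Flanker congruency (NA outside ANTI/EV)",
    "target_location", "c", "up|down", "Target above/below fixation",
    "target_direction", "c", "left|right", "Direction of the central arrow",
    "target_displacement_px", "i", NA, "Vertical displacement of the target (0 on ANTI, signed on EV)",
    "jitter_px_1", "i", NA, "Vertical jitter of arrow 1 (px)",
    "jitter_px_2", "i", NA, "Vertical jitter of arrow 2 (px)",
    "jitter_px_3", "i", NA, "Vertical jitter of arrow 3 (the target)",
    "jitter_px_4", "i", NA, "Vertical jitter of arrow 4 (px)",
    "jitter_px_5", "i", NA, "Vertical jitter of arrow 5 (px)",
    "fa_difficult", "l", NA, "ANTI trial with > 2 px target-to-flanker jitter (the FA denominator)",
    "onset_ms", "d", NA, "Scheduled onset from session start (TPs are untimed)",
    "expected_response", "c", "direction_key|spacebar|any_key|probe_rating|none", "Response the task expects",
    "response_class", "c", "direction_left|direction_right|spacebar|any_key|none|probe_value", "Observed response",
    "rt_ms", "d", NA, "Response time in ms (empty iff no response)",
    "correct", "l", NA, "Response correctness (NA where not applicable)",
    "screen_full", "l", NA, "Trial ran in full-screen mode",
    "probe_rating", "d", NA, "Thought-probe rating in [-1, 1] (TP rows only)"
  )
}

#' The trial-level CSV codebook
#'
#' One row per column of the raw-trial CSV dialect this package reads and
#' writes: name, type (`c`haracter / `i`nteger / `d`ouble / `l`ogical),
#' allowed values, and a description.
#'
#' @return A tibble.
#' @export
#' @examples
#' trial_codebook()
trial_codebook <- function() {
  codebook_def()
}

validate_trials <- function(records) {
  cb <- codebook_def()
  missing_cols <- setdiff(cb$column, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "antivea_dialect_error")
  }
  bad_date <- !grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$",
                     records$session_date)
  if (any(bad_date)) {
    abort(sprintf("malformed session_date in %d row(s); expected 'yyyy-mm-dd hh:mm:ss'",
                  sum(bad_date)),
          class = "antivea_dialect_error")
  }
  for (i in which(!is.na(cb$allowed))) {
    col <- cb$column[i]
    vals <- if (grepl(":", cb$allowed[i])) {
      rng <- as.integer(strsplit(cb$allowed[i], ":")[[1]])
      as.character(seq(rng[1], rng[2]))
    } else {
      strsplit(cb$allowed[i], "|", fixed = TRUE)[[1]]
    }
    bad <- !is.na(records[[col]]) & !as.character(records[[col]]) %in% vals
    if (any(bad)) {
      abort(sprintf("column '%s' has %d value(s) outside its codebook range",
                    col, sum(bad)),
            class = "antivea_dialect_error")
    }
  }
  key <- paste(records$subject_id, records$session_number,
               records$trial_index)
  if (anyDuplicated(key)) {
    abort("duplicate (subject_id, session_number, trial_index) rows",
          class = "antivea_dialect_error")
  }
  no_resp <- records$response_class == "none"
  if (any(no_resp != is.na(records$rt_ms), na.rm = TRUE)) {
    abort("rt_ms must be missing exactly when response_class is 'none'",
          class = "antivea_dialect_error")
  }
  invisible(records)
}

#' Write raw trial records to CSV
#'
#' Writes the documented dialect (RFC-4180 quoting, UTF-8): deterministic
#' codebook column order, rows sorted by subject, session, and trial index,
#' missing values as empty fields, RTs at 3 and probe ratings at 6 decimal
#' places. Records are validated before anything is written.
#'
#' @param records A tibble of raw trial records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  cb <- codebook_def()
  validate_trials(records)
  out <- records[cb$column] |>
    arrange(.data$subject_id, .data$session_number, .data$trial_index) |>
    mutate(rt_ms = round(.data$rt_ms, 3),
           probe_rating = round(.data$probe_rating, 6))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read raw trial records from CSV
#'
#' Parses and validates a trial-level CSV in the package dialect. Strict
#' mode rejects unknown columns; lenient mode drops and reports them. A
#' column map adapts externally produced files: a named character vector
#' whose names are dialect columns and whose values are the file's column
#' names.
#'
#' @param path CSV file path.
#' @param strict Reject unknown columns? (default `TRUE`)
#' @param col_map Optional named character vector renaming file columns to
#'   dialect columns.
#' @return A validated tibble of raw trial records.
#' @export
read_trials <- function(path, strict = TRUE, col_map = NULL) {
  cb <- codebook_def()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  if (!is.null(col_map)) {
    hit <- col_map[col_map %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- names(hit)
  }
  extra <- setdiff(names(raw), cb$column)
  if (length(extra) > 0) {
    if (strict) {
      abort(paste0("unknown column(s) in strict mode: ",
                   paste(extra, collapse = ", ")),
            class = "antivea_dialect_error")
    }
    inform(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    raw <- raw[setdiff(names(raw), extra)]
  }
  missing_cols <- setdiff(cb$column, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "antivea_dialect_error")
  }
  conv <- list(c = as.character, i = as.integer, d = as.numeric,
               l = as.logical)
  for (i in seq_len(nrow(cb))) {
    raw[[cb$column[i]]] <- conv[[cb$type[i]]](raw[[cb$column[i]]])
  }
  raw <- raw[cb$column]
  validate_trials(raw)
  raw
}
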