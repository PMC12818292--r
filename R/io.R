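# Delimited-text formats: trial tables, score tables, transcript tables and
# run manifests. All files are comma-separated UTF-8 with a header row.

trial_required_cols <- c(
  "study_day", "dyad_id", "subject_a", "subject_b", "task", "trial_index",
  "correct_answer", "answer_a", "answer_b", "correct_a", "correct_b",
  "confidence_a", "confidence_b", "joint_answer", "joint_correct", "conflict"
)
trial_optional_cols <- c("words_a", "words_b", "lexicon_count")
trial_char_cols <- c("dyad_id", "subject_a", "subject_b", "task",
                     "correct_answer", "answer_a", "answer_b", "joint_answer")

fail_rows <- function(bad, what) {
  if (any(bad)) {
    stop_olf(what, " in row(s): ",
             paste(utils::head(which(bad), 10), collapse = ", "),
             if (sum(bad) > 10) " ..." else "",
             class = "olfdyad_schema_error")
  }
}

#' Validate a day-2 trial table against the schema
#'
#' Checks column names, value ranges, key uniqueness and internal
#' consistency: the conflict flag must equal the answer mismatch, the
#' individual and joint correctness flags must agree with the answers and
#' the correct answer, and trial indices must be unique within
#' (dyad, task, day). Violations are reported with the offending row
#' numbers.
#'
#' @param trials data.frame to validate.
#' @return the validated data.frame, invisibly.
#' @export
validate_trial_table <- function(trials) {
  miss <- setdiff(trial_required_cols, names(trials))
  if (length(miss)) {
    stop_olf("missing column(s): ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  unknown <- setdiff(names(trials), c(trial_required_cols, trial_optional_cols))
  if (length(unknown)) {
    stop_olf("unknown column(s): ", paste(unknown, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  fail_rows(!trials$study_day %in% c(1L, 2L), "study_day not in {1, 2}")
  fail_rows(!trials$task %in% c("discrimination", "identification"),
            "unknown task")
  fail_rows(trials$trial_index < 1, "trial_index below 1")
  key <- interaction(trials$dyad_id, trials$task, trials$study_day,
                     trials$trial_index, drop = TRUE)
  fail_rows(duplicated(key), "duplicate (dyad, task, day, trial) key")
  fail_rows(trials$conflict != classify_conflict(trials$answer_a, trials$answer_b),
            "conflict flag disagrees with the answers")
  fail_rows(trials$correct_a != (trials$answer_a == trials$correct_answer),
            "correct_a disagrees with answer_a vs correct_answer")
  fail_rows(trials$correct_b != (trials$answer_b == trials$correct_answer),
            "correct_b disagrees with answer_b vs correct_answer")
  fail_rows(trials$joint_correct != (trials$joint_answer == trials$correct_answer),
            "joint_correct disagrees with joint_answer vs correct_answer")
  fail_rows(trials$confidence_a < 1 | trials$confidence_b < 1,
            "confidence below 1")
  for (col in intersect(trial_optional_cols, names(trials))) {
    fail_rows(trials[[col]] < 0, paste0(col, " negative"))
  }
  invisible(trials)
}

#' Write / read a trial table
#'
#' `write_trial_table()` validates and writes the table as CSV;
#' `read_trial_table()` reads and validates it, preserving answer columns
#' as character (pen positions and option labels are labels, not numbers).
#' A write followed by a read returns an identical table.
#'
#' @param trials data.frame following the trial-table schema.
#' @param path file path.
#' @return `read_trial_table()` returns the validated data.frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    stop_olf("no such file: ", path, class = "olfdyad_missing_input")
  }
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  classes <- stats::setNames(rep(NA_character_, length(header)), header)
  classes[header %in% trial_char_cols] <- "character"
  trials <- utils::read.csv(path, colClasses = classes, check.names = FALSE)
  validate_trial_table(trials)
  trials
}

#' Write / read a subject score table
#'
#' One row per subject per day: `subject_id`, `day`, optional demographics,
#' `t_score` (day 1 only), `d_score`, `i_score`, `di_sum`.
#'
#' @param scores data.frame of subject scores.
#' @param path file path.
#' @export
write_score_table <- function(scores, path) {
  req <- c("subject_id", "day", "d_score", "i_score", "di_sum")
  miss <- setdiff(req, names(scores))
  if (length(miss)) {
    stop_olf("score table missing column(s): ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  utils::write.csv(scores, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) {
    stop_olf("no such file: ", path, class = "olfdyad_missing_input")
  }
  scores <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  bad_rng <- !is.na(scores$d_score) & (scores$d_score < 0 | scores$d_score > 16)
  fail_rows(bad_rng, "d_score outside 0..16")
  bad_rng <- !is.na(scores$i_score) & (scores$i_score < 0 | scores$i_score > 16)
  fail_rows(bad_rng, "i_score outside 0..16")
  fail_rows(scores$di_sum != scores$d_score + scores$i_score,
            "di_sum is not d_score + i_score")
  scores
}

#' Write / read a transcript table
#'
#' One row per speaker turn: `dyad_id`, `task`, `trial_index`, `speaker`,
#' `utterance`.
#'
#' @param transcript data.frame of utterances.
#' @param path file path.
#' @export
write_transcript_table <- function(transcript, path) {
  req <- c("dyad_id", "task", "trial_index", "speaker", "utterance")
  miss <- setdiff(req, names(transcript))
  if (length(miss)) {
    stop_olf("transcript table missing column(s): ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  utils::write.csv(transcript, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_transcript_table
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) {
    stop_olf("no such file: ", path, class = "olfdyad_missing_input")
  }
  utils::read.csv(path, colClasses = c(dyad_id = "character", task = "character",
                                       speaker = "character",
                                       utterance = "character"))
}

#' Write / read a run manifest
#'
#' Plain-text key: value pairs recording seeds, parameters and versions.
#'
#' @param manifest named character vector or list.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  keys <- names(manifest)
  if (is.null(keys) || any(!nzchar(keys))) {
    stop_olf("manifest entries must be named")
  }
  writeLines(paste0(keys, ": ", vapply(manifest, as.character, character(1))),
             path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keys <- sub(":.*$", "", lines)
  vals <- sub("^[^:]*: ?", "", lines)
  stats::setNames(vals, keys)
}
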