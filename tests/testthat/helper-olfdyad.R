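# Shared fixture builders. Everything is generated in code; no data files.

# A tiny, fully consistent day-2 trial table for one dyad and task.
# conflicts: trial 2 (resolvable, resolved), trial 3 (resolvable, failed),
# trial 4 (both wrong). trial 1 and 5: agreement.
make_trials <- function(dyad_id = "dyad01", task = "discrimination") {
  ans <- function(x) as.character(x)
  df <- data.frame(
    study_day = 2L,
    dyad_id = dyad_id,
    subject_a = "S01",
    subject_b = "S02",
    task = task,
    trial_index = 1:5,
    correct_answer = ans(c(1, 2, 3, 1, 2)),
    answer_a = ans(c(1, 2, 3, 2, 2)),
    answer_b = ans(c(1, 3, 1, 3, 2)),
    confidence_a = c(3L, 4L, 2L, 1L, 3L),
    confidence_b = c(2L, 1L, 3L, 2L, 3L),
    joint_answer = ans(c(1, 2, 1, 3, 2)),
    words_a = c(5L, 30L, 12L, 18L, 4L),
    words_b = c(3L, 10L, 25L, 9L, 6L),
    lexicon_count = c(0L, 3L, 2L, 1L, 0L)
  )
  df$correct_a <- df$answer_a == df$correct_answer
  df$correct_b <- df$answer_b == df$correct_answer
  df$joint_correct <- df$joint_answer == df$correct_answer
  df$conflict <- df$answer_a != df$answer_b
  df[c("study_day", "dyad_id", "subject_a", "subject_b", "task", "trial_index",
       "correct_answer", "answer_a", "answer_b", "correct_a", "correct_b",
       "confidence_a", "confidence_b", "joint_answer", "joint_correct",
       "conflict", "words_a", "words_b", "lexicon_count")]
}

# Small, quick study dataset for pipeline tests.
make_small_dataset <- function(seed = 7, ...) {
  generate_study_dataset(
    cohort_config(n_day1 = 24L, n_return = 16L),
    language_config(...),
    seed = seed
  )
}

# Monte-Carlo standard error of a proportion.
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
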