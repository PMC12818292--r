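#' Ability-similarity ratio within a dyad
#'
#' The similarity ratio of a pair of individual test scores is
#' \eqn{S_{min}/S_{max}}: the lower score divided by the higher one. A value
#' of 1 means the two members are equally able on that subtest; values near
#' zero mean one member is far better than the other. The ratio is symmetric
#' in its two arguments.
#'
#' @param score_a,score_b non-negative individual scores (same subtest),
#'   vectorized.
#' @return a data.frame with columns `s_min`, `s_max`, `ratio`.
#' @export
#' @examples
#' similarity_ratio(8, 16)$ratio  # 0.5
similarity_ratio <- function(score_a, score_b) {
  if (length(score_a) != length(score_b)) {
    stop_olf("score_a and score_b must have equal length", class = "olfdyad_alignment_error")
  }
  if (any(is.na(score_a)) || any(is.na(score_b))) {
    stop_olf("missing score", class = "olfdyad_missing_data")
  }
  if (any(score_a < 0) || any(score_b < 0)) {
    stop_olf("scores must be non-negative")
  }
  s_max <- pmax(score_a, score_b)
  s_min <- pmin(score_a, score_b)
  if (any(s_max == 0)) {
    stop_olf("similarity ratio undefined when both scores are zero",
             class = "olfdyad_undefined_ratio")
  }
  data.frame(s_min = s_min, s_max = s_max, ratio = s_min / s_max)
}

#' Collective benefit of a dyad
#'
#' Collective benefit is the ratio between a dyad's joint score and the
#' individual score of its better member. Values above 1 indicate the pair
#' outperformed its best individual.
#'
#' @param s_dyad joint (collaborative) score of the dyad, vectorized.
#' @param score_a,score_b the two members' individual scores.
#' @return a data.frame with columns `s_dyad`, `s_max`, `cb`.
#' @export
#' @examples
#' collective_benefit(14, 12, 10)$cb # 1.1667
collective_benefit <- function(s_dyad, score_a, score_b) {
  n <- length(s_dyad)
  if (length(score_a) != n || length(score_b) != n) {
    stop_olf("inputs must have equal length", class = "olfdyad_alignment_error")
  }
  if (any(is.na(s_dyad)) || any(is.na(score_a)) || any(is.na(score_b))) {
    stop_olf("missing score", class = "olfdyad_missing_data")
  }
  s_max <- pmax(score_a, score_b)
  if (any(s_max == 0)) {
    stop_olf("collective benefit undefined when the best individual score is zero",
             class = "olfdyad_undefined_ratio")
  }
  data.frame(s_dyad = s_dyad, s_max = s_max, cb = s_dyad / s_max)
}

#' Classify a trial as a conflict
#'
#' A conflict trial is one where the two members' private answers differ
#' (exact label equality on the trial's alternative set).
#'
#' @param answer_a,answer_b the two private answers (vectorized; any atomic
#'   label type).
#' @return logical vector, `TRUE` where answers differ.
#' @export
classify_conflict <- function(answer_a, answer_b) {
  if (length(answer_a) != length(answer_b)) {
    stop_olf("answers must have equal length", class = "olfdyad_alignment_error")
  }
  if (any(is.na(answer_a)) || any(is.na(answer_b))) {
    stop_olf("missing answer", class = "olfdyad_missing_data")
  }
  as.character(answer_a) != as.character(answer_b)
}

#' Outcome of a conflict trial
#'
#' A conflict counts as successfully resolved when the joint answer is
#' correct. Resolution is only defined for conflicts where exactly one
#' member was correct; conflicts where both members were wrong (or, not a
#' conflict at all, both right) are flagged as excluded from
#' resolution-rate denominators.
#'
#' @param trial a data.frame of trial records with columns `answer_a`,
#'   `answer_b`, `correct_a`, `correct_b`, `joint_answer`, `joint_correct`.
#' @return character vector with values `success`, `failure`,
#'   `excluded_both_wrong`, `excluded_both_correct`, `not_conflict`.
#' @export
resolve_conflict_outcome <- function(trial) {
  req <- c("answer_a", "answer_b", "correct_a", "correct_b",
           "joint_answer", "joint_correct")
  miss <- setdiff(req, names(trial))
  if (length(miss)) {
    stop_olf("trial table missing columns: ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  if (any(is.na(trial$joint_answer)) || any(is.na(trial$joint_correct))) {
    stop_olf("joint answer absent", class = "olfdyad_missing_data")
  }
  conflict <- classify_conflict(trial$answer_a, trial$answer_b)
  n_corr <- as.integer(trial$correct_a) + as.integer(trial$correct_b)
  out <- character(nrow(trial))
  out[!conflict] <- "not_conflict"
  out[conflict & n_corr == 0L] <- "excluded_both_wrong"
  out[conflict & n_corr == 2L] <- "excluded_both_correct"
  res <- conflict & n_corr == 1L
  out[res & trial$joint_correct] <- "success"
  out[res & !trial$joint_correct] <- "failure"
  out
}

#' Summarize conflicts for one dyad and task
#'
#' Counts conflict trials, the subset that is resolvable (exactly one member
#' correct), and how many of those the dyad resolved (joint answer correct).
#' The conflict percentage is reported on the 0-100 scale.
#'
#' @param trials data.frame of one dyad/task/day's trial records (see
#'   [resolve_conflict_outcome()] for required columns).
#' @return one-row data.frame: `n_trials`, `n_conflicts`, `pct_conflicts`,
#'   `n_resolvable`, `n_resolved`, `resolution_rate` (`NA` when there are no
#'   resolvable conflicts).
#' @export
summarize_conflicts <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop_olf("empty trial set", class = "olfdyad_empty_input")
  }
  outcome <- resolve_conflict_outcome(trials)
  n_trials <- nrow(trials)
  n_conflicts <- sum(outcome != "not_conflict")
  n_resolvable <- sum(outcome %in% c("success", "failure"))
  n_resolved <- sum(outcome == "success")
  data.frame(
    n_trials = n_trials,
    n_conflicts = n_conflicts,
    pct_conflicts = 100 * n_conflicts / n_trials,
    n_resolvable = n_resolvable,
    n_resolved = n_resolved,
    resolution_rate = if (n_resolvable > 0) n_resolved / n_resolvable else NA_real_
  )
}

#' Quartile-based dyad matching on combined ability
#'
#' Ranks participants by their combined discrimination + identification
#' (D + I) score and splits the cohort into a bottom quartile (low ability),
#' two middle quartiles (average ability) and a top quartile (high ability).
#' Average-ability participants are randomly paired with one another
#' (`high_similarity` dyads); high-ability participants are randomly paired
#' with low-ability ones (`low_similarity` dyads). Any member left over
#' after pairing is dropped with a warning.
#'
#' Quartile boundaries for cohorts not divisible by 4 are taken at
#' `ceiling(n/4)` and `floor(3n/4)` of the ascending ranking, with ties
#' broken by subject id so the split is deterministic.
#'
#' @param day1_scores data.frame with columns `subject_id` and `di_sum`.
#' @param seed integer seed controlling the random pairings.
#' @return data.frame with columns `dyad_id`, `member_1`, `member_2`,
#'   `similarity_group` (`high_similarity` or `low_similarity`).
#' @export
match_dyads <- function(day1_scores, seed = NULL) {
  req <- c("subject_id", "di_sum")
  if (!all(req %in% names(day1_scores))) {
    stop_olf("day1_scores needs columns subject_id and di_sum",
             class = "olfdyad_schema_error")
  }
  n <- nrow(day1_scores)
  if (n < 4) {
    stop_olf("need at least 4 participants to form matched dyads",
             class = "olfdyad_insufficient_cohort")
  }
  ord <- order(day1_scores$di_sum, day1_scores$subject_id)
  ranked <- day1_scores[ord, , drop = FALSE]
  lo_cut <- ceiling(n / 4)
  hi_cut <- floor(3 * n / 4)
  bottom <- ranked$subject_id[seq_len(lo_cut)]
  top <- ranked$subject_id[(hi_cut + 1):n]
  middle <- ranked$subject_id[(lo_cut + 1):hi_cut]

  with_seed(seed, {
    mid_shuffled <- sample(middle)
    n_mid_pairs <- floor(length(mid_shuffled) / 2)
    dropped <- character(0)
    if (length(mid_shuffled) %% 2 == 1) {
      dropped <- c(dropped, mid_shuffled[length(mid_shuffled)])
    }
    top_shuffled <- sample(top)
    bot_shuffled <- sample(bottom)
    n_lo_pairs <- min(length(top_shuffled), length(bot_shuffled))
    if (length(top_shuffled) > n_lo_pairs) {
      dropped <- c(dropped, top_shuffled[(n_lo_pairs + 1):length(top_shuffled)])
    }
    if (length(bot_shuffled) > n_lo_pairs) {
      dropped <- c(dropped, bot_shuffled[(n_lo_pairs + 1):length(bot_shuffled)])
    }
    if (length(dropped)) {
      warning("dropping unpaired participants: ", paste(dropped, collapse = ", "),
              call. = FALSE)
    }
    hi <- if (n_mid_pairs > 0) {
      data.frame(
        member_1 = mid_shuffled[seq(1, by = 2, length.out = n_mid_pairs)],
        member_2 = mid_shuffled[seq(2, by = 2, length.out = n_mid_pairs)],
        similarity_group = "high_similarity"
      )
    } else NULL
    lo <- if (n_lo_pairs > 0) {
      data.frame(
        member_1 = top_shuffled[seq_len(n_lo_pairs)],
        member_2 = bot_shuffled[seq_len(n_lo_pairs)],
        similarity_group = "low_similarity"
      )
    } else NULL
    out <- rbind(hi, lo)
    out <- cbind(dyad_id = sprintf("dyad%02d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Paired comparisons of dyad scores against individual baselines
#'
#' Runs two two-sided paired t tests per call: the dyad's joint score
#' against its better member's score ("dyad vs best"), and against the mean
#' of its two members' scores ("dyad vs average"). The latter is the
#' prediction of the coin-flip voting model of joint decision-making, so a
#' positive dyad-minus-average difference indicates integration beyond
#' voting.
#'
#' @param dyad_scores,best_scores,mean_scores aligned per-dyad numeric
#'   vectors.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return data.frame with one row per comparison: `comparison`,
#'   `mean_diff`, `t`, `df`, `p`, `ci_low`, `ci_high`.
#' @export
compare_dyad_baselines <- function(dyad_scores, best_scores, mean_scores,
                                   conf_level = 0.95) {
  n <- length(dyad_scores)
  if (length(best_scores) != n || length(mean_scores) != n) {
    stop_olf("score vectors must be aligned per dyad",
             class = "olfdyad_alignment_error")
  }
  if (n < 2) stop_olf("need at least 2 dyads for a paired test")
  one <- function(label, baseline) {
    d <- dyad_scores - baseline
    if (stats::sd(d) == 0) {
      # degenerate paired test: all differences identical
      est <- mean(d)
      data.frame(comparison = label, mean_diff = est,
                 t = if (est == 0) 0 else NaN, df = n - 1,
                 p = if (est == 0) 1 else NaN,
                 ci_low = est, ci_high = est)
    } else {
      tt <- stats::t.test(dyad_scores, baseline, paired = TRUE,
                          conf.level = conf_level)
      data.frame(comparison = label, mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, ci_low = tt$conf.int[1],
                 ci_high = tt$conf.int[2])
    }
  }
  rbind(one("dyad_vs_best", best_scores),
        one("dyad_vs_average", mean_scores))
}

#' Per-dyad score and similarity summary
#'
#' Aggregates a day-2 dyadic trial table into one row per dyad and task:
#' each member's individual score, the joint score, similarity ratios on
#' the day-2 basis (and the day-1 basis when a day-1 score table is given)
#' and the collective benefit.
#'
#' @param trials day-2 trial table (see [read_trial_table()] for the schema).
#' @param day1_scores optional day-1 score table with `subject_id`,
#'   `d_score`, `i_score`.
#' @return data.frame, one row per (dyad, task), with columns `dyad_id`,
#'   `task`, `subject_a`, `subject_b`, `n_trials`, `s_a`, `s_b`, `s_dyad`,
#'   `s_max`, `s_mean`, `ratio_day2`, `cb`, and `ratio_day1` when day-1
#'   scores are supplied.
#' @export
dyad_score_table <- function(trials, day1_scores = NULL) {
  req <- c("dyad_id", "task", "subject_a", "subject_b",
           "correct_a", "correct_b", "joint_correct")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop_olf("trial table missing columns: ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  key <- interaction(trials$dyad_id, trials$task, drop = TRUE)
  rows <- lapply(split(trials, key), function(tr) {
    data.frame(
      dyad_id = tr$dyad_id[1],
      task = tr$task[1],
      subject_a = tr$subject_a[1],
      subject_b = tr$subject_b[1],
      n_trials = nrow(tr),
      s_a = sum(tr$correct_a),
      s_b = sum(tr$correct_b),
      s_dyad = sum(tr$joint_correct)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$s_max <- pmax(out$s_a, out$s_b)
  out$s_mean <- (out$s_a + out$s_b) / 2
  out$ratio_day2 <- similarity_ratio(out$s_a, out$s_b)$ratio
  out$cb <- collective_benefit(out$s_dyad, out$s_a, out$s_b)$cb
  if (!is.null(day1_scores)) {
    sc <- day1_scores
    col_for <- function(task) ifelse(task == "discrimination", "d_score", "i_score")
    get1 <- function(subject, task) {
      i <- match(subject, sc$subject_id)
      if (any(is.na(i))) {
        stop_olf("day-1 scores missing for some dyad members",
                 class = "olfdyad_missing_data")
      }
      ifelse(task == "discrimination", sc$d_score[i], sc$i_score[i])
    }
    a1 <- get1(out$subject_a, out$task)
    b1 <- get1(out$subject_b, out$task)
    out$ratio_day1 <- similarity_ratio(a1, b1)$ratio
  }
  out
}
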