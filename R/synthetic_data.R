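#' Cohort configuration for the synthetic study generator
#'
#' Defaults describe the study conditions the generator emulates: a 53-person
#' day-1 cohort of which 40 return in 20 dyads, 16-trial 3AFC discrimination
#' and 16-trial 4AFC identification blocks, a 16-level threshold staircase,
#' heterogeneous latent abilities with higher day-1 to day-2 retest
#' correlation for discrimination than identification, and confidence
#' ratings coupled to accuracy through the observer model's metacognitive
#' noise. Ability means were chosen so that expected subtest scores fall in
#' the healthy-adult range of the clinical battery (D and I near 13/16) and
#' private answers disagree on roughly one third of dyadic trials.
#'
#' @param n_day1 day-1 cohort size.
#' @param n_return subjects returning on day 2 (must be even, at most
#'   `n_day1`).
#' @param ability_mean_d,ability_sd_d discrimination latent ability
#'   distribution (Gaussian, truncated at 0).
#' @param ability_mean_i,ability_sd_i identification latent ability
#'   distribution.
#' @param rho_d,rho_i day-1/day-2 retest correlations of the latent
#'   abilities (`rho_d > rho_i` by default: discrimination is the more
#'   reliable subtest).
#' @param theta_mean,theta_sd distribution of the threshold psychometric
#'   midpoint (level units).
#' @param thresh_slope logistic slope of the threshold psychometric
#'   function (level units).
#' @param gap_mean_days,gap_sd_days inter-session gap; recorded as metadata
#'   only.
#' @param n_trials trials per task block.
#' @param meta_noise metacognitive noise of all observers.
#' @param n_conf_levels ordinal confidence levels.
#' @param age_mean,age_sd,prop_male demographic distribution.
#' @param age_slope_i linear age effect on the identification latent
#'   ability, per year of age (0 disables it).
#' @param conflict_band acceptable band for the overall conflict proportion,
#'   used by validation checks.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_day1 = 53L, n_return = 40L,
                          ability_mean_d = 1.65, ability_sd_d = 0.5, rho_d = 0.8,
                          ability_mean_i = 2.0, ability_sd_i = 0.5, rho_i = 0.6,
                          theta_mean = 9, theta_sd = 2.5, thresh_slope = 1.5,
                          gap_mean_days = 40.6, gap_sd_days = 23.3,
                          n_trials = 16L, meta_noise = 0.5, n_conf_levels = 4L,
                          age_mean = 24.42, age_sd = 4.07, prop_male = 16 / 53,
                          age_slope_i = 0.05,
                          conflict_band = c(0.25, 0.42)) {
  if (n_return > n_day1) stop_olf("n_return cannot exceed n_day1")
  if (n_return %% 2 != 0) stop_olf("n_return must be even (whole dyads)")
  if (abs(rho_d) > 1 || abs(rho_i) > 1) stop_olf("retest correlations must lie in [-1, 1]")
  structure(as.list(environment()), class = "cohort_config")
}

#' Language-generation configuration
#'
#' Controls the transcript-derived metrics attached to each dyadic trial:
#' total words per trial (log-normal dyad effect, Poisson trial counts, an
#' additive boost on conflict trials and a reduction in identification),
#' confidence-lexicon counts (Poisson, log-linear in conflict and task) and
#' the talkative-wins mechanism that decides conflict trials by relative
#' talkativeness. Effect defaults are set to the magnitudes a study of this
#' design can expect: about 48 extra words on conflict trials, about 11
#' fewer in identification, a +1.26 log-rate conflict effect and a -0.35
#' log-rate identification effect on lexicon counts, and log-odds of -0.59
#' that the more talkative member's answer becomes the joint answer.
#'
#' @param base_words expected dyad-total words on a non-conflict
#'   discrimination trial.
#' @param conflict_boost_words additional expected words on conflict trials.
#' @param task_effect_words change in expected words for identification
#'   trials (negative = fewer).
#' @param dyad_talkativeness_sd between-dyad SD of log talkativeness.
#' @param trial_word_sd extra within-dyad trial-level log-normal SD.
#' @param member_imbalance_sd SD of the per-dyad member log-odds share of
#'   words (0 = members always split words evenly in expectation).
#' @param talkative_wins logical; when `TRUE` the joint answer on conflict
#'   trials is re-decided by talkativeness (see Details).
#' @param talkative_wins_logodds log-odds that the *more* talkative member
#'   wins a conflict trial.
#' @param base_lexicon_rate expected lexicon matches on a non-conflict
#'   discrimination trial.
#' @param lexicon_conflict_effect,lexicon_task_effect log-scale effects of
#'   conflict and of identification on the lexicon rate.
#' @param lexicon_dyad_sd between-dyad SD of the log lexicon rate.
#' @return an object of class `language_config`.
#' @export
language_config <- function(base_words = 25, conflict_boost_words = 47.9,
                            task_effect_words = -11.47,
                            dyad_talkativeness_sd = 0.3, trial_word_sd = 0.25,
                            member_imbalance_sd = 0.4,
                            talkative_wins = TRUE,
                            talkative_wins_logodds = -0.59,
                            base_lexicon_rate = 0.6,
                            lexicon_conflict_effect = 1.26,
                            lexicon_task_effect = -0.35,
                            lexicon_dyad_sd = 0.2) {
  if (dyad_talkativeness_sd < 0 || trial_word_sd < 0 || member_imbalance_sd < 0 ||
      lexicon_dyad_sd < 0) {
    stop_olf("standard deviations must be non-negative")
  }
  structure(as.list(environment()), class = "language_config")
}

# correlated truncated-Gaussian latent abilities for two days
latent_pair <- function(n, mean, sd, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(day1 = pmax(0, mean + sd * z1), day2 = pmax(0, mean + sd * z2))
}

#' Generate a synthetic day-1 cohort
#'
#' Draws demographics and latent abilities for every subject, then produces
#' day-1 subtest scores by actually running the test procedures: the
#' threshold staircase against each subject's logistic psychometric
#' function, and 16 simulated trials each of the 3AFC discrimination and
#' 4AFC identification tasks.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return object of class `olf_cohort`: list with `scores` (day-1 score
#'   table: `subject_id`, `day`, `age`, `gender`, `t_score`, `d_score`,
#'   `i_score`, `di_sum`, `excluded_anosmia`, `gap_days`), `latent`
#'   (per-subject latent abilities for both days) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  cc <- config
  with_seed(seed, {
    n <- cc$n_day1
    subject_id <- sprintf("S%02d", seq_len(n))
    age <- round(stats::rnorm(n, cc$age_mean, cc$age_sd))
    age <- pmax(18, age)
    gender <- ifelse(stats::runif(n) < cc$prop_male, "male", "female")
    ab_d <- latent_pair(n, cc$ability_mean_d, cc$ability_sd_d, cc$rho_d)
    ab_i <- latent_pair(n, cc$ability_mean_i, cc$ability_sd_i, cc$rho_i)
    if (cc$age_slope_i != 0) {
      shift <- cc$age_slope_i * (age - cc$age_mean)
      ab_i$day1 <- pmax(0, ab_i$day1 + shift)
      ab_i$day2 <- pmax(0, ab_i$day2 + shift)
    }
    theta <- pmin(16, pmax(1, stats::rnorm(n, cc$theta_mean, cc$theta_sd)))
    gap_days <- pmax(7, round(stats::rnorm(n, cc$gap_mean_days, cc$gap_sd_days)))

    t_score <- numeric(n)
    excluded <- logical(n)
    d_score <- integer(n)
    i_score <- integer(n)
    for (k in seq_len(n)) {
      res <- run_threshold_test(logistic_responder(theta[k], cc$thresh_slope))
      t_score[k] <- res$t_score
      excluded[k] <- res$excluded_anosmia
      pd <- observer_params(ab_d$day1[k], cc$meta_noise, cc$n_conf_levels)
      pi_ <- observer_params(ab_i$day1[k], cc$meta_noise, cc$n_conf_levels)
      d_score[k] <- sum(simulate_individual_trials(pd, 3L, cc$n_trials)$correct)
      i_score[k] <- sum(simulate_individual_trials(pi_, 4L, cc$n_trials)$correct)
    }
    scores <- data.frame(
      subject_id = subject_id, day = 1L, age = age, gender = gender,
      t_score = t_score, d_score = d_score, i_score = i_score,
      di_sum = d_score + i_score, excluded_anosmia = excluded,
      gap_days = gap_days
    )
    latent <- data.frame(
      subject_id = subject_id,
      ability_d_day1 = ab_d$day1, ability_d_day2 = ab_d$day2,
      ability_i_day1 = ab_i$day1, ability_i_day2 = ab_i$day2,
      theta = theta
    )
    structure(list(scores = scores, latent = latent, config = cc),
              class = "olf_cohort")
  })
}

#' Generate a complete synthetic study dataset
#'
#' Runs the whole design end-to-end: day-1 cohort via [generate_cohort()],
#' quartile-based dyad matching on the day-1 D + I sum via [match_dyads()],
#' random selection of the returning dyads, day-2 dyadic sessions for both
#' tasks under the chosen aggregation rule, and transcript-derived word and
#' lexicon counts per trial. When the talkative-wins mechanism is enabled
#' (the default), the joint answer of each conflict trial is re-decided:
#' the more talkative member's answer is adopted with probability
#' `plogis(talkative_wins_logodds)`, the less talkative member's otherwise,
#' which breaks any link between the aggregation rule and conflict
#' outcomes. Disable it (`talkative_wins = FALSE`) to study the aggregation
#' rules themselves.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param language_cfg a [language_config()].
#' @param rule dyadic aggregation rule (see [combine_dyad_decision()]).
#' @param seed integer seed; all randomness in the dataset flows from it.
#' @return list of class `olf_dataset` with `trials` (day-2 trial table
#'   including `words_a`, `words_b`, `lexicon_count`), `scores` (day-1 and
#'   day-2 score table), `transcript_metrics`, `pairing` and `manifest`
#'   (named character vector of generation parameters).
#' @export
generate_study_dataset <- function(cohort_cfg = cohort_config(),
                                   language_cfg = language_config(),
                                   rule = "defer_to_higher_confidence",
                                   seed = 1L) {
  notes <- character(0)
  cohort <- generate_cohort(cohort_cfg, child_seed(seed, "cohort"))
  pairing <- withCallingHandlers(
    match_dyads(cohort$scores, child_seed(seed, "match")),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  n_dyads <- cohort_cfg$n_return / 2L
  pairing <- with_seed(child_seed(seed, "return"), {
    grp <- split(seq_len(nrow(pairing)), pairing$similarity_group)
    n_hi <- min(length(grp$high_similarity %||% integer(0)), ceiling(n_dyads / 2))
    n_lo <- min(length(grp$low_similarity %||% integer(0)), n_dyads - n_hi)
    if (n_hi + n_lo < n_dyads) {
      n_hi <- min(length(grp$high_similarity), n_dyads - n_lo)
    }
    if (n_hi + n_lo < n_dyads) {
      stop_olf("not enough matched dyads for the requested returning cohort",
               class = "olfdyad_insufficient_cohort")
    }
    keep <- c(sample(grp$high_similarity, n_hi), sample(grp$low_similarity, n_lo))
    out <- pairing[sort(keep), , drop = FALSE]
    out$dyad_id <- sprintf("dyad%02d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })

  latent <- cohort$latent
  cc <- cohort_cfg
  trials <- with_seed(child_seed(seed, "session"), {
    blocks <- lapply(seq_len(nrow(pairing)), function(i) {
      pa <- pairing$member_1[i]
      pb <- pairing$member_2[i]
      la <- latent[match(pa, latent$subject_id), ]
      lb <- latent[match(pb, latent$subject_id), ]
      do.call(rbind, lapply(c("discrimination", "identification"), function(task) {
        col <- if (task == "discrimination") "ability_d_day2" else "ability_i_day2"
        simulate_session(
          observer_params(la[[col]], cc$meta_noise, cc$n_conf_levels),
          observer_params(lb[[col]], cc$meta_noise, cc$n_conf_levels),
          rule = rule, n_trials = cc$n_trials, task = task,
          dyad_id = pairing$dyad_id[i], subject_a = pa, subject_b = pb)
      }))
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })

  trials <- with_seed(child_seed(seed, "language"), {
    lc <- language_cfg
    n <- nrow(trials)
    ident <- trials$task == "identification"
    dyads <- unique(trials$dyad_id)
    talk_mult <- stats::setNames(
      exp(stats::rnorm(length(dyads), 0, lc$dyad_talkativeness_sd) -
            lc$dyad_talkativeness_sd^2 / 2), dyads)
    share_a <- stats::setNames(
      stats::plogis(stats::rnorm(length(dyads), 0, lc$member_imbalance_sd)), dyads)
    lex_re <- stats::setNames(
      stats::rnorm(length(dyads), 0, lc$lexicon_dyad_sd) -
        lc$lexicon_dyad_sd^2 / 2, dyads)
    id <- trials$dyad_id
    trial_mult <- exp(stats::rnorm(n, 0, lc$trial_word_sd) - lc$trial_word_sd^2 / 2)
    lambda <- pmax(2, lc$base_words +
                     lc$conflict_boost_words * trials$conflict +
                     lc$task_effect_words * ident) *
      talk_mult[id] * trial_mult
    trials$words_a <- stats::rpois(n, lambda * share_a[id])
    trials$words_b <- stats::rpois(n, lambda * (1 - share_a[id]))
    lex_lambda <- exp(log(lc$base_lexicon_rate) +
                        lc$lexicon_conflict_effect * trials$conflict +
                        lc$lexicon_task_effect * ident + lex_re[id])
    trials$lexicon_count <- stats::rpois(n, lex_lambda)

    if (isTRUE(lc$talkative_wins)) {
      idx <- which(trials$conflict & trials$words_a != trials$words_b)
      if (length(idx)) {
        more_a <- trials$words_a[idx] > trials$words_b[idx]
        more_wins <- stats::runif(length(idx)) < stats::plogis(lc$talkative_wins_logodds)
        pick_a <- (more_a & more_wins) | (!more_a & !more_wins)
        trials$joint_answer[idx] <- ifelse(pick_a, trials$answer_a[idx],
                                           trials$answer_b[idx])
        trials$joint_correct[idx] <- trials$joint_answer[idx] ==
          trials$correct_answer[idx]
      }
    }
    trials
  })

  # day-2 individual scores from the trial table
  long <- pivot_members(trials)
  agg <- stats::aggregate(correct ~ subject_id + task, long, sum)
  wide <- stats::reshape(agg, idvar = "subject_id", timevar = "task",
                         direction = "wide")
  names(wide) <- sub("^correct\\.", "", names(wide))
  day1 <- cohort$scores
  day2 <- data.frame(
    subject_id = wide$subject_id, day = 2L,
    age = day1$age[match(wide$subject_id, day1$subject_id)],
    gender = day1$gender[match(wide$subject_id, day1$subject_id)],
    t_score = NA_real_,
    d_score = wide$discrimination, i_score = wide$identification,
    di_sum = wide$discrimination + wide$identification,
    excluded_anosmia = FALSE,
    gap_days = day1$gap_days[match(wide$subject_id, day1$subject_id)]
  )
  scores <- rbind(day1, day2)
  rownames(scores) <- NULL

  metrics <- trials[c("dyad_id", "task", "trial_index",
                      "words_a", "words_b", "lexicon_count")]
  metrics$words_total <- metrics$words_a + metrics$words_b

  manifest <- c(
    seed = as.character(seed),
    package = paste0("olfdyad ", as.character(utils::packageVersion("olfdyad"))),
    r_version = R.version.string,
    rule = rule,
    n_day1 = as.character(cc$n_day1),
    n_return = as.character(cc$n_return),
    n_trials_per_task = as.character(cc$n_trials),
    ability_model = "gaussian latent ability truncated at zero",
    ability_mean_d = as.character(cc$ability_mean_d),
    ability_sd_d = as.character(cc$ability_sd_d),
    rho_d = as.character(cc$rho_d),
    ability_mean_i = as.character(cc$ability_mean_i),
    ability_sd_i = as.character(cc$ability_sd_i),
    rho_i = as.character(cc$rho_i),
    meta_noise = as.character(cc$meta_noise),
    talkative_wins = as.character(language_cfg$talkative_wins),
    talkative_wins_logodds = as.character(language_cfg$talkative_wins_logodds),
    lexicon_conflict_effect = as.character(language_cfg$lexicon_conflict_effect),
    lexicon_task_effect = as.character(language_cfg$lexicon_task_effect),
    notes = if (length(notes)) paste(notes, collapse = "; ") else "none"
  )

  structure(list(trials = trials, scores = scores,
                 transcript_metrics = metrics, pairing = pairing,
                 manifest = manifest),
            class = "olf_dataset")
}
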