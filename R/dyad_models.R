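#' Signal-detection observer for n-alternative forced choice
#'
#' On each trial the target alternative yields evidence drawn from
#' Normal(ability, 1) and each distractor from Normal(0, 1), all
#' independent; the observer picks the alternative with the largest
#' evidence. Confidence is an ordinal rating obtained by binning the
#' decision margin (top evidence minus runner-up) after adding Gaussian
#' metacognitive noise, so larger `meta_noise` decouples confidence from
#' accuracy.
#'
#' @param ability mean evidence advantage of the target (>= 0); 0 is a
#'   chance-level observer.
#' @param meta_noise standard deviation of the noise added to the
#'   confidence signal (>= 0; 0 gives perfectly informative confidence).
#' @param n_conf_levels number of ordinal confidence levels (default 4).
#' @param conf_bin_edges optional strictly increasing vector of
#'   `n_conf_levels - 1` margin cutoffs; when `NULL`, quantile cutoffs of
#'   the chance-observer margin distribution are computed for the task at
#'   simulation time (see [conf_bin_edges()]).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(ability, meta_noise = 0.5, n_conf_levels = 4L,
                            conf_bin_edges = NULL) {
  if (!is.numeric(ability) || length(ability) != 1 || ability < 0) {
    stop_olf("ability must be a single non-negative number")
  }
  if (meta_noise < 0) stop_olf("meta_noise must be non-negative")
  if (n_conf_levels < 2) stop_olf("need at least 2 confidence levels")
  if (!is.null(conf_bin_edges)) {
    if (length(conf_bin_edges) != n_conf_levels - 1 ||
        is.unsorted(conf_bin_edges, strictly = TRUE)) {
      stop_olf("conf_bin_edges must be ", n_conf_levels - 1,
               " strictly increasing cutoffs")
    }
  }
  structure(list(ability = ability, meta_noise = meta_noise,
                 n_conf_levels = as.integer(n_conf_levels),
                 conf_bin_edges = conf_bin_edges),
            class = "observer_params")
}

# cache for quadrature-derived bin edges, keyed by "m.levels"
.olf_edge_cache <- new.env(parent = emptyenv())

#' Theoretical accuracy of the nAFC observer
#'
#' Closed-form (quadrature) probability that the target alternative wins:
#' the integral of dnorm(e - ability) * pnorm(e)^(m - 1) over e.
#'
#' @param ability mean evidence advantage of the target.
#' @param m number of alternatives.
#' @return probability of a correct choice.
#' @export
#' @examples
#' nafc_accuracy(0, 4)  # 0.25
nafc_accuracy <- function(ability, m) {
  vapply(ability, function(a) {
    stats::integrate(function(e) stats::dnorm(e - a) * stats::pnorm(e)^(m - 1),
                     -Inf, Inf, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Default confidence bin edges for a task
#'
#' Cutoffs are the equally spaced quantiles of the chance-observer decision
#' margin (the gap between the largest and second-largest of `m` standard
#' normal draws), computed deterministically by numerical quadrature, so a
#' zero-ability observer uses all confidence levels about equally often.
#'
#' @param m number of alternatives (2, 3 or 4 in this battery).
#' @param n_conf_levels number of ordinal confidence levels.
#' @return numeric vector of `n_conf_levels - 1` strictly increasing cutoffs.
#' @export
conf_bin_edges <- function(m, n_conf_levels = 4L) {
  key <- paste(m, n_conf_levels, sep = ".")
  if (!is.null(.olf_edge_cache[[key]])) return(.olf_edge_cache[[key]])
  # P(margin > t) = m * Int phi(x) Phi(x - t)^(m-1) dx
  surv <- function(t) {
    m * stats::integrate(function(x) stats::dnorm(x) * stats::pnorm(x - t)^(m - 1),
                         -Inf, Inf, rel.tol = 1e-9)$value
  }
  probs <- seq_len(n_conf_levels - 1) / n_conf_levels
  edges <- vapply(probs, function(p) {
    stats::uniroot(function(t) 1 - surv(t) - p, c(1e-9, 20), tol = 1e-8)$root
  }, numeric(1))
  .olf_edge_cache[[key]] <- edges
  edges
}

#' Simulate individual forced-choice trials
#'
#' Draws `n_trials` independent trials of the nAFC observer model: evidence
#' vectors, argmax choice, correctness, confidence margin and binned ordinal
#' confidence.
#'
#' @param params an [observer_params()].
#' @param m number of alternatives (3 for the discrimination oddity task, 4
#'   for identification).
#' @param n_trials number of trials.
#' @param target optional integer vector of target positions (recycled);
#'   when `NULL`, targets are drawn uniformly.
#' @param seed optional seed.
#' @return data.frame with columns `target`, `choice`, `correct`,
#'   `conf_margin`, `confidence`, and the evidence matrix in columns
#'   `ev.1 ... ev.m`.
#' @export
simulate_individual_trials <- function(params, m, n_trials = 1L,
                                       target = NULL, seed = NULL) {
  if (!inherits(params, "observer_params")) stop_olf("params must be observer_params")
  if (!m %in% c(2L, 3L, 4L)) stop_olf("m must be 2, 3 or 4")
  with_seed(seed, {
    tgt <- if (is.null(target)) sample.int(m, n_trials, replace = TRUE)
           else rep_len(as.integer(target), n_trials)
    ev <- matrix(stats::rnorm(n_trials * m), n_trials, m)
    ev[cbind(seq_len(n_trials), tgt)] <- ev[cbind(seq_len(n_trials), tgt)] + params$ability
    choice <- max.col(ev, ties.method = "first")
    sorted_top2 <- t(apply(ev, 1, function(r) sort(r, decreasing = TRUE)[1:2]))
    margin <- sorted_top2[, 1] - sorted_top2[, 2] +
      stats::rnorm(n_trials, 0, params$meta_noise)
    edges <- params$conf_bin_edges %||% conf_bin_edges(m, params$n_conf_levels)
    confidence <- findInterval(margin, edges) + 1L
    out <- data.frame(target = tgt, choice = choice,
                      correct = choice == tgt,
                      conf_margin = margin, confidence = confidence)
    ev_df <- as.data.frame(ev)
    names(ev_df) <- paste0("ev.", seq_len(m))
    cbind(out, ev_df)
  })
}

#' Combine two members' decisions into a joint decision
#'
#' When the two choices agree the joint choice is the common one. On
#' disagreement the rule decides: `coin_flip_voting` picks either choice
#' with probability 1/2; `defer_to_higher_confidence` takes the choice of
#' the member with the higher ordinal confidence (a fair coin on ties);
#' `evidence_sum` takes the argmax of the elementwise sum of the two
#' members' evidence vectors (an ideal pooling benchmark that real dyads
#' cannot implement verbally).
#'
#' @param trial_a,trial_b aligned trial data.frames from
#'   [simulate_individual_trials()] for the same task and targets.
#' @param rule one of `"coin_flip_voting"`, `"defer_to_higher_confidence"`,
#'   `"evidence_sum"`.
#' @param seed optional seed for the coin flips.
#' @return data.frame with `joint_choice`, `joint_correct`, `conflict`.
#' @export
combine_dyad_decision <- function(trial_a, trial_b,
                                  rule = c("defer_to_higher_confidence",
                                           "coin_flip_voting", "evidence_sum"),
                                  seed = NULL) {
  rule <- match.arg(rule)
  n <- nrow(trial_a)
  if (nrow(trial_b) != n || !identical(trial_a$target, trial_b$target)) {
    stop_olf("trials are not aligned on the same task and targets",
             class = "olfdyad_alignment_error")
  }
  ev_cols_a <- grep("^ev\\.", names(trial_a), value = TRUE)
  ev_cols_b <- grep("^ev\\.", names(trial_b), value = TRUE)
  if (length(ev_cols_a) != length(ev_cols_b)) {
    stop_olf("mismatched number of alternatives", class = "olfdyad_alignment_error")
  }
  with_seed(seed, {
    agree <- trial_a$choice == trial_b$choice
    joint <- trial_a$choice
    dis <- which(!agree)
    if (length(dis)) {
      joint[dis] <- switch(rule,
        coin_flip_voting = {
          pick_a <- stats::runif(length(dis)) < 0.5
          ifelse(pick_a, trial_a$choice[dis], trial_b$choice[dis])
        },
        defer_to_higher_confidence = {
          ca <- trial_a$confidence[dis]
          cb <- trial_b$confidence[dis]
          tie <- ca == cb
          pick_a <- ca > cb
          pick_a[tie] <- stats::runif(sum(tie)) < 0.5
          ifelse(pick_a, trial_a$choice[dis], trial_b$choice[dis])
        },
        evidence_sum = {
          pooled <- as.matrix(trial_a[dis, ev_cols_a, drop = FALSE]) +
            as.matrix(trial_b[dis, ev_cols_b, drop = FALSE])
          max.col(pooled, ties.method = "first")
        }
      )
    }
    data.frame(joint_choice = joint,
               joint_correct = joint == trial_a$target,
               conflict = !agree)
  })
}

#' Closed-form weighted-confidence-sharing benchmark (2AFC)
#'
#' Under the weighted confidence sharing model of joint two-alternative
#' perceptual decisions, a dyad whose members have sensitivities `s_low`
#' and `s_high` achieves joint sensitivity (s_low + s_high) / sqrt(2). The
#' collective benefit relative to the better member is
#' (1 + s_low/s_high) / sqrt(2), which exceeds 1 exactly when the
#' sensitivity ratio exceeds sqrt(2) - 1.
#'
#' @param s_low,s_high member sensitivities (d-prime scale), both > 0,
#'   `s_low <= s_high`.
#' @return list with `s_dyad` and `cb`.
#' @export
#' @examples
#' wcs_oracle(1, 1)$cb # sqrt(2)
wcs_oracle <- function(s_low, s_high) {
  if (any(s_low <= 0) || any(s_high <= 0)) {
    stop_olf("sensitivities must be positive", class = "olfdyad_domain_error")
  }
  if (any(s_low > s_high)) stop_olf("s_low must not exceed s_high")
  list(s_dyad = (s_low + s_high) / sqrt(2),
       cb = (1 + s_low / s_high) / sqrt(2))
}

.rule_labels <- c("coin_flip_voting", "defer_to_higher_confidence", "evidence_sum")

#' Simulate dyads across the full range of ability similarity
#'
#' Benchmark design for studying how collective benefit depends on ability
#' similarity: each dyad pairs a fixed-ability member (`s_high`) with a
#' partner whose ability is a uniform random fraction of it, runs one
#' session under the chosen rule, and records the score-based similarity
#' ratio and collective benefit.
#'
#' @param n_dyads number of dyads to simulate.
#' @param s_high ability of the better member (default 2).
#' @param rule aggregation rule (see [combine_dyad_decision()]).
#' @param n_trials trials per session (default 16).
#' @param task task type.
#' @param meta_noise metacognitive noise of both members.
#' @param ratio_range range the latent ability ratio is drawn from.
#' @param seed optional seed.
#' @return data.frame with one row per dyad: `ability_ratio`, `s_a`, `s_b`,
#'   `s_dyad`, `ratio` (score-based similarity), `cb`.
#' @export
simulate_similarity_sweep <- function(n_dyads, s_high = 2,
                                      rule = "defer_to_higher_confidence",
                                      n_trials = 16L,
                                      task = "discrimination",
                                      meta_noise = 0.5,
                                      ratio_range = c(0.05, 1),
                                      seed = NULL) {
  with_seed(seed, {
    r <- stats::runif(n_dyads, ratio_range[1], ratio_range[2])
    rows <- lapply(seq_len(n_dyads), function(i) {
      pa <- observer_params(s_high, meta_noise)
      pb <- observer_params(s_high * r[i], meta_noise)
      tab <- simulate_session(pa, pb, rule, n_trials, task)
      sa <- sum(tab$correct_a); sb <- sum(tab$correct_b)
      data.frame(ability_ratio = r[i], s_a = sa, s_b = sb,
                 s_dyad = sum(tab$joint_correct),
                 ratio = min(sa, sb) / max(sa, sb),
                 cb = sum(tab$joint_correct) / max(sa, sb))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# choice labels written to trial tables: pen positions for the 3AFC oddity
# task, option letters for the 4AFC identification card
choice_label <- function(choice, task) {
  if (task == "discrimination") as.character(choice)
  else c("optA", "optB", "optC", "optD")[choice]
}

#' Simulate one dyadic testing session
#'
#' Generates a block of trials for one dyad on one task: both members'
#' private answers and confidences from the observer model, the joint
#' answer under the chosen aggregation rule, correctness and conflict
#' flags. Output rows follow the day-2 trial-table schema (answers stored
#' as pen positions `"1".."3"` for discrimination and option labels
#' `"optA".."optD"` for identification).
#'
#' @param params_a,params_b [observer_params()] for the two members.
#' @param rule aggregation rule, see [combine_dyad_decision()].
#' @param n_trials trials in the block (default 16, one per pen/triplet).
#' @param task `"discrimination"` (3AFC) or `"identification"` (4AFC).
#' @param seed optional seed; a fixed seed makes the table reproducible.
#' @param dyad_id,subject_a,subject_b identifiers copied into the table.
#' @return a day-2 trial table (data.frame); see [read_trial_table()].
#' @export
simulate_session <- function(params_a, params_b,
                             rule = "defer_to_higher_confidence",
                             n_trials = 16L,
                             task = c("discrimination", "identification"),
                             seed = NULL, dyad_id = "dyad01",
                             subject_a = "a", subject_b = "b") {
  task <- match.arg(task)
  if (n_trials < 1) stop_olf("n_trials must be at least 1")
  m <- if (task == "discrimination") 3L else 4L
  with_seed(seed, {
    tgt <- sample.int(m, n_trials, replace = TRUE)
    ta <- simulate_individual_trials(params_a, m, n_trials, target = tgt)
    tb <- simulate_individual_trials(params_b, m, n_trials, target = tgt)
    joint <- combine_dyad_decision(ta, tb, rule)
    data.frame(
      study_day = 2L,
      dyad_id = dyad_id,
      subject_a = subject_a,
      subject_b = subject_b,
      task = task,
      trial_index = seq_len(n_trials),
      correct_answer = choice_label(tgt, task),
      answer_a = choice_label(ta$choice, task),
      answer_b = choice_label(tb$choice, task),
      correct_a = ta$correct,
      correct_b = tb$correct,
      confidence_a = ta$confidence,
      confidence_b = tb$confidence,
      joint_answer = choice_label(joint$joint_choice, task),
      joint_correct = joint$joint_correct,
      conflict = joint$conflict
    )
  })
}
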