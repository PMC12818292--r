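# Statistical stage: estimate tables, clustered models, paired tests,
# BIC Bayes factors and the full report.

est_table <- function(term, estimate, se, statistic, df, p, ci_low, ci_high,
                      exponentiate = FALSE) {
  out <- data.frame(term = term, estimate = estimate, se = se,
                    statistic = statistic, df = df, p = p,
                    ci_low = ci_low, ci_high = ci_high,
                    exponentiated = if (exponentiate) exp(estimate) else NA_real_)
  rownames(out) <- NULL
  class(out) <- c("olf_estimates", "data.frame")
  out
}

est_from_merMod <- function(fit, exponentiate = TRUE) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  out <- est_table(names(b), unname(b), unname(se), unname(z), NA_real_,
                   2 * stats::pnorm(-abs(z)),
                   unname(b - stats::qnorm(0.975) * se),
                   unname(b + stats::qnorm(0.975) * se),
                   exponentiate = exponentiate)
  attr(out, "model") <- fit
  out
}

est_from_lm <- function(fit) {
  sm <- stats::summary.lm(fit)$coefficients
  ci <- stats::confint(fit)
  out <- est_table(rownames(sm), sm[, 1], sm[, 2], sm[, 3],
                   stats::df.residual(fit), sm[, 4], ci[, 1], ci[, 2])
  attr(out, "model") <- fit
  out
}

#' Proportion correct at each confidence level
#'
#' The standard descriptive check of metacognitive sensitivity: for each
#' observer, the proportion of correct responses at each occupied level of
#' the confidence scale, plus the across-observer aggregate per level.
#'
#' @param trials data.frame with columns `subject_id`, `confidence`
#'   (ordinal) and `correct` (logical or 0/1).
#' @return list with `per_subject` (subject_id, confidence, n, prop_correct)
#'   and `aggregate` (confidence, n_subjects, mean_prop, se).
#' @export
accuracy_by_confidence <- function(trials) {
  req <- c("subject_id", "confidence", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop_olf("missing columns: ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  agg <- stats::aggregate(correct ~ subject_id + confidence, data = trials,
                          FUN = function(x) c(n = length(x), p = mean(x)))
  per_subject <- data.frame(subject_id = agg$subject_id,
                            confidence = agg$confidence,
                            n = agg$correct[, "n"],
                            prop_correct = agg$correct[, "p"])
  per_subject <- per_subject[order(per_subject$subject_id, per_subject$confidence), ]
  rownames(per_subject) <- NULL
  lv <- sort(unique(per_subject$confidence))
  aggregate_tab <- do.call(rbind, lapply(lv, function(l) {
    p <- per_subject$prop_correct[per_subject$confidence == l]
    data.frame(confidence = l, n_subjects = length(p), mean_prop = mean(p),
               se = if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else NA_real_)
  }))
  list(per_subject = per_subject, aggregate = aggregate_tab)
}

# crude complete-separation heuristic on a fitted binomial model
looks_separated <- function(b, se) {
  any(!is.finite(b)) || any(!is.finite(se)) || max(abs(b)) > 10 || max(se) > 25
}

#' Clustered (mixed-effects) logistic regression
#'
#' Fits a logistic regression of a binary outcome on the fixed effects in
#' `formula`, with a random intercept for `cluster` (dyad or subject,
#' depending on the design). Estimates are reported with Wald 95% CIs and
#' odds ratios. When the fit shows signs of complete separation the
#' function warns and refits the fixed effects with a small ridge penalty
#' (no standard errors are available for the penalized estimates).
#'
#' @param formula fixed-effects formula, e.g. `correct ~ confidence`.
#' @param data data.frame containing the outcome, predictors and cluster id.
#' @param cluster name of the cluster id column.
#' @return an `olf_estimates` data.frame (term, estimate, se, statistic, p,
#'   ci_low, ci_high, exponentiated = odds ratio), with the fitted model in
#'   `attr(, "model")` and `attr(, "separation")` set if penalized.
#' @export
fit_binary_clustered <- function(formula, data, cluster) {
  if (!cluster %in% names(data)) {
    stop_olf("cluster column not found: ", cluster, class = "olfdyad_schema_error")
  }
  if (length(unique(data[[cluster]])) < 2) {
    stop_olf("need at least 2 clusters")
  }
  y <- stats::model.frame(formula, data)[[1]]
  if (!all(y %in% c(0, 1, TRUE, FALSE))) {
    stop_olf("outcome must be binary", class = "olfdyad_schema_error")
  }
  full <- stats::update.formula(formula,
    stats::as.formula(paste(". ~ . + (1 |", cluster, ")")))
  fit <- suppressMessages(lme4::glmer(full, data = data, family = stats::binomial()))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (looks_separated(b, se)) {
    warning("possible complete separation; refitting fixed effects with a ridge penalty",
            call. = FALSE)
    out <- ridge_logistic(formula, data)
    attr(out, "separation") <- TRUE
    return(out)
  }
  est_from_merMod(fit, exponentiate = TRUE)
}

# ridge-penalized logistic fallback for separated data (point estimates only)
ridge_logistic <- function(formula, data, lambda = 0.05) {
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(mf[[1]])
  x <- stats::model.matrix(formula, data)
  if (ncol(x) >= 3) {
    fit <- glmnet::glmnet(x[, -1, drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = lambda)
    b <- c(fit$a0, as.numeric(fit$beta))
    terms <- c("(Intercept)", rownames(fit$beta))
  } else if (ncol(x) == 2) {
    # glmnet needs >= 2 predictors; duplicate the single column and sum back
    xx <- cbind(x[, 2], x[, 2])
    fit <- glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                          lambda = lambda)
    b <- c(fit$a0, sum(as.numeric(fit$beta)))
    terms <- colnames(x)
  } else {
    # intercept only: shrunk empirical log-odds
    b <- stats::qlogis((sum(y) + 0.5) / (length(y) + 1))
    terms <- "(Intercept)"
  }
  est_table(terms, unname(b), NA_real_, NA_real_, NA_real_, NA_real_,
            NA_real_, NA_real_, exponentiate = TRUE)
}

#' Clustered (mixed-effects) Poisson regression
#'
#' Log-link Poisson regression of a non-negative integer count on the fixed
#' effects in `formula` with a random intercept for `cluster`. The
#' `exponentiated` column holds rate ratios.
#'
#' @inheritParams fit_binary_clustered
#' @return an `olf_estimates` data.frame with the fitted model attached.
#' @export
fit_count_clustered <- function(formula, data, cluster) {
  if (!cluster %in% names(data)) {
    stop_olf("cluster column not found: ", cluster, class = "olfdyad_schema_error")
  }
  y <- stats::model.frame(formula, data)[[1]]
  if (any(y < 0) || any(y != round(y))) {
    stop_olf("outcome must be non-negative integer counts",
             class = "olfdyad_schema_error")
  }
  if (all(y == 0)) {
    stop_olf("degenerate fit: all counts are zero", class = "olfdyad_degenerate_fit")
  }
  full <- stats::update.formula(formula,
    stats::as.formula(paste(". ~ . + (1 |", cluster, ")")))
  fit <- suppressMessages(lme4::glmer(full, data = data, family = stats::poisson()))
  est_from_merMod(fit, exponentiate = TRUE)
}

#' Ordinary least-squares regression with an estimate table
#'
#' Thin wrapper around `lm()` returning the package's standard estimate
#' table (two-sided t tests, 95% CIs, residual df).
#'
#' @param formula model formula.
#' @param data data.frame.
#' @return an `olf_estimates` data.frame with the `lm` fit attached.
#' @export
fit_linear <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) <= length(attr(stats::terms(formula, data = data), "term.labels")) + 1) {
    stop_olf("not enough observations for the number of terms")
  }
  fit <- stats::lm(formula, data)
  if (any(is.na(stats::coef(fit)))) {
    stop_olf("rank-deficient design (aliased terms)",
             class = "olfdyad_singularity_error")
  }
  est_from_lm(fit)
}

# Gaussian mixed model (random intercept) with Satterthwaite t tests
fit_gaussian_clustered <- function(formula, data, cluster) {
  full <- stats::update.formula(formula,
    stats::as.formula(paste(". ~ . + (1 |", cluster, ")")))
  fit <- suppressMessages(lmerTest::lmer(full, data = data))
  sm <- stats::coef(summary(fit))
  ci <- sm[, "Estimate"] + stats::qnorm(c(0.025)) * sm[, "Std. Error"]
  out <- est_table(rownames(sm), sm[, "Estimate"], sm[, "Std. Error"],
                   sm[, "t value"], sm[, "df"], sm[, "Pr(>|t|)"],
                   sm[, "Estimate"] - stats::qnorm(0.975) * sm[, "Std. Error"],
                   sm[, "Estimate"] + stats::qnorm(0.975) * sm[, "Std. Error"])
  attr(out, "model") <- fit
  out
}

#' BIC-approximated Bayes factor for nested models
#'
#' Compares two models of the same data by the Schwarz approximation:
#' `BF01 = exp((BIC_complex - BIC_simple) / 2)`, the Bayes factor in favor
#' of the simpler model. Values above 1 favor the simple model.
#'
#' @param model_simple,model_complex fitted model objects supporting
#'   `BIC()` and `nobs()`, fitted to the same rows.
#' @return list of class `model_comparison` with `bic_simple`,
#'   `bic_complex`, `bf01`.
#' @export
bayes_factor_bic <- function(model_simple, model_complex) {
  if (stats::nobs(model_simple) != stats::nobs(model_complex)) {
    stop_olf("models were fitted to different data rows",
             class = "olfdyad_alignment_error")
  }
  bs <- stats::BIC(model_simple)
  bc <- stats::BIC(model_complex)
  structure(list(bic_simple = bs, bic_complex = bc,
                 bf01 = exp((bc - bs) / 2)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("BIC simple = %.2f, BIC complex = %.2f, BF01 = %.3g %s\n",
              x$bic_simple, x$bic_complex, x$bf01,
              if (x$bf01 > 1) "(favors the simple model)" else "(favors the complex model)"))
  invisible(x)
}

#' Reshape a dyadic trial table to one row per member response
#'
#' @param trials day-2 trial table.
#' @return data.frame with columns `subject_id`, `dyad_id`, `task`,
#'   `trial_index`, `answer`, `correct`, `confidence`, `member`.
#' @export
pivot_members <- function(trials) {
  base <- trials[c("dyad_id", "task", "trial_index")]
  a <- cbind(base, data.frame(subject_id = trials$subject_a,
                              answer = trials$answer_a,
                              correct = trials$correct_a,
                              confidence = trials$confidence_a,
                              member = "member_1"))
  b <- cbind(base, data.frame(subject_id = trials$subject_b,
                              answer = trials$answer_b,
                              correct = trials$correct_b,
                              confidence = trials$confidence_b,
                              member = "member_2"))
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}

holm_label <- function(p) {
  adj <- stats::p.adjust(p, method = "holm")
  list(p_corrected = adj,
       label = sprintf("p = %.3g [corrected]", adj))
}

#' Run the full analysis sequence on a study dataset
#'
#' Orchestrates every model of the analysis pipeline on a dataset of the
#' form produced by [generate_study_dataset()] (or read from disk): a day-2
#' trial table with word/lexicon counts and a score table with day-1
#' subtest scores, age and gender. Sections, in order: demographics,
#' metacognition (accuracy-confidence), dyad vs best and dyad vs average
#' paired tests, similarity-benefit regressions (day-1 and day-2 bases, per
#' task), similarity-conflict-count and similarity-resolution regressions,
#' trial-level word-count model, words-resolution logistic models (with
#' Holm-corrected per-task contrasts), word-use component model,
#' talkative-wins model, confidence-lexicon Poisson model, and the BIC
#' Bayes-factor comparison of the resolution models with and without the
#' task-by-lexicon interaction.
#'
#' @param dataset list with elements `trials` (day-2 trial table including
#'   `words_a`, `words_b`, `lexicon_count`) and `scores` (score table with
#'   day-1 rows carrying `age` and `gender`).
#' @return an object of class `olf_report`: a named list of sections.
#' @export
run_full_analysis <- function(dataset) {
  for (nm in c("trials", "scores")) {
    if (is.null(dataset[[nm]])) {
      stop_olf("missing input table: ", nm, class = "olfdyad_missing_input")
    }
  }
  trials <- dataset$trials
  scores <- dataset$scores
  day1 <- scores[scores$day == 1, ]
  report <- list()

  # 1. demographics: per-subtest OLS on day-1 scores
  if (all(c("age", "gender") %in% names(day1))) {
    report$demographics <- list(
      threshold = fit_linear(t_score ~ age + gender, day1),
      discrimination = fit_linear(d_score ~ age + gender, day1),
      identification = fit_linear(i_score ~ age + gender, day1)
    )
  } else {
    report$demographics <- "age/gender not available"
  }

  # 2. metacognition: confidence -> accuracy, clustered by subject
  long <- pivot_members(trials)
  report$metacognition <- lapply(split(long, long$task), function(d) {
    list(profile = accuracy_by_confidence(d),
         model = fit_binary_clustered(correct ~ confidence, d, "subject_id"))
  })

  # 3-4. dyad vs best / dyad vs average paired tests, per task
  dstats <- dyad_score_table(trials, day1_scores = day1)
  report$dyad_stats <- dstats
  report$baselines <- lapply(split(dstats, dstats$task), function(d) {
    compare_dyad_baselines(d$s_dyad, d$s_max, d$s_mean)
  })

  # 5. similarity -> collective benefit (both day bases)
  report$similarity_benefit <- lapply(split(dstats, dstats$task), function(d) {
    list(day1 = fit_linear(cb ~ ratio_day1, d),
         day2 = fit_linear(cb ~ ratio_day2, d))
  })

  # 6-7. similarity -> conflict counts and resolution rate
  key <- interaction(trials$dyad_id, trials$task, drop = TRUE)
  conf <- do.call(rbind, lapply(split(trials, key), function(tr) {
    cbind(dyad_id = tr$dyad_id[1], task = tr$task[1], summarize_conflicts(tr))
  }))
  rownames(conf) <- NULL
  report$conflict_summaries <- conf
  cstats <- merge(dstats, conf, by = c("dyad_id", "task"))
  report$similarity_conflicts <- lapply(split(cstats, cstats$task), function(d) {
    fit_linear(n_conflicts ~ ratio_day1, d)
  })
  report$similarity_resolution <- lapply(split(cstats, cstats$task), function(d) {
    fit_linear(resolution_rate ~ ratio_day1, d[!is.na(d$resolution_rate), ])
  })

  # 8. trial-level word-count model (Gaussian mixed, dyad intercept)
  trials$words_total <- trials$words_a + trials$words_b
  report$word_count_model <- fit_gaussian_clustered(
    words_total ~ conflict + task, trials, "dyad_id")

  # 9. words -> conflict resolution (resolvable conflicts only)
  resolv <- trials[resolve_conflict_outcome(trials) %in% c("success", "failure"), ]
  report$words_resolution <- list(
    overall = fit_binary_clustered(joint_correct ~ words_total, resolv, "dyad_id")
  )
  per_task <- lapply(split(resolv, resolv$task), function(d) {
    fit_binary_clustered(joint_correct ~ words_total, d, "dyad_id")
  })
  slope_p <- vapply(per_task, function(e) e$p[e$term == "words_total"], numeric(1))
  corr <- holm_label(slope_p)
  for (i in seq_along(per_task)) {
    per_task[[i]]$p_corrected <- ifelse(per_task[[i]]$term == "words_total",
                                        corr$p_corrected[i], NA_real_)
    attr(per_task[[i]], "correction") <- "holm [corrected]"
  }
  report$words_resolution$per_task <- per_task

  # 10. word-use components on identification conflicts
  ident_conf <- resolv[resolv$task == "identification", ]
  if (nrow(ident_conf) > 10) {
    comp <- word_use_components(ident_conf)
    comp_dat <- cbind(ident_conf, comp[c("within_dev", "between", "imbalance")])
    report$word_components_model <- fit_binary_clustered(
      joint_correct ~ within_dev + between + imbalance, comp_dat, "dyad_id")
  }

  # 11. talkative-wins (identification conflicts, decided trials)
  tw <- trials[trials$conflict & trials$task == "identification", ]
  outc <- suppressWarnings(talkative_outcome(tw$words_a, tw$words_b,
                                             tw$answer_a, tw$answer_b,
                                             tw$joint_answer))
  tw <- tw[outc != "tie_or_excluded", ]
  tw$more_won <- outc[outc != "tie_or_excluded"] == "more_talkative_won"
  report$talkative_wins <- fit_binary_clustered(more_won ~ 1, tw, "dyad_id")
  b0 <- report$talkative_wins$estimate[1]
  report$talkative_wins_probability <- 100 * stats::plogis(b0)

  # 12. confidence-lexicon Poisson model (conflict x task)
  report$lexicon_model <- fit_count_clustered(
    lexicon_count ~ conflict * task, trials, "dyad_id")

  # 13. lexicon -> resolution logistic models and BF comparison
  simple <- fit_binary_clustered(joint_correct ~ lexicon_count, resolv, "dyad_id")
  complex <- fit_binary_clustered(joint_correct ~ lexicon_count * task, resolv, "dyad_id")
  report$lexicon_resolution <- list(simple = simple, complex = complex)
  report$bf_comparison <- bayes_factor_bic(attr(simple, "model"),
                                           attr(complex, "model"))

  class(report) <- "olf_report"
  report
}

#' @export
print.olf_report <- function(x, digits = 3, ...) {
  cat("== Dyadic olfactory decision-making analysis report ==\n\n")
  fmt_est <- function(e, indent = "  ") {
    for (i in seq_len(nrow(e))) {
      cat(indent, sprintf("%-22s B = %7.3f  SE = %6.3f  stat = %7.2f  p = %.3g",
                          e$term[i], e$estimate[i], e$se[i], e$statistic[i],
                          e$p[i]))
      if (!is.na(e$exponentiated[i])) cat(sprintf("  exp(B) = %.3f", e$exponentiated[i]))
      cat("\n")
    }
  }
  if (is.list(x$demographics)) {
    cat("-- Demographics (day-1 OLS) --\n")
    for (nm in names(x$demographics)) {
      cat(" ", nm, ":\n"); fmt_est(x$demographics[[nm]], "    ")
    }
  }
  cat("\n-- Metacognition (confidence -> accuracy, subject-clustered logistic) --\n")
  for (nm in names(x$metacognition)) {
    cat(" ", nm, ":\n"); fmt_est(x$metacognition[[nm]]$model, "    ")
  }
  cat("\n-- Dyads vs individual baselines (paired t) --\n")
  for (nm in names(x$baselines)) {
    b <- x$baselines[[nm]]
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %s / %s: mean diff = %.3f, t(%d) = %.2f, p = %.3g, 95%% CI [%.2f, %.2f]\n",
                  nm, b$comparison[i], b$mean_diff[i], b$df[i], b$t[i], b$p[i],
                  b$ci_low[i], b$ci_high[i]))
    }
  }
  cat("\n-- Similarity ratio -> collective benefit (OLS) --\n")
  for (nm in names(x$similarity_benefit)) {
    for (basis in c("day1", "day2")) {
      e <- x$similarity_benefit[[nm]][[basis]]
      i <- 2
      cat(sprintf("  %s (%s basis): B = %.3f, SE = %.3f, t(%d) = %.2f, p = %.3g\n",
                  nm, basis, e$estimate[i], e$se[i], e$df[i], e$statistic[i], e$p[i]))
    }
  }
  cat("\n-- Similarity -> conflicts / resolution (OLS) --\n")
  for (nm in names(x$similarity_conflicts)) {
    e <- x$similarity_conflicts[[nm]]
    cat(sprintf("  %s conflicts:  B = %.3f, p = %.3g\n", nm, e$estimate[2], e$p[2]))
    e2 <- x$similarity_resolution[[nm]]
    cat(sprintf("  %s resolution: B = %.3f, p = %.3g\n", nm, e2$estimate[2], e2$p[2]))
  }
  cat("\n-- Word counts (Gaussian mixed model) --\n")
  fmt_est(x$word_count_model)
  cat("\n-- Words -> conflict resolution (logistic, dyad-clustered) --\n")
  fmt_est(x$words_resolution$overall)
  for (nm in names(x$words_resolution$per_task)) {
    e <- x$words_resolution$per_task[[nm]]
    i <- which(e$term == "words_total")
    cat(sprintf("  %s: OR = %.3f, p = %.3g [corrected]\n",
                nm, e$exponentiated[i], e$p_corrected[i]))
  }
  if (!is.null(x$word_components_model)) {
    cat("\n-- Word-use components (identification conflicts) --\n")
    fmt_est(x$word_components_model)
  }
  cat("\n-- Talkative-wins --\n")
  fmt_est(x$talkative_wins)
  cat(sprintf("  P(more talkative member wins) = %.1f%%\n",
              x$talkative_wins_probability))
  cat("\n-- Confidence lexicon (Poisson mixed model) --\n")
  fmt_est(x$lexicon_model)
  cat("\n-- Lexicon -> resolution model comparison --\n")
  print(x$bf_comparison)
  invisible(x)
}
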