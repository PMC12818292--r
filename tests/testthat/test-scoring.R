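test_that("similarity ratio is S_min/S_max, symmetric, and guards zero", {
  cases <- list(list(12, 12, 1.0), list(8, 16, 0.5), list(16, 4, 0.25),
                list(4, 16, 0.25))
  for (cs in cases) {
    expect_equal(similarity_ratio(cs[[1]], cs[[2]])$ratio, cs[[3]])
    expect_equal(similarity_ratio(cs[[2]], cs[[1]])$ratio, cs[[3]])
  }
  r <- similarity_ratio(c(8, 16), c(16, 4))
  expect_equal(r$ratio, c(0.5, 0.25))
  expect_true(all(r$s_min <= r$s_max))
  expect_error(similarity_ratio(0, 0), class = "olfdyad_undefined_ratio")
  expect_error(similarity_ratio(NA, 3), class = "olfdyad_missing_data")
})

test_that("collective benefit is dyad score over best member, order-invariant", {
  expect_equal(collective_benefit(12, 12, 12)$cb, 1.0)
  expect_equal(collective_benefit(14, 12, 10)$cb, 14 / 12, tolerance = 1e-12)
  expect_equal(collective_benefit(10, 12, 8)$cb, 10 / 12, tolerance = 1e-12)
  expect_equal(collective_benefit(14, 10, 12)$cb, collective_benefit(14, 12, 10)$cb)
  expect_error(collective_benefit(5, 0, 0), class = "olfdyad_undefined_ratio")
})

test_that("conflict classification is exact label inequality", {
  expect_false(classify_conflict(2, 2))
  expect_true(classify_conflict(2, 3))
  expect_true(classify_conflict("lemon", "peach"))
  expect_equal(classify_conflict(c("a", "b"), c("a", "c")), c(FALSE, TRUE))
  expect_error(classify_conflict(NA, "a"), class = "olfdyad_missing_data")
})

test_that("conflict outcomes partition trials correctly", {
  tr <- make_trials()
  out <- resolve_conflict_outcome(tr)
  expect_equal(out, c("not_conflict", "success", "failure",
                      "excluded_both_wrong", "not_conflict"))
  tr_bad <- tr
  tr_bad$joint_answer[2] <- NA
  expect_error(resolve_conflict_outcome(tr_bad), class = "olfdyad_missing_data")
})

test_that("conflict summaries compute counts, percentage and resolution rate", {
  tr <- make_trials()
  s <- summarize_conflicts(tr)
  expect_equal(s$n_trials, 5)
  expect_equal(s$n_conflicts, 3)
  expect_equal(s$pct_conflicts, 60)
  expect_equal(s$n_resolvable, 2)
  expect_equal(s$n_resolved, 1)
  expect_equal(s$resolution_rate, 0.5)
  # counting identity: conflicts = resolvable + both-wrong conflicts
  both_wrong <- sum(resolve_conflict_outcome(tr) == "excluded_both_wrong")
  expect_equal(s$n_conflicts, s$n_resolvable + both_wrong)

  # 16 trials with exactly 5 conflicts -> 31.25%
  tr16 <- tr[c(2, 3, 4, 2, 3, rep(1, 11)), ]
  tr16$trial_index <- 1:16
  s16 <- summarize_conflicts(tr16)
  expect_equal(s16$n_conflicts, 5)
  expect_equal(s16$pct_conflicts, 31.25)

  # degenerate: no conflicts
  agree <- tr[tr$answer_a == tr$answer_b, ]
  s0 <- summarize_conflicts(agree)
  expect_equal(s0$pct_conflicts, 0)
  expect_true(is.na(s0$resolution_rate))

  expect_error(summarize_conflicts(tr[0, ]), class = "olfdyad_empty_input")
})

test_that("quartile matching pairs mid with mid and top with bottom", {
  scores <- data.frame(subject_id = sprintf("S%02d", 1:8), di_sum = 1:8)
  pairing <- match_dyads(scores, seed = 1)
  expect_equal(nrow(pairing), 4)
  hi <- pairing[pairing$similarity_group == "high_similarity", ]
  lo <- pairing[pairing$similarity_group == "low_similarity", ]
  mids <- sprintf("S%02d", 3:6)
  expect_setequal(c(hi$member_1, hi$member_2), mids)
  expect_setequal(c(lo$member_1, lo$member_2), sprintf("S%02d", c(1, 2, 7, 8)))
  # in low-similarity dyads, one member from the top and one from the bottom
  for (i in seq_len(nrow(lo))) {
    ms <- c(lo$member_1[i], lo$member_2[i])
    expect_length(intersect(ms, sprintf("S%02d", 7:8)), 1)
    expect_length(intersect(ms, sprintf("S%02d", 1:2)), 1)
  }
  # determinism
  expect_identical(pairing, match_dyads(scores, seed = 1))
  expect_false(identical(pairing, match_dyads(scores, seed = 2)))
})

test_that("matching handles ties, odd cohorts and tiny cohorts", {
  same <- data.frame(subject_id = sprintf("S%02d", 1:8), di_sum = rep(10, 8))
  pairing <- match_dyads(same, seed = 3)
  expect_equal(nrow(pairing), 4)
  expect_error(match_dyads(same[1:3, ], seed = 1),
               class = "olfdyad_insufficient_cohort")
  # odd leftover dropped with a warning; every returned subject in one dyad
  odd <- data.frame(subject_id = sprintf("S%02d", 1:53),
                    di_sum = rep(1:27, length.out = 53))
  expect_warning(p53 <- match_dyads(odd, seed = 4), "dropping unpaired")
  members <- c(p53$member_1, p53$member_2)
  expect_equal(anyDuplicated(members), 0)
  expect_true(all(members %in% odd$subject_id))
  # high-similarity dyads drawn only from the middle quartiles
  ranked <- odd[order(odd$di_sum, odd$subject_id), ]
  mids <- ranked$subject_id[(ceiling(53 / 4) + 1):floor(3 * 53 / 4)]
  hi <- p53[p53$similarity_group == "high_similarity", ]
  expect_true(all(c(hi$member_1, hi$member_2) %in% mids))
})

test_that("baseline comparisons return paired t results with n-1 df", {
  set.seed(11)
  dyad <- rnorm(20, 13)
  best <- dyad + rnorm(20, 0.5)
  avg <- dyad - rnorm(20, 0.8)
  res <- compare_dyad_baselines(dyad, best, avg)
  expect_equal(res$comparison, c("dyad_vs_best", "dyad_vs_average"))
  expect_equal(res$df, c(19, 19))
  ref <- t.test(dyad, best, paired = TRUE)
  expect_equal(res$t[1], unname(ref$statistic))
  expect_equal(res$p[1], ref$p.value)
  # identity case: zero difference, t = 0
  same <- compare_dyad_baselines(dyad, dyad, avg)
  expect_equal(same$t[1], 0)
  expect_equal(same$mean_diff[1], 0)
  expect_error(compare_dyad_baselines(dyad, best[1:10], avg),
               class = "olfdyad_alignment_error")
})

test_that("dyad score table aggregates scores, ratios and benefit", {
  tr <- rbind(make_trials("dyad01"), make_trials("dyad02"))
  tr$answer_b[8] <- tr$correct_answer[8]
  tr$correct_b <- tr$answer_b == tr$correct_answer
  tr$conflict <- tr$answer_a != tr$answer_b
  d1 <- data.frame(subject_id = c("S01", "S02"), d_score = c(12, 6),
                   i_score = c(10, 10))
  out <- dyad_score_table(tr, d1)
  expect_equal(nrow(out), 2)
  expect_equal(out$s_a, tapply(tr$correct_a, tr$dyad_id, sum)[out$dyad_id],
               ignore_attr = TRUE)
  expect_equal(out$cb, out$s_dyad / pmax(out$s_a, out$s_b))
  expect_equal(out$ratio_day1, rep(0.5, 2)) # 6/12 on the discrimination basis
})
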