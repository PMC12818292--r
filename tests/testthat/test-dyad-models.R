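test_that("observer parameters are validated", {
  expect_error(observer_params(-1))
  expect_error(observer_params(1, meta_noise = -0.1))
  expect_error(observer_params(1, n_conf_levels = 1))
  expect_error(observer_params(1, conf_bin_edges = c(2, 1, 3)))
})

test_that("zero-ability observers perform at chance", {
  p <- observer_params(0)
  n <- 6000
  acc4 <- mean(simulate_individual_trials(p, 4, n, seed = 1)$correct)
  acc3 <- mean(simulate_individual_trials(p, 3, n, seed = 2)$correct)
  expect_lt(abs(acc4 - 0.25), 3 * mc_se(0.25, n))
  expect_lt(abs(acc3 - 1 / 3), 3 * mc_se(1 / 3, n))
})

test_that("simulated accuracy matches the quadrature oracle", {
  # oracle computed independently of the simulator
  oracle <- integrate(function(e) dnorm(e - 2) * pnorm(e)^2, -Inf, Inf)$value
  expect_equal(oracle, 0.865767, tolerance = 1e-5)
  n <- 20000
  acc <- mean(simulate_individual_trials(observer_params(2), 3, n, seed = 3)$correct)
  expect_lt(abs(acc - oracle), 3 * mc_se(oracle, n))
  expect_equal(nafc_accuracy(2, 3), oracle, tolerance = 1e-8)
})

test_that("chance-observer confidence uses all levels about equally", {
  # bin edges are quantiles of the chance margin distribution by design
  n <- 8000
  tr <- simulate_individual_trials(observer_params(0, meta_noise = 0), 3, n,
                                   seed = 4)
  props <- tabulate(tr$confidence, 4) / n
  expect_true(all(abs(props - 0.25) < 3 * mc_se(0.25, n)))
})

test_that("joint decisions follow the aggregation rules", {
  p <- observer_params(1)
  ta <- simulate_individual_trials(p, 3, 200, seed = 5)
  tb <- simulate_individual_trials(p, 3, 200, target = ta$target, seed = 6)
  for (rule in c("coin_flip_voting", "defer_to_higher_confidence", "evidence_sum")) {
    j <- combine_dyad_decision(ta, tb, rule, seed = 7)
    agree <- ta$choice == tb$choice
    expect_equal(j$joint_choice[agree], ta$choice[agree])
    expect_equal(j$conflict, !agree)
    expect_true(all(j$joint_correct == (j$joint_choice == ta$target)))
  }
  # defer rule: higher confidence wins on disagreement
  dis <- which(ta$choice != tb$choice & ta$confidence != tb$confidence)
  jd <- combine_dyad_decision(ta, tb, "defer_to_higher_confidence", seed = 8)
  winner_a <- ta$confidence[dis] > tb$confidence[dis]
  expect_equal(jd$joint_choice[dis],
               ifelse(winner_a, ta$choice[dis], tb$choice[dis]))
  # evidence_sum: argmax of the pooled evidence vectors
  je <- combine_dyad_decision(ta, tb, "evidence_sum")
  pooled <- as.matrix(ta[paste0("ev.", 1:3)]) + as.matrix(tb[paste0("ev.", 1:3)])
  expect_equal(je$joint_choice[!agree], max.col(pooled)[!agree])
  # coin flip: each side picked about half the time on disagreement
  dis_all <- which(ta$choice != tb$choice)
  picks <- vapply(1:400, function(s) {
    j <- combine_dyad_decision(ta, tb, "coin_flip_voting", seed = s)
    mean(j$joint_choice[dis_all] == ta$choice[dis_all])
  }, numeric(1))
  expect_lt(abs(mean(picks) - 0.5), 3 * mc_se(0.5, 400 * length(dis_all)))
  # mismatched targets are rejected
  tc <- simulate_individual_trials(p, 3, 200, target = 1, seed = 9)
  expect_error(combine_dyad_decision(ta, tc, "coin_flip_voting"),
               class = "olfdyad_alignment_error")
})

test_that("voting identity: dyad accuracy equals the members' average", {
  pa <- observer_params(1.5)
  pb <- observer_params(0.5)
  n <- 100000
  ta <- simulate_individual_trials(pa, 3, n, seed = 10)
  tb <- simulate_individual_trials(pb, 3, n, target = ta$target, seed = 11)
  # exact sample identity: P(both) + P(one)/2 = (p1 + p2)/2
  p_both <- mean(ta$correct & tb$correct)
  p_one <- mean(xor(ta$correct, tb$correct))
  expect_equal(p_both + p_one / 2, (mean(ta$correct) + mean(tb$correct)) / 2)
  # simulation of the coin flips within 3 MC standard errors
  j <- combine_dyad_decision(ta, tb, "coin_flip_voting", seed = 12)
  target <- (mean(ta$correct) + mean(tb$correct)) / 2
  expect_lt(abs(mean(j$joint_correct) - target), 3 * mc_se(target, n))
})

test_that("confidence sharing beats the best individual when abilities match", {
  p <- observer_params(1.5, meta_noise = 0)
  n <- 60000
  ta <- simulate_individual_trials(p, 3, n, seed = 13)
  tb <- simulate_individual_trials(p, 3, n, target = ta$target, seed = 14)
  best <- max(mean(ta$correct), mean(tb$correct))
  jd <- combine_dyad_decision(ta, tb, "defer_to_higher_confidence", seed = 15)
  je <- combine_dyad_decision(ta, tb, "evidence_sum")
  se <- mc_se(best, n)
  expect_gt(mean(jd$joint_correct), best + 3 * se)
  expect_gte(mean(je$joint_correct), mean(jd$joint_correct) - 3 * se)
})

test_that("infinite metacognitive noise reduces deferral to voting", {
  pa <- observer_params(1.5, meta_noise = 1e6)
  pb <- observer_params(0.5, meta_noise = 1e6)
  n <- 60000
  ta <- simulate_individual_trials(pa, 3, n, seed = 16)
  tb <- simulate_individual_trials(pb, 3, n, target = ta$target, seed = 17)
  jd <- combine_dyad_decision(ta, tb, "defer_to_higher_confidence", seed = 18)
  voting <- (mean(ta$correct) + mean(tb$correct)) / 2
  expect_lt(abs(mean(jd$joint_correct) - voting), 3 * mc_se(voting, n))
})

test_that("weighted confidence sharing closed form", {
  expect_equal(wcs_oracle(1, 1)$s_dyad, sqrt(2))
  expect_equal(wcs_oracle(1, 1)$cb, sqrt(2))
  r <- sqrt(2) - 1
  expect_equal(wcs_oracle(r, 1)$cb, 1)
  expect_equal(wcs_oracle(0.5, 1)$cb, 1.5 / sqrt(2))
  expect_error(wcs_oracle(0, 1), class = "olfdyad_domain_error")
  expect_error(wcs_oracle(2, 1))
})

test_that("2AFC evidence pooling matches the closed-form dyad sensitivity", {
  a1 <- 1; a2 <- 2
  n <- 60000
  ta <- simulate_individual_trials(observer_params(a1), 2, n, seed = 19)
  tb <- simulate_individual_trials(observer_params(a2), 2, n, target = ta$target,
                                   seed = 20)
  je <- combine_dyad_decision(ta, tb, "evidence_sum")
  # 2AFC: accuracy = Phi(s / sqrt(2)), so s_hat = sqrt(2) * qnorm(accuracy)
  s_hat <- sqrt(2) * qnorm(mean(je$joint_correct))
  s_pred <- wcs_oracle(a1, a2)$s_dyad
  acc_pred <- pnorm(s_pred / sqrt(2))
  se_s <- sqrt(2) / dnorm(qnorm(acc_pred)) * mc_se(acc_pred, n)
  expect_lt(abs(s_hat - s_pred), 3 * se_s)
})

test_that("sessions are reproducible and internally consistent", {
  pa <- observer_params(1.5)
  pb <- observer_params(1.0)
  s1 <- simulate_session(pa, pb, "defer_to_higher_confidence", 16,
                         "identification", seed = 21)
  s2 <- simulate_session(pa, pb, "defer_to_higher_confidence", 16,
                         "identification", seed = 21)
  expect_identical(s1, s2)
  expect_equal(s1$conflict, classify_conflict(s1$answer_a, s1$answer_b))
  expect_true(all(s1$answer_a %in% c("optA", "optB", "optC", "optD")))
  sd_ <- simulate_session(pa, pb, "coin_flip_voting", 16, "discrimination",
                          seed = 22)
  expect_true(all(sd_$answer_a %in% c("1", "2", "3")))
  expect_error(simulate_session(pa, pb, n_trials = 0))
})

test_that("chance-level dyads disagree at the independent-guessing rate", {
  p0 <- observer_params(0)
  n <- 6000
  s3 <- simulate_session(p0, p0, "coin_flip_voting", n, "discrimination", seed = 23)
  s4 <- simulate_session(p0, p0, "coin_flip_voting", n, "identification", seed = 24)
  expect_lt(abs(mean(s3$conflict) - 2 / 3), 3 * mc_se(2 / 3, n))
  expect_lt(abs(mean(s4$conflict) - 3 / 4), 3 * mc_se(3 / 4, n))
  # very able dyads almost never disagree
  phi <- observer_params(6)
  s5 <- simulate_session(phi, phi, "coin_flip_voting", 2000, "discrimination",
                         seed = 25)
  expect_lt(mean(s5$conflict), 0.01)
})

test_that("collective benefit grows with ability similarity under deferral", {
  sweep <- simulate_similarity_sweep(80, seed = 26)
  fit <- fit_linear(cb ~ ratio, sweep)
  expect_gt(fit$estimate[2], 0)
})
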