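test_that("accuracy-by-confidence profiles behave at the extremes", {
  all_right <- data.frame(subject_id = rep(c("s1", "s2"), each = 6),
                          confidence = rep(1:3, 4), correct = TRUE)
  prof <- accuracy_by_confidence(all_right)
  expect_true(all(prof$per_subject$prop_correct == 1))
  expect_true(all(prof$aggregate$mean_prop == 1))
  # confidence unrelated to accuracy: flat profile at the base rate
  set.seed(71)
  n <- 6000
  flat <- data.frame(subject_id = sample(sprintf("s%d", 1:20), n, TRUE),
                     confidence = sample(1:4, n, TRUE),
                     correct = runif(n) < 0.6)
  prof2 <- accuracy_by_confidence(flat)
  agg <- aggregate(correct ~ confidence, flat, mean)
  expect_true(all(abs(agg$correct - 0.6) < 3 * mc_se(0.6, n / 4)))
  expect_error(accuracy_by_confidence(flat[c("subject_id", "correct")]),
               class = "olfdyad_schema_error")
})

test_that("clustered logistic regression recovers a known odds ratio", {
  set.seed(72)
  n <- 4000
  d <- data.frame(subject_id = sample(sprintf("s%d", 1:20), n, TRUE),
                  confidence = sample(1:4, n, TRUE))
  d$correct <- runif(n) < plogis(-1.2 + log(2) * d$confidence)
  est <- fit_binary_clustered(correct ~ confidence, d, "subject_id")
  i <- which(est$term == "confidence")
  expect_true(est$ci_low[i] <= log(2) && log(2) <= est$ci_high[i])
  expect_equal(est$exponentiated[i], exp(est$estimate[i]))
  expect_error(fit_binary_clustered(correct ~ confidence, d, "nope"),
               class = "olfdyad_schema_error")
  expect_error(fit_binary_clustered(confidence ~ correct, d, "subject_id"),
               class = "olfdyad_schema_error")
})

test_that("complete separation is flagged and refitted with a penalty", {
  d <- data.frame(y = rep(c(TRUE, FALSE), each = 20),
                  x = rep(c(1, 0), each = 20),
                  g = rep(c("a", "b"), 20))
  w <- capture_warnings(est <- fit_binary_clustered(y ~ x, d, "g"))
  expect_true(any(grepl("separation", w)))
  expect_true(isTRUE(attr(est, "separation")))
  expect_true(all(is.finite(est$estimate)))
  expect_lt(max(abs(est$estimate)), 10)
})

test_that("clustered Poisson regression recovers rate ratios", {
  set.seed(73)
  n <- 2000
  d <- data.frame(g = sample(sprintf("d%d", 1:20), n, TRUE),
                  conflict = runif(n) < 0.4)
  d$count <- rpois(n, exp(0 + 1 * d$conflict))
  est <- fit_count_clustered(count ~ conflict, d, "g")
  i <- 2
  expect_true(est$ci_low[i] <= 1 && 1 <= est$ci_high[i])
  # null predictor: rate ratio near 1
  d$noise <- runif(n) < 0.5
  est0 <- fit_count_clustered(count ~ noise, d, "g")
  expect_lt(abs(est0$exponentiated[2] - 1), 0.25)
  d$count <- 0L
  expect_error(fit_count_clustered(count ~ conflict, d, "g"),
               class = "olfdyad_degenerate_fit")
  d$count <- runif(n)
  expect_error(fit_count_clustered(count ~ conflict, d, "g"),
               class = "olfdyad_schema_error")
})

test_that("mixed estimates collapse to the unclustered GLM at zero variance", {
  # balanced data built with no cluster effect at all: the variance
  # component is estimated at the boundary and the fits must coincide
  d <- expand.grid(rep = 1:10, g = sprintf("c%d", 1:8), x = c(0, 1))
  d$y <- rep(c(rep(TRUE, 3), rep(FALSE, 7)), length.out = nrow(d))
  est_mm <- fit_binary_clustered(y ~ x, d, "g")
  fit <- attr(est_mm, "model")
  expect_lt(unname(lme4::VarCorr(fit)$g[1]), 1e-8)
  est_glm <- coef(glm(y ~ x, binomial(), d))
  expect_equal(est_mm$estimate, unname(est_glm), tolerance = 1e-6)
  d$count <- rep(c(0L, 1L, 2L), length.out = nrow(d))
  est_pois <- fit_count_clustered(count ~ x, d, "g")
  fitp <- attr(est_pois, "model")
  expect_lt(unname(lme4::VarCorr(fitp)$g[1]), 1e-8)
  est_pglm <- coef(glm(count ~ x, poisson(), d))
  expect_equal(est_pois$estimate, unname(est_pglm), tolerance = 1e-6)
})

test_that("ordinary least squares wrapper reports exact fits and df", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  est <- suppressWarnings(fit_linear(y ~ x, d))
  expect_equal(est$estimate[est$term == "x"], 2)
  expect_equal(max(abs(resid(attr(est, "model")))), 0, tolerance = 1e-12)
  d20 <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_equal(fit_linear(y ~ x, d20)$df, c(18, 18))
  d$z <- d$x * 3
  expect_error(fit_linear(y ~ x + z, d), class = "olfdyad_singularity_error")
})

test_that("OLS slope is recovered across seeds in the benefit regression", {
  covered <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    r <- runif(20, 0.3, 1)
    cb <- 0.6 + 0.7 * r + rnorm(20, 0, 0.12)
    est <- fit_linear(cb ~ r, data.frame(r = r, cb = cb))
    est$ci_low[2] <= 0.7 && 0.7 <= est$ci_high[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("confidence intervals attain nominal coverage under the null", {
  hits <- vapply(1:250, function(s) {
    set.seed(2000 + s)
    d <- data.frame(x = rnorm(30), y = rnorm(30))
    est <- fit_linear(y ~ x, d)
    est$ci_low[2] <= 0 && 0 <= est$ci_high[2]
  }, logical(1))
  bt <- binom.test(sum(hits), length(hits), p = 0.95)
  expect_gt(bt$p.value, 0.01)
})

test_that("the BIC Bayes factor follows its definition", {
  set.seed(74)
  d <- data.frame(x = rnorm(40), z = rnorm(40))
  d$y <- d$x + rnorm(40)
  m1 <- lm(y ~ x, d)
  m2 <- lm(y ~ x + z, d)
  cmp <- bayes_factor_bic(m1, m2)
  expect_equal(cmp$bf01, exp((BIC(m2) - BIC(m1)) / 2))
  expect_gt(cmp$bf01, 0)
  # the same model against itself is perfectly indifferent
  expect_equal(bayes_factor_bic(m1, m1)$bf01, 1)
  m3 <- lm(y ~ x, d[1:30, ])
  expect_error(bayes_factor_bic(m1, m3), class = "olfdyad_alignment_error")
})

test_that("an interaction-free generator favors the simple model", {
  favored <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    d <- data.frame(x = rnorm(120), g = sample(c(0, 1), 120, TRUE))
    d$y <- d$x + rnorm(120)
    bayes_factor_bic(lm(y ~ x + g, d), lm(y ~ x * g, d))$bf01 > 1
  }, logical(1))
  expect_gt(mean(favored), 0.5)
})

test_that("the full analysis report covers every section", {
  ds <- make_small_dataset(seed = 75)
  rep <- suppressWarnings(run_full_analysis(ds))
  expect_s3_class(rep, "olf_report")
  expect_true(all(c("demographics", "metacognition", "baselines",
                    "similarity_benefit", "similarity_conflicts",
                    "similarity_resolution", "conflict_summaries",
                    "word_count_model", "words_resolution", "talkative_wins",
                    "lexicon_model", "lexicon_resolution", "bf_comparison")
                  %in% names(rep)))
  expect_equal(names(rep$metacognition),
               c("discrimination", "identification"))
  expect_equal(rep$baselines$discrimination$df, c(7, 7))
  # Holm-corrected task-wise p values are present and labelled
  pt <- rep$words_resolution$per_task
  expect_true(all(vapply(pt, function(e) "p_corrected" %in% names(e), logical(1))))
  expect_match(attr(pt[[1]], "correction"), "corrected")
  # corrected p values are never smaller than the raw ones
  for (e in pt) {
    i <- which(e$term == "words_total")
    expect_gte(e$p_corrected[i], e$p[i] - 1e-12)
  }
  expect_gt(rep$bf_comparison$bf01, 0)
  # talkative-wins probability is the inverse logit of the intercept
  expect_equal(rep$talkative_wins_probability,
               100 * plogis(rep$talkative_wins$estimate[1]))
  out <- capture.output(print(rep))
  expect_true(any(grepl("collective benefit", out, ignore.case = TRUE)))
  expect_error(run_full_analysis(list(trials = ds$trials)),
               class = "olfdyad_missing_input")
})
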