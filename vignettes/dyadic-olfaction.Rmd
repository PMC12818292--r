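---
title: "Modelling dyadic olfactory decisions: observers, staircases and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dyadic olfactory decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfdyad)
```

## The problem

Forced-choice olfactory test batteries score three subtests: a 16-level
n-butanol detection **threshold** (T), a 16-trial three-alternative oddity
**discrimination** task (D, chance 1/3) and a 16-trial four-alternative
**identification** task (I, chance 1/4). When two people first answer
privately and then agree on a joint answer, three questions arise: does the
pair beat its better member (*collective benefit*), does that depend on how
similar the two members' abilities are (*similarity ratio*), and what in
the conversation carries the benefit? This package implements the full
pipeline for those questions — scoring, a generative model of individual
and paired observers, a synthetic study generator, and the statistical
stage — so that every analysis can be exercised end-to-end without any
participant data.

## The observer model

An individual trial with `m` alternatives is modelled as a race between
independent Gaussian evidence draws: the target contributes
Normal(*a*, 1) and each distractor Normal(0, 1), where *a* >= 0 is the
observer's latent **ability** on that task. The choice is the argmax; the
probability of a correct choice is

$$P(\text{correct}) = \int \phi(e - a)\,\Phi(e)^{m-1}\,de,$$

available as `nafc_accuracy()` and used as an independent quadrature check
on the simulator. At *a* = 0 this reduces to 1/m for any m.

**Confidence** is the top-minus-runner-up evidence margin plus
Normal(0, `meta_noise`) metacognitive noise, cut into `n_conf_levels`
ordinal levels. The default cutoffs are the equal-probability quantiles of
the chance-observer margin (computed by quadrature in `conf_bin_edges()`),
so a zero-ability observer occupies all levels uniformly. `meta_noise = 0`
gives maximally informative confidence; large values decouple confidence
from accuracy entirely. The package treats confidence as numeric in the
metacognition models, which matches reporting a single odds ratio per task.

Distractor evidences are i.i.d.; no inter-odor similarity structure is
modelled, so confusion patterns between particular odors are outside the
model's scope.

## Dyadic aggregation rules

`combine_dyad_decision()` implements three benchmarks, not claims about
what real pairs do:

- **coin_flip_voting** — agreement stands, disagreement is a fair coin.
  For any pair of accuracies and any answer correlation the expected joint
  accuracy is exactly the members' mean: P(both correct) + P(exactly one)/2
  = (p1 + p2)/2. This is the floor that genuine communication must beat.
- **defer_to_higher_confidence** — disagreement goes to the member with
  the higher ordinal confidence (ties: fair coin, logged as such). With
  informative confidence this rule produces a collective benefit that
  grows with ability similarity; with `meta_noise` large it converges to
  voting.
- **evidence_sum** — the argmax of the summed evidence vectors; an ideal
  pooling ceiling no verbal exchange can reach. In the 2AFC special case
  its joint sensitivity follows the closed form
  `s_dyad = (s_low + s_high) / sqrt(2)` (`wcs_oracle()`), so collective
  benefit crosses 1 exactly at similarity ratio `sqrt(2) - 1`.

## The threshold staircase

The staircase is a state machine (`staircase_step()`) over levels 1
(strongest) to 16 (weakest):

- **Initial phase**: presentation starts at level 16 and descends in steps
  of two (16, 14, ..., 2, 1). A correct response repeats the same level; two
  consecutive corrects record the level as the first turning point and open
  the main phase; an incorrect resumes the descent. An observer who reaches
  level 1 without two consecutive corrects is excluded (suspected anosmia).
- **Main phase**: a single 2-down/1-up staircase on concentration — two
  consecutive corrects move one level weaker, any incorrect one level
  stronger. Each direction reversal records the level at which it occurred.
  The run completes at seven turning points; the **T score** is the mean of
  the last four.

Two numerical guards make degenerate observers terminate: at the boundary
levels the staircase holds its level and records a boundary turning point
(so a perfect observer scores T = 16), and a presentation cap (default 60
main-phase presentations) returns an explicit *incomplete* flag rather than
a fabricated score. The roughly 30-second inter-trial interval of the
clinical procedure has no computational consequence and is not modelled.
The phrasing of the clinical manual on the post-reversal direction is
ambiguous; the standard 2-down/1-up reading adopted here reproduces the
expected hand-trace: an observer correct exactly down to level 8 walks
turning points 8, 9, 8, 9, 8, 9, 8 and scores T = 8.5.

```{r staircase}
run_threshold_test(step_responder(8), seed = 1)
```

## The synthetic study generator

`generate_study_dataset()` emulates a two-day design: a day-1 cohort tested
individually on all three subtests, quartile-based matching into
equal-ability and unequal-ability dyads on the day-1 D + I sum
(`match_dyads()`: the two middle quartiles pair with each other, the top
quartile pairs with the bottom), a returning subset, and day-2 dyadic
sessions of both tasks with transcript-derived word and lexicon counts.

Key parameters, defaults and reasons:

- `n_day1 = 53`, `n_return = 40` (20 dyads), 16 trials per task — the
  cohort geometry the analysis is designed around.
- Latent abilities are Gaussian truncated at zero, `N(1.65, 0.5)` for
  discrimination and `N(2.0, 0.5)` for identification. These were chosen
  once so that expected scores land in the healthy-adult range of the
  clinical battery (means near 13/16) and private answers disagree on
  roughly one third of trials, and were not revisited. The generated
  conflict proportion is checked against the configured band (0.25–0.42).
- Day-1/day-2 retest correlations `rho_d = 0.8 > rho_i = 0.6`:
  discrimination is the more reliable subtest. There is no systematic mean
  shift between days. The inter-session gap (mean 40.6 d, SD 23.3) is
  recorded as metadata only.
- `meta_noise = 0.5` with 4 confidence levels yields confidence–accuracy
  odds ratios around 1.8–2.1 in the metacognition models — the magnitude
  such batteries produce in practice.
- An optional linear age effect on identification ability
  (`age_slope_i = 0.05` per year of latent ability, about 0.16 score
  points per year) is the only demographic structure.
- Threshold psychometric functions are logistic over levels with midpoint
  `N(9, 2.5)` and slope 1.5, floored at the 3AFC guessing rate.

**Language metrics.** Per-trial dyad word totals follow a Poisson count
whose mean combines additive fixed effects (baseline 25 words, +47.9 on
conflict trials, −11.47 in identification) with multiplicative log-normal
dyad- and trial-level effects (SDs 0.3 and 0.25) — any overdispersed
positive count model with this within/between structure would do; this one
is simple. A per-dyad logistic share (SD 0.4) splits words between members.
Confidence-lexicon counts are Poisson with log-linear effects (+1.26 on
conflict, −0.35 in identification, dyad SD 0.2).

**Talkative-wins.** With the default `talkative_wins = TRUE`, the joint
answer of each conflict trial is re-decided: the *more* talkative member's
answer is adopted with probability `plogis(-0.59)` = 35.7%. This mechanism
deliberately severs the link between the aggregation rule and conflict
outcomes, so analyses of the aggregation rules themselves (e.g. the
similarity–benefit structure of confidence deferral) should generate with
`talkative_wins = FALSE` or use `simulate_similarity_sweep()`, which pairs
a fixed-ability member with partners spanning the full ability-ratio range.

What passing tests on these data do **not** show: real transcripts, real
inter-odor confusability, learning or fatigue across trials, or the
feedback loops of live conversation. The generator establishes that the
pipeline recovers known structure; it cannot validate substantive claims
about human dyads.

## The inference stage

`run_full_analysis()` runs the model sequence on a dataset (synthetic or
read from CSV): demographics (OLS per subtest), metacognition
(subject-clustered logistic regression of accuracy on confidence),
dyad-vs-best and dyad-vs-average paired t tests (two-sided, 95% CIs;
differences are reported as dyad minus baseline), similarity–benefit OLS on
both day bases, similarity–conflict-count and similarity–resolution OLS,
a Gaussian mixed model for trial word counts, dyad-clustered logistic
models of conflict resolution on words (task-specific contrasts
Holm-corrected and labelled as such), the word-use variance decomposition
model, the talkative-wins intercept model, the confidence-lexicon Poisson
mixed model, and a BIC-approximated Bayes factor
(`BF01 = exp((BIC_complex - BIC_simple)/2)`) comparing the resolution
models with and without the task-by-lexicon interaction.

Design choices where the design was open: random effects are intercepts
only (no slopes are reported anywhere in this literature's tables); the
multiple-testing correction is Holm; the Bayes factor uses the Schwarz
(BIC) approximation; models cluster by dyad except metacognition, which
clusters by subject because those decisions are private. Complete
separation in a logistic fit is detected heuristically (absurd estimates
or standard errors), warned about, and refitted with a small ridge penalty
via glmnet — point estimates only, flagged in the result.

```{r analysis, eval = FALSE}
ds <- generate_study_dataset(seed = 42)
report <- run_full_analysis(ds)
print(report)
```

## Numerical and scale choices

- Percentages are reported on the 0–100 scale; `round_half_up()` matches
  the half-up convention of clinical score tables.
- Similarity and benefit ratios error out (rather than return NaN) when
  the denominator score is zero.
- Resolution rates are absent (NA), not zero, for dyads with no resolvable
  conflicts.
- Quartile boundaries for cohorts not divisible by four sit at
  `ceiling(n/4)` and `floor(3n/4)` of the ascending D + I ranking, ties
  broken by subject id; leftover subjects are dropped with a warning that
  the generator records in its manifest.
- All randomness flows through explicit seeds; every generator restores
  the caller's RNG state.
- Test problem sizes: 10,000-trial chance checks, 100,000-trial voting
  identity, 100-replicate recovery of the generating language effects, and
  24-seed sign tests for the similarity–benefit slope with 60 dyads per
  seed — sizes at which Monte-Carlo error is far below the effects under
  test while the suite stays quick.

## Known limitations

- Ability is unidimensional per task; no shared perceptual space across
  tasks beyond the latent correlations.
- The confidence scale of real batteries varies; the pipeline accepts any
  ordinal scale but models it linearly.
- The talkative-wins generator chooses winners independently of
  correctness, which is a deliberately pessimistic model of conversation:
  real dyads presumably mix confidence-based and verbosity-based
  resolution.
- The lexicon is a configuration artifact seeded with common
  English confidence expressions, not a validated instrument.
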