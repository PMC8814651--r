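---
title: "Methods: scoring, prioritization and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, prioritization and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iflt)
```

## The instrument model

The tool couples a 17-item food-literacy screener to 24 food-literacy goals
across five domains (plan, select, prepare, eat, evaluate information). Each
goal carries a unique *expert ranking weight* in {0.01, …, 0.24}: the higher
the weight, the more relevant the goal according to the expert panel that
ranked the goals. Fifteen items address one goal each; two forced-choice
*situation* items ("in which situation / during which meal do you struggle
most?") fan out to five and four goals respectively, so the 17 items cover
all 24 goals.

Every answer option carries two scores:

* **IOS (item overall score), 0–6.** Summed over the 17 items and rescaled
  to percent of the attainable maximum (6 × 17 = 102), giving the overall
  0–100 food-literacy score.
* **IPS (item priority score), 0–5.** The need signal: 5 means the
  respondent would clearly benefit from working on the linked goal, 0 means
  no need.

For each goal the algorithm adds the (capped) IPS contribution and the
goal's weight; ranking the 24 totals descending yields the personal priority
list. Integer IPS components plus pairwise-distinct two-decimal weights
below 1 make ties impossible: the IPS decides the coarse order and the
expert weight breaks every remaining comparison. The all-zero-IPS profile
therefore reproduces the default expert ordering exactly.

## Reconstructing the option sets

Only two option sets are published in full: the agreement item behind
"making healthy food choices" (IOS 0–6 from *strongly disagree* to *strongly
agree*, IPS 5,4,3,2,1,0,0) and the water-frequency item (seven portion
bands, with the recommended band scoring IOS 6 and the over-consumption band
IOS 5; IPS 5,4,3,2,1,0,0). Both printed sets satisfy one rule:

```
IPS = max(0, 5 − IOS)
```

The bundled instrument generalizes that rule to the fifteen unpublished
option sets, and marks them `reconstructed` in the JSON config so a user can
override wording or scores without touching code. Specific choices:

* **Agreement and always/never items** use the 7-point scheme verbatim;
  reverse-keyed items (meat, snacks, overeating) flip the IOS direction so
  that less of the unhealthy behaviour scores higher, with the recommended
  level at 6.
* **Forward frequency items** (vegetables, fruit, water) place the
  recommended band at IOS 6 with the over-consumption band below it at 5,
  mirroring the published water item.
* **Reverse frequency items** (meat, ultra-processed snacks) are scored
  monotonically — the recommended low intake is IOS 6 and there is no
  "too little" penalty, because the underlying guidelines are upper bounds.
* **Situation items**: naming a difficulty scores IOS 0 and gives the chosen
  situation's goal IPS 5 (siblings 0); a "no particular difficulties" option
  scores IOS 6 / IPS 0. The published material fixes neither value. We
  considered a neutral midpoint IOS for situation answers, but that would
  contradict two stated contracts — the score must reach 0 exactly when
  every item is at its minimum and 100 exactly at its maximum — so the
  binary 0/6 coding was adopted; it is also the unique coding consistent
  with `IPS = max(0, 5 − IOS)` at the two defined IPS levels (5 for a named
  difficulty, 0 for none). For users who prefer to keep the forced choice
  out of the overall score entirely, `overall_score(..., exclude_situation
  = TRUE)` drops both items and rescales the denominator to 90.
* **The 0.8 weight.** The published goal table prints 0.8 for the
  food-label goal, but the 24 weights are stated to form the set
  {0.01, …, 0.24} and 0.08 is the only missing value; the bundled instrument
  uses 0.08 and records the correction in its metadata.

Goals mapped to several items would have their IPS contributions summed and
capped at 5, preserving the weight's tie-breaking role; the bundled
instrument maps one item per goal, so the cap is exercised only in tests
with modified configs.

## Validation statistics

* **Pearson correlation** via the t transform with n − 2 degrees of freedom,
  pairwise deletion; construct validity is "good" for 0.4 < r < 0.9.
* **Cronbach's alpha** with n − 1 sample variances throughout (that
  convention is what the toy oracles in the tests assume).
* **Test-retest**: both the Pearson coefficient and ICC(A,1) — two-way
  random effects, absolute agreement, single measures — are reported,
  because the source material calls the statistic an intraclass coefficient
  but labels the figure *r*. The Pearson value is the headline; both are
  compared with the 0.7 cut-off. Absolute agreement penalizes a constant
  shift between waves, so `icc <= pearson` for mean-shifted replicates.
* **t-tests** default to the pooled-variance form (the era-typical software
  default); Welch is a flag.
* **CVI**: I-CVI is the share of experts rating 3–4; S-CVI the mean I-CVI;
  thresholds 0.78 / 0.9. Values are reported at two decimals, raw fractions
  retained. The bundled instrument carries the published 7-expert tallies
  (11 items at 7/7, 4 at 6/7, 2 at 5/7), whose mean is 111/119 = 0.9328,
  printed as 0.93.
* **Flesch reading ease** takes explicit counts (the formula's contract);
  the vowel-group syllable counter is a clearly labelled convenience
  approximation, since no counting convention is published for the Dutch
  questionnaire text — which is also why the package does not attempt to
  reproduce the screener's own published readability score.

## Eating-goal accuracy

Accuracy of an eating goal = among respondents with that goal in their
top-3, the share whose FFQ intake actually violates the recommendation
(meat > 100 g/d, vegetables < 300 g/d, fruit < 250 g/d, water < 1500 ml/d,
ultra-processed > 50 g/d; strict inequalities, so boundary values are
compliant). Percentages are rounded half-up; 0 assigned / 0 correct is
reported as 100% to match the published table, but flagged
`undefined_by_convention`. Energy adjustment (rescaling intakes by
reference/actual energy) is available but off by default: the published
thresholds are absolute quantities, and the exact correction used in the
original analysis is unspecified.

## The synthetic cohort

The generator states one world and the tests live in it:

* **Latent trait** θ ~ Beta(5, 2.2) (mean 0.69), chosen so the mean overall
  score lands near the observed ≈ 69% band. With evenly spaced answer
  thresholds the simulated score spread (sd ≈ 13–14) is wider than the
  observed 6.7 — a known, accepted simplification; narrowing it would
  require compressing the answer model around the trait with no published
  basis.
* **Agreement answers**: cumulative-threshold model; the answer latent is
  θ plus N(0, `answer_sd` = 0.12) noise, cut at 1/7, …, 6/7. Expected IOS is
  monotone in θ.
* **Intakes**: truncated normals (at zero) whose means move from the
  non-compliant toward the recommended side as `coupling · θ` grows, e.g.
  vegetables N(120 + 280·cθ, 70) g/day, water N(700 + 1300·cθ, 300) ml/day.
  Energy is independent N(2200, 300) kcal/day.
* **Frequency answers are deterministic functions of the intakes**, with bin
  edges aligned to the recommendation thresholds: an answer with IPS ≥ 1
  implies the intake genuinely violates the guideline. One visible
  consequence: the generator's water bins use 1500 ml as the edge between
  the "7–8 glasses" and recommended bands (nominal glass counts would put it
  at 1600 ml) — the alignment is deliberately guideline-faithful rather than
  label-faithful.
* **Situation items**: simulated respondents always name a difficulty (the
  published instrument offers no opt-out on these items), with fixed
  realistic choice probabilities favouring "at work/school/on the road" and
  the lunch/dinner/snacking meals.
* **External criteria**: diet-quality proxy = 35 + 45·cθ + N(0, 10) clamped
  to 0–100; HESE = 10 + 18·cθ + N(0, 2.5) clamped to the 7-item 7–35 range.
  At `coupling = 0` they are pure noise around a constant, so the screener
  score and the criteria decouple.
* **Determinism**: one global seed fans out to per-component substreams.

**Why full coupling forces 100% accuracy.** Both situation goals of a
respondent carry IPS 5, so at least two goals always have positive need; and
among zero-need goals the heaviest is the 0.24-weight choice goal, which
outranks every zero-need eating goal (weights ≤ 0.23). An eating goal can
therefore only enter a top-3 with IPS ≥ 1, and IPS ≥ 1 implies true
non-compliance because the answer bins are threshold-aligned. The guarantee
is structural, not statistical — which is exactly what makes it a useful
end-to-end consistency check and *not* evidence about real cohorts, where
answer error and threshold mismatch produced accuracies of 88–100%.

**Retest model.** Wave two reuses wave one's per-item latents plus fresh
N(0, `noise_sd`) perturbations (intakes are perturbed by `noise_sd` × their
generator SD and re-binned). `noise_sd = 0` reproduces wave one exactly —
coefficient 1 by construction. The expected coefficient follows the
classical reliability form `V_T / (V_T + σ²)` with trait variance estimated
by the between-wave covariance and σ² the per-wave error variance
`var(S2 − S1)/2`. The default `noise_sd = 0.65` was calibrated once on a
4000-respondent grid so the expected coefficient is ≈ 0.72, inside the
published 0.6–0.8 reliability band; it was not adjusted afterwards.

## What a green test does not establish

The generator matches the statistical *shape* the tool assumes — a single
latent trait, monotone item responses, threshold-aligned intake reporting.
It does not emulate real Belgian food-consumption covariance, differential
item functioning, social desirability, seasonal intake, or the published
cohort's demographics; reproducing the original correlations (0.536, 0.685,
0.721) on real data is out of reach without the raw survey. Green
parameter-recovery tests certify the pipeline's internal consistency, not
field validity.

## Degenerate inputs and numerical conventions

* Missing answers: strict error by default, listing the unanswered items;
  an opt-in policy rescales by the attainable maximum of the answered items
  and flags the output.
* Constant series, zero total variance, groups smaller than 2, empty rating
  vectors: errors, never silent NA.
* Score and CVI values are kept as exact floats; rounding (half-up for
  accuracy percentages, two decimals for CVI) happens only at the reporting
  edge.
* Defensive rank tie-break (reachable only with non-conforming user
  configs): higher expert weight first, then goal id.
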