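---
title: "Methods: longitudinal vocal-biomarker monitoring of asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal vocal-biomarker monitoring of asthma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmon)
```

## The monitoring problem

Adults with asthma can record short sustained-vowel voice samples on a
smartphone; a pre-trained model turns each sample into a
respiratory-responsive vocal-biomarker (RRVB) score on a 0--100 scale,
with higher scores indicating a higher risk of respiratory impairment.
In a self-directed monitoring study each app session also collects up
to three peak expiratory flow (PEF) readings from a handheld meter, a
three-level well-being response ("How is your asthma right now?"), and
symptom/trigger/medication reports; participants additionally complete
a monthly Asthma Control Test (ACT, scored 5--25). `vbmon` implements
the complete analysis pipeline for such data: quality control of the
paired voice scores, PEF personal-best estimation and zone
classification, respiratory-state labeling, per-participant score
normalization, and prevalence risk ratios quantifying how well the
biomarker separates respiratory states and asthma-control levels. The
scoring model itself is out of scope: scores enter the pipeline as
opaque numbers.

## Quality control

Each session is designed to capture two voice samples. A real-time
*elicitation check* (acoustic criteria applied on-device; this package
only consumes its recorded pass/fail flags and attempt counts) allows
up to three recording attempts per sample. Post hoc, *two-sample
scoring* accepts a session only when its two scores agree within 10
points, and averages them into one final score. We read "within 10
points" inclusively (`|s1 - s2| <= 10`); the boundary choice is
configurable and boundary sessions are rare. A session without two
elicitation-passing scores is `FAIL_ELICITATION`; a disagreeing pair is
`FAIL_CONSISTENCY`. `qc_state_balance()` checks, via a chi-square
homogeneity test, whether either gate excluded sessions unevenly
across respiratory states, which would bias downstream prevalence
ratios.

## Relative PEF and personal best

PEF readings above 1000 L/min are removed as device errors and the
highest remaining reading represents the session. A participant's
*personal best* is estimated from the study data itself (there is no
baseline period): the highest session maximum not exceeding the 95th
percentile of all their session maxima. The percentile cap means a
single gross over-blow cannot set the reference. Percentiles use
linear interpolation between order statistics (`stats::quantile`
type 7) throughout the package; the convention is configurable in the
sense that it is isolated in one place, and the choice only matters at
small sample sizes. The percentile is taken over per-session maxima
(the value the analysis consumes), not over raw readings.

Sessions are then expressed as a percentage of personal best and
classified into traffic-light zones: GREEN >= 80%, YELLOW 50--79%, RED
< 50%. Relative values below 20% or above 120% are clinically
implausible and excluded. The design is two-pass without iteration:
personal best is estimated once from all session maxima, then the
20%/120% exclusion is applied; excluded sessions do not trigger
re-estimation.

## Respiratory-state labels

A session's state combines an objective and a subjective criterion:

* PEF criterion: relative PEF below 80% of personal best (YELLOW/RED);
* well-being criterion: response NOT_GOOD or BAD.

Both met is an **exacerbation**, neither is **normal function**,
exactly one is a **mild event**. The label never uses the biomarker
score, so the risk analysis is free of circularity (a property tested
directly). Sessions lacking a usable PEF reading, a well-being
response, or a QC-passing score receive no label; they still count for
engagement, which measures app use.

## Cohorts, normalization and the high-risk thresholds

Three nested cohorts: *enrollment* (everyone), *analysis* (at least 4
completed sessions -- completed, not QC-passing, since the cohort rule
is about study participation and QC exclusion is state-independent by
design), and *normalized* (analysis members with at least 5
normal-function sessions).

Raw scores are banded at 65 (high risk >= 65), a validated screening
benchmark carried over as a fixed constant. For the normalized
analysis, each participant's *reference score* is the median of their
normal-function final scores over the whole study, and
`normalized_score = final_score - reference`. The normalized high-risk
threshold is derived from the data as the mean, across normalized-
cohort participants, of the 70th-minus-50th percentile gap of their
normal-function scores -- the average distance from a participant's
typical normal score to the upper edge of their normal range. An
alternative reading of the threshold definition ("the 70th percentile
of the normalized reference-score distribution") is implemented as
`threshold_method = "pooled_p70"` (the 70th percentile of pooled
normalized normal-function scores); the percentile-gap formulation is
the default because it is operationally explicit about whose
distribution is meant and reduces to the same quantity participant by
participant. Band assignment is inclusive at the threshold (>= is
HIGH).

## Prevalence risk ratios

For event state E (exacerbation or mild) against normal function N,
sessions in the third state are excluded and the table is

|            | E   | N   |
|------------|-----|-----|
| high band  | a   | b   |
| low band   | c   | d   |

with RR = (a/(a+b)) / (c/(c+d)). The confidence interval is the Katz
log method: `exp(log RR +/- z * SE)` with
`SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, and the two-sided p-value
is the normal tail of `log RR / SE`. The unit of analysis is the
session (for ACT contrasts, the assessment), pooled across
participants without a clustering adjustment -- this matches how such
tables are conventionally computed from printed counts, and the
package reports the cells alongside every estimate so any reader can
re-derive them. Zero event cells are a hard error by default with an
opt-in 0.5 continuity correction (`correction = TRUE`); silent
correction would change printed values invisibly.

ACT assessments are linked to the biomarker by averaging a
participant's scores in a 4-week window centered on the assessment
date (14 days each side, boundaries inclusive); centering lets the
enrollment and end-of-study assessments link too. Control levels are
WELL (>= 20), NOT_WELL (16--19), POOR (<= 15), with WELL as the
reference level of the contrasts. Subgroup analyses reuse the same
machinery per stratum, flag strata with undefined estimates, and
assess between-stratum differences by confidence-interval overlap.

## Change scores and engagement

`transition_matrix()` pairs consecutive scored sessions within a
participant (bridging over unscored sessions, with an optional maximum
calendar gap for sensitivity analysis) and summarizes score changes by
transition type with mean and standard error. Months are consecutive
30-day blocks anchored at each participant's enrollment date --
calendar months would make "month 3" ill-defined for mid-month
enrollees in a 90-day study. Engagement groups are defined on total
completed sessions (HIGH >= 52, MEDIUM 26--51, LOW 1--25), and month-3
retention is reported as any use (>= 1 session) and consistent use
(>= 8 sessions).

## The synthetic cohort

`simulate_cohort()` generates a full `study_dataset` so every stage is
testable without access to study data. The generative model and its
defaults:

* **Cohort**: 84 participants, 90 days; demographics drawn to match a
  predominantly female, middle-aged, comorbid urban asthma cohort.
* **Engagement archetypes** (mix 33/25/42% high/medium/low): high
  holds ~22 sessions/month (floor 14) all three months; medium starts
  ~16/month and halves by month 3 with a 12% chance of quitting before
  month 3; low starts ~6/month with a 45% quit hazard after each
  month. These produce a cohort mean near 35 total sessions and the
  observed retention pattern (high ~100% consistent month-3 use, low
  ~30% any use).
* **Latent respiratory state**: a daily 3-state process per
  participant using the mixture kernel `P = rho*I + (1 - rho)*1*pi'`
  with persistence `rho = 0.6` and stationary target
  `pi = (0.615, 0.278, 0.107)` for normal/mild/exacerbation. The
  kernel's stationary distribution equals the target exactly for any
  `rho`, so the marginal calibration is by construction, and `rho`
  only sets episode duration (mean run length ~2.5 days). The state
  evolves whether or not a session occurs; missingness is
  state-independent by default, with a switch
  (`state_dependent_missingness`) that drops 30% of
  exacerbation-day sessions to stress-test informative missingness.
* **Scores**: participant baseline ~ N(61.7, 10) between participants;
  state shifts +3 (mild) and +8 (exacerbation); shared day noise SD 6;
  independent per-sample noise SD 5.6, chosen analytically so that
  about 79% of score pairs agree within 10 points
  (`|s1-s2| ~ N(0, sqrt(2)*5.64)`).
* **QC**: per-attempt elicitation failure probabilities
  0.133/0.353/0.446; a second sample is missing with probability
  0.066 (derived from the funnel arithmetic: ~192 never-attempted
  second samples out of 2 x 2922). Jointly these give ~71--72% of
  sessions scored.
* **PEF**: latent personal best ~ N(420, 80) L/min truncated to
  250--900; relative level drawn from a truncated normal concentrated
  at 0.93 (0.805--1.02) for normal-PEF sessions and 0.68 (0.25--0.795)
  for reduced-PEF sessions; readings are integer L/min with occasional
  missing sessions (2%) and rare >1000 error readings (0.3%).
* **Well-being** is drawn jointly with the PEF level so the pair is
  consistent with the latent state (a mild event meets exactly one
  criterion, with the PEF criterion chosen 60% of the time).
* **ACT**: assessments at days 1/30/60/90 with 70% completion;
  `score = 22 - 9*burden + noise` clamped to 5--25, where burden is
  the trailing-30-day fraction of mild days plus twice the fraction of
  exacerbation days -- so ACT tracks recent state burden but is not a
  deterministic function of it.

The latent truth (baselines, personal bests, archetypes, per-session
states) is attached to the dataset, enabling parameter-recovery tests:
estimated personal bests land within a few percent of the latent
values for well-sampled participants, and with the state shifts set to
zero the downstream risk ratios are consistent with 1.

What the simulator deliberately does **not** model: day-to-day score
autocorrelation beyond the Markov state (no stated basis for a value),
seasonal or weekday effects, device or enrollment-site effects,
learning effects in PEF technique, and item-level ACT structure (only
the total is consumed downstream). Passing tests on simulated data
therefore show the pipeline's arithmetic and its statistical behavior
under the stated generative assumptions -- not that real data satisfy
those assumptions.

## The engineered validation cohort

`validation_cohort()` is a deterministic, counts-level synthetic
dataset built so the *entire* pipeline -- QC, personal best, zones,
labels, references, threshold, banding, risk ratios, ACT windows --
must be simultaneously correct to reproduce known cell counts and the
estimates they imply (e.g. exacerbation RR 2.15 raw and 3.57
normalized). Scores use a 10-point-spaced alphabet around group
references of 50 and 70 so that any derived normalized threshold in
(0, 10] produces identical banding, making the harness robust to the
exact threshold value; ACT windows are realized as value-pure session
clusters 28 days apart so each centered 4-week window sees only its
own cluster. It is a regression harness, not a realistic cohort.

## Numerical and degenerate-input choices

* Percentiles: linear interpolation (type 7); medians use the standard
  midpoint convention for even counts.
* All band and window boundaries are inclusive (score >= threshold is
  HIGH; a session exactly 14 days from the ACT date is in the window;
  a score difference of exactly 10 passes QC; relative PEF exactly 80%
  is GREEN).
* Zero event cells: hard error naming the continuity-correction
  option.
* Empty inputs: empty cross-tabs return all-zero tables; a participant
  below the normal-session floor is silently omitted from the
  normalized cohort; an assessment with an empty window is marked
  ineligible rather than dropped; a dataset with no exacerbations
  completes the pipeline with the affected tables marked undefined.
* Sessions with no valid PEF reading are excluded from labeling but
  retained for engagement counting.

## Problem sizes used in the checks

The package's stochastic self-checks run at sizes chosen to make the
properties sharp but cheap: the null-coverage study uses 200
replicates of 40 participants x 60 days (large enough that the
log-interval's asymptotics apply; at much smaller event counts the
Katz interval is known to undercover slightly), effect-ordering uses
50 full-scale (84 x 90) seeds, and parameter-recovery pools three
full-scale seeds. The elicitation funnel check uses 50 replicates of
5652 samples.

## Limitations

Pooling sessions across participants without a clustering adjustment
understates uncertainty when participants contribute very unequal
session counts; a cluster bootstrap over participants would widen the
intervals and is a natural extension point. The personal best is a
study-internal estimate and will be biased low for participants who
never achieved a true maximal effort. The state definition depends on
self-reported well-being and effort-dependent PEF; the simulator's
clean separation between criteria is an idealization. The normalized
threshold is derived post hoc from the same data it bands, which is
faithful to the analysis design but not a prospective decision rule.
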