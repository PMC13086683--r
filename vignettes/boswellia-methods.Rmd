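---
title: "Models and methods behind boswellia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boswellia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boswellia)
```

`boswellia` packages a complete synthetic re-implementation of a framed
common-pool-resource study: a bioeconomic model of frankincense tapping, a
card-game experiment in which groups of five harvesters vote on non-binding
extraction targets under short-term property rights, a household survey
measuring cognitive and structural bonding social capital, and the panel
regressions linking the two. This vignette explains each model, the tunable
parameters, the choices made where the design was genuinely open, and what the
synthetic pipeline can and cannot say about real field data.

## The tapping model

A *Boswellia papyrifera* tree's resin yield depends on its health, which
declines with tapping. With $q_t$ wounds applied in period $t$ and cumulative
wounds $Q_t = \sum_{i \le t} q_i$ (the current period included), the model is

$$
V_t = \alpha - \beta Q_t, \qquad
h_t = \zeta\, q_t V_t, \qquad
\pi_t = P h_t - c\, q_t,
$$

with initial health $\alpha$, marginal health loss per wound $\beta$,
production coefficient $\zeta$, price $P$ (tokens per harvest unit) and unit
effort cost $c$ (tokens per wound). The experiment's calibration —
`extraction_params()` defaults — is $P = 5$, $\zeta = 0.7$, $\alpha = 21$,
$\beta = 0.5$, $c = 0.5$, a three-period tree lifetime and a hard cap of 40
wounds (cards) per tree. Extraction is profitable at all only when
$P\zeta\alpha > c$ (`feasibility_condition()`).

Summing $\pi_t$ over the horizon $T$ and writing $S = \sum_t q_t$ shows the
lifetime payoff depends on a plan only through $S$ and $\sum_t q_t^2$:

$$
\Pi = (P\zeta\alpha - c)\,S - \tfrac{1}{2} P\zeta\beta\,(S^2 + \textstyle\sum_t q_t^2).
$$

Two consequences drive the package's benchmarks:

* **Long-term tenure (no tree reallocation).** For a fixed total, the evenest
  split maximizes $\Pi$; optimizing over $S$ gives the constant plan
  $q^\* = (P\zeta\alpha - c)/((T+1)\beta P\zeta)$ — for the default horizon
  $73/7 \approx 10.43$ wounds per period. The per-round *integer* benchmark,
  found by exhaustive search over constant plans
  (`optimal_integer_plan(constant = TRUE)`), is 10 wounds per round
  (payoff 1140 tokens). The unrestricted integer search returns the uneven
  split $(10, 10, 11)$ with payoff 1141.25: with a continuous optimal total of
  $31.29$, integer granularity favours total 31 split as evenly as possible.
  Both are exposed; the game's "social optimum" benchmark is the constant
  plan, which is also what a single per-round target can encode.
* **Short-term tenure (random reallocation each period).** A myopic harvester
  maximizes the one-period payoff of the tree in hand:
  $q_t = (P\zeta(\alpha - \beta Q_{t-1}) - c)/(2\beta P\zeta)$. The recursion
  halves the marginal surplus every period, so each interior step is exactly
  half the previous one — for the defaults
  $(20.86, 10.43, 5.21)$, integer path $(21, 10, 5)$. Relative to the
  long-term optimum the myopic path always cuts more in total and earns less,
  the model's core tenure-security prediction.

Both closed forms were derived from first-order conditions and are verified in
the test suite against dense grid-search oracles, including the exact-halving
property across randomly drawn parameter sets.

## Survey scoring

The instrument has thirteen 1–4 Likert items: nine *cognitive* (one trust,
four reciprocity, four social norms) and four *structural bonding* (three
participation, one organizational membership), shipped with their published
calibration means and SDs in `inst/extdata/sc_items.json`. Scoring
(`score_survey()`):

1. each item is z-standardized across respondents (sample SD, denominator
   $n-1$; a zero-variance item is a hard error naming the item);
2. the cognitive (bonding) index is the unweighted mean of the respondent's
   nine (four) item z-scores; the aggregate index is the sum of the two;
3. group-level indices are the mean of the five members' indices — mean rather
   than sum so that group and individual indices live on the same scale and
   group size does not leak into the index — while the aggregate remains the
   sum across dimensions.

The negatively worded reciprocity item ("would try to take advantage of you…")
is scored as printed by default; `sc_item_catalog(reverse_negative_items =
TRUE)` flips it. Reversal is off by default because the published item mean is
used as-is in the source instrument's descriptive table.

## The synthetic cohort

`generate_cohort()` produces the study population: 210 harvesters, 54% female,
mean age 38, mean schooling 2.8 years, mean adult-equivalent family size 5.4
(adults + 0.5 × children, built from Poisson adult and child counts), gamma
landholdings, a three-class wealth self-classification centred on the middle
class, and log-normal annual income with mean Birr 46,980 (only the mean is
published; a right-skewed positive distribution is the natural shape for rural
household income). Groups of five are formed by seeded random partition and
assigned near-evenly to seven treatment sequences.

Likert items are generated ordinal-probit style. For each item, a discretized
normal is fitted so that the implied four-category mean matches the
calibration mean *exactly* and the SD as closely as the family allows; the
category cut points are mapped to the standard-normal scale, and the
respondent's item latent is $\rho F + \sqrt{1-\rho^2}\,\varepsilon$ with
dimension factor $F$ and item loading $\rho = 0.7$. Two limitations are
inherent and documented rather than hidden: (i) an item with mean 3.99 on a
1–4 scale cannot have SD 0.21 (the maximum for that mean is 0.17), so the
volunteer item's SD is matched only as far as arithmetic permits; (ii) the
same item is constant in roughly one sample in ten at $n = 210$, so the
generator nudges one seeded respondent by one category when that happens
(a mean shift of $1/n$, far inside sampling noise).

The factors are driven by demographics. The cognitive factor uses log income
and family size with loadings 0.117 and 0.263; the noise SD is computed in
closed form (via the telescoping covariance between a discretized normal and
its latent) so that an OLS of the cognitive *index* on demographics recovers
the configured loadings in expectation. For the bonding dimension the
published loadings (schooling 0.070, landholding −0.070, family size 0.116,
female 1.789) are too large to hold on a mean-of-z-scores index — a female
coefficient of 1.789 exceeds the largest variance such an index can have —
which indicates the original determinants table used sum-type indices. The
bonding signal is therefore shrunk proportionally (signs and ratios preserved)
until demographics carry half the factor variance, which puts the bonding
index $R^2$ near the published 0.28. The cognitive index $R^2$ then lands
well above its published 0.048; with the mean-index convention the published
cognitive coefficient and $R^2$ cannot both hold, and the package favours
coefficient recovery, which is what the determinants regression checks.

## The experiment simulator

`simulate_experiment()` runs every group through six sessions of three rounds
(18 decisions per participant). Trees reset to 40 cards at each session start;
after every round the tree envelopes are collected, shuffled and randomly
redistributed within the group, so wounds travel with the tree. Sessions 1–2
are plain shuffling (no target): members follow the myopic path with integer
noise, and the rows are flagged `analysis_excluded` — they keep the protocol's
shape but never enter the analysis. Sessions 3–6 follow the sequence matrix;
in the default matrix (editable JSON) the public-disclosure ("reputation")
condition occupies consecutive session pairs: sessions 3–4 for sequences 3–4
and 5–6 for sequence 5. The printed source table for the sequences is
typographically ambiguous; the shipped matrix is a best reading and any matrix
passing `validate_sequence_matrix()` may be substituted.

The *calibrated* mode draws the group target and individual extraction from
the two linear structures the analysis estimates, using the published
round-level coefficients as defaults (target equation: intercept 17.407,
period shifts −2.431 and −5.299, cognitive 0.624, bonding −0.028, reputation
−0.026, plus the period interactions; extraction equation: intercept 12.358,
adherence slope 0.199, reputation −0.920, period shifts −2.962 and −6.143,
plus social-capital terms). Decisions are rounded half-up and clamped to
$[0, 40]$ and — with the default `envelope = TRUE` — to the cards remaining on
the assigned tree. Noise is a group random intercept (SD 2.0 in both
equations) plus idiosyncratic draws whose SDs (1.5 for targets, 1.9 for
extraction) were calibrated once so the fitted overall $R^2$ of the two
equations lands near the published 0.42 and 0.64; they are documented tuning
constants, not estimates.

The *mechanistic* mode replaces the target draw with explicit agents: each
member proposes the myopic benchmark of the tree in hand adjusted by their own
social capital, and the consensus is the rounded median of the five proposals.
The unanimity stage of the real protocol (proposals, five minutes of talk, a
unanimous vote) is not operationalizable from the printed description; the
median is a robust, order-free stand-in whose only role is to give the
mechanistic mode a defensible consensus rule.

### The envelope and what it does to the published coefficients

The published coefficients imply mean extraction of about
$15.8 + 12.4 + 8.6 = 36.8$ cards per 40-card session. With realistic noise,
the physical envelope therefore censors a sizeable share of round-3 decisions
(the latent demand exceeds the cards left on the tree). Embedding the
published coefficients in the full card game and re-estimating consequently
*attenuates* the extraction-equation coefficients — most visibly the
reputation effect, because privately-deciding groups are censored harder than
publicly-observed ones, and the round-3 dummy, which absorbs the common
shortfall. This is a structural property of a near-exhausted resource, not an
estimator defect: simulated from the bare linear structures
(`envelope = FALSE`, the process the estimator actually assumes), the pipeline
recovers every coefficient without bias, which is what the Monte Carlo
recovery studies assert. Users comparing simulated coefficient tables to the
published ones should keep the two regimes apart.

A related discretization note: with all noise switched off, a *rounded* target
is an exact integer function of the social-capital indices and the round, so
the adherence slope degenerates into quantization error. Identification
checks therefore use `discretize = FALSE`, where the fit reproduces the
data-generating coefficients to machine precision.

## Panel estimation

`build_panel()` arranges voting-session records at four levels (group-round,
group-session, individual-round, individual-session). Session-level outcomes
are the session *sum* of rounds — extraction over the tree's lifetime — with a
`session_stat = "mean"` switch. Round dummies reference round 1, session
dummies the first voting session; individual-level specifications include the
group target as the adherence regressor, group-level ones do not.

`fit_panel_re()` estimates a linear model with a group random intercept and
reports CR1 cluster-robust standard errors (clustered by group), with t
inference on $G-1$ degrees of freedom. Variance components come either from
Swamy–Arora feasible GLS (within and between residual variances, then
quasi-demeaning; the default) or from maximum likelihood via `lme4`, with the
GLS step and the clustered sandwich computed identically from either source —
the two agree to a few thousandths on the default designs, and the choice is
exposed because the original table notes do not say which estimator was used.
Integer outcomes are modelled as continuous, as in the source specifications,
and no multiple-testing adjustment is applied (none is applied there either).
The overall $R^2$ is the squared correlation between the outcome and the
fixed-effect linear predictor.

`gap_test()` is a Welch two-sample t test of the per-record target−extraction
gap between the public-disclosure and private scenarios (positive statistic:
the gap is wider under disclosure), with degenerate-variance inputs flagged
rather than crashed on. `summarize_rounds()` produces the per-scenario,
per-round means with the 10-wound benchmark column.

## Monte Carlo studies and problem sizes

`recovery_study()` repeats cohort generation → simulation → estimation with
replicate seeds derived from one master seed and summarizes mean estimates
against the configured truth (`recovery_summary()`). The package's own checks
use: 200 replicates of 42 groups for coefficient recovery and for the
null-calibration coverage check (social-capital effects zeroed, estimates
within two clustered SEs of zero in well over 90% of replicates), a
10,000-respondent cohort for item-moment calibration, and single runs at the
study scale for protocol fidelity. The acceptance script uses 2,500
target-equation and 400 extraction-equation replicates, sized so that Monte
Carlo error is small against the quantities' own scale. The group-level
cognitive coefficient is the noisiest recovery (a group-constant regressor
with SD ≈ 0.35 against a group random effect of SD 2 yields a per-replicate
SE above 1), which is why its replicate count is an order of magnitude larger.

## Known limitations

* Synthetic throughout: passing tests show internal consistency of the
  model–simulator–estimator chain, not agreement with the undeposited field
  data. The published observation counts (810 individual-round rows, 162
  group-round rows) cannot be reconciled with 42 groups × 4 voting sessions ×
  3 rounds, so the analysed sub-panel of the original study is unknown; the
  simulated panel uses all voting sessions.
* The cognitive-dimension index cannot simultaneously match the published
  determinants coefficient and $R^2$ under the mean-index convention (see
  above); the generator favours the coefficient.
* No learning, communication content, sanctioning behaviour, discounting,
  tree regrowth, or heterogeneous trees; reputation is a session-level flag
  with no carry-over.
* The calibrated simulator reproduces the *statistical* structure of
  target-setting; the mechanistic mode's consensus rule is a modelling choice,
  not an estimate of the real voting process.
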