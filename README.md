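# boswellia

Bioeconomic modelling and simulation of common-pool frankincense extraction.

Communal *Boswellia papyrifera* woodlands are tapped for frankincense by
harvester cooperatives holding short, insecure concessions. Whether such
communities restrain extraction — and whether social capital helps them do so —
is a classic common-pool-resource question. `boswellia` is an R package for
researchers in ecological economics and experimental resource management that
makes one such study fully reproducible on synthetic data: a tapping model
with analytic extraction optima under long- and short-term tenure, a
social-capital survey scorer, a calibrated generator of harvester cohorts, a
simulator of a framed card-game experiment with collective target voting, and
random-effects panel estimation with group-clustered errors.

## The models in brief

**Tapping model.** A tree tapped with $q_t$ wounds in period $t$ has health
$V_t = \alpha - \beta Q_t$ (cumulative wounds $Q_t$, current period included),
yields $h_t = \zeta q_t V_t$, and pays $\pi_t = P h_t - c q_t$. With the
experiment's calibration ($P=5$, $\zeta=0.7$, $\alpha=21$, $\beta=0.5$,
$c=0.5$, three periods, 40-card cap):

* long-term tenure: the lifetime optimum is the constant plan
  $q^* = (P\zeta\alpha - c)/(4\beta P\zeta) = 73/7 \approx 10.43$; the integer
  per-round benchmark is **10 wounds per round** (payoff 1140 tokens);
* short-term tenure (trees reshuffled every period): the myopic rule
  $q_t = (P\zeta(\alpha-\beta Q_{t-1}) - c)/(2\beta P\zeta)$ halves each
  period — $(20.86, 10.43, 5.21)$, integers $(21, 10, 5)$ — extracting more in
  total for a lower lifetime payoff.

**Experiment.** Groups of five play six sessions of three rounds. In the
voting sessions the group first sets a non-binding per-member extraction
target by unanimous vote; individuals then extract privately
(`voting_shuffling`) or with every decision publicly revealed
(`voting_shuffling_reputation`). The calibrated simulator draws targets and
extractions from the published round-level regression structures (target
intercept 17.407, period shifts −2.431/−5.299, cognitive coefficient 0.624;
extraction intercept 12.358, adherence slope 0.199, reputation effect −0.920,
period shifts −2.962/−6.143) with a group random intercept and calibrated
noise.

**Estimation.** `fit_panel_re()` fits the four panel specifications
(group/individual × round/session) with a group random intercept (Swamy–Arora
FGLS or ML) and CR1 cluster-robust standard errors, the convention of the
study's tables.

## Worked example

```r
library(boswellia)

# extraction benchmarks under the experiment's calibration
optimal_constant_extraction(extraction_params())
#> [1] 10.42857

# full pipeline: cohort -> simulation -> estimation
cfg <- default_run_config()
cfg$seed <- 2026L
res <- run_all(cfg, out_dir = "boswellia_run", quiet = TRUE)

res$round_summary
#>                      scenario round mean_target mean_extraction benchmark
#> 1            voting_shuffling     1        17.0           15.94        10
#> 3            voting_shuffling     2        14.7           12.46        10
#> 5            voting_shuffling     3        11.8            7.31        10
#> 2 voting_shuffling_reputation     1        17.7           15.32        10
#> 4 voting_shuffling_reputation     2        15.4           11.82        10
#> 6 voting_shuffling_reputation     3        12.4            7.43        10

summary(res$fits$eq_target_round)
#> Random-intercept panel fit (fgls)
#>   504 obs, 42 groups; sigma_u 1.878, sigma_e 1.540, overall R^2 0.449
#>   Robust standard errors clustered at group level; stars: *** 1%, ** 5%, * 10%
#>
#>                      estimate se_cluster      t        p sig
#> (Intercept)           17.0943     0.3036  56.30 1.87e-40 ***
#> reputation             0.1432     0.2025   0.71 4.84e-01
#> sc_cognitive           0.9074     0.9675   0.94 3.54e-01
#> ...
#> period2               -2.3155     0.1472 -15.73 5.75e-19 ***
#> period3               -5.1667     0.1705 -30.31 1.07e-29 ***
```

Read: simulated groups set targets around 17 wounds in round 1 — well above
the 10-wound long-term benchmark — and both targets and extraction decline as
trees degrade; extraction runs below the target, and the gap is wider when
decisions are public (`res$gap_test`, here t = 6.2). The fitted table has the
shape of the study's: period declines are sharp and precisely estimated, while
a single 42-group sample estimates the social-capital coefficients noisily —
their recovery is a Monte Carlo question (`recovery_study()`), not a
single-run one.

The methods vignette (`vignettes/boswellia-methods.Rmd`) documents the model
derivations, the generator's calibration, the envelope-censoring caveat for
the extraction equation, and all defaults.

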