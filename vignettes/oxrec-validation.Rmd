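---
title: "Validating and recalibrating a fixed-horizon reoffending risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating a fixed-horizon reoffending risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxrecval)
```

## The model and its assumptions

OxRec is a proportional-hazards risk score. An individual's predictor
values enter a linear predictor `lp = Σ βⱼ·RFⱼ`, and the probability of a
violent reoffence by horizon *t* months after release is

$$\mathrm{risk}_t = 1 - S_t^{\exp(s_t (a + lp))}$$

with baseline survival $S_t$, multiplicative recalibration slope $s_t$ and
absent-predictor adjustment $a$. The assumptions this encodes:

* **Proportional hazards** — a unit increase in the bracket multiplies the
  hazard by a constant factor at all times. The recalibration machinery
  inherits this: one Cox slope is, strictly, horizon-free.
* **Fixed-horizon binary outcomes with complete follow-up** — outcomes are
  binarised at 12 and 24 months, so 12-month events are always a subset of
  24-month events, and the AUC is the plain concordance probability rather
  than a censoring-adjusted c-index. A dropout option exists in the
  simulator for robustness studies but is off by default, matching
  complete-follow-up settings.
* **Additivity** — no interactions; age and neighbourhood deprivation enter
  as linear continuous terms by default, because only continuous summaries
  of both are available to us; the configuration format accepts per-level
  weights if a binned form is preferred.

Wholly absent predictors (education, disposable income, severe mental
disorder in the English configuration) are handled by assigning every
individual the derivation-sample average: the constant
$a = \sum_j \beta_j p_j$ over their non-reference levels. This is exactly
equivalent to folding their average effect into the baseline risk, which is
why the updated baseline survival values are so much lower than the
original ones — they also absorb a different outcome definition and base
rate.

The shipped presets carry the published constants ($S_1, S_2$, slopes, the
seven $\beta \times p$ products). All other betas are **flagged
placeholders** (`placeholder_betas` in the configuration): the development
study's weights are not reproduced here, and no test or shipped result
depends on a placeholder value. Replace them before any real-data use.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `baseline_survival` | preset | probability | published per-horizon values |
| `recalibration_slope` | preset (1 for original) | — | multiplies the bracket on the log-hazard scale |
| `category_cutoffs` | 0.3, 0.6 | probability | the published low/medium/high cut-offs are not printed; these are configurable defaults, boundary assigned upward (≥ is positive, consistent with threshold metrics) |
| `m` (imputations) | 20 | count | recommended practice for the observed missingness levels |
| `maxit` (chained cycles) | 10 | count | standard burn-in; the chains are short because only five predictors are partially missing |
| step trigger | O:E outside [1/1.1, 1.1] or slope outside [0.9, 1.1] | — | the source workflow advances "in the event of poor performance" without quantifying it; these bands are our choice and are configurable |
| thresholds | 10–50% | probability | the grid used in published threshold tables |

## What the synthetic generator emulates — and what it does not

`cohort_preset("england")` draws predictors **independently** from the
published cohort margins (92% male, median age 33, 31% incarcerated 24+
months, 63% employed, …), event times from a Weibull proportional-hazards
model matched to the published 12-/24-month event rates (31%/43%), injects
the published per-predictor missingness (from <1% on immigrant status to
15% on employment, MCAR by default), and drops the three wholly absent
predictors. `cohort_preset("sweden")` does the same for the derivation
cohort's margins and its 12%/21% event rates.

Choices made once, with rationale:

* **Independence of predictors.** Only margins are published; inventing a
  joint structure would smuggle in assumptions. An optional MAR hook lets
  missingness depend on observed fields, but predictors themselves are
  independent. Consequence: the synthetic cohort's linear predictor has
  less variance than a real cohort's (real risk factors cluster), so
  synthetic AUCs are conservative.
* **Baseline hazard.** `cohort_spec()` defaults to an exponential baseline
  (the simplest hazard consistent with fixed-horizon outcomes); the presets
  use the two-parameter Weibull from `baseline_from_rates()` because a
  single exponential cannot match a 31% 1-year and 43% 2-year rate
  simultaneously (it would imply 52% at 2 years). The fitted shape ≈ 0.6
  encodes declining hazard — most reoffending happens early, which is also
  what the published rates imply.
* **Centred hazard multiplier.** The multiplier is
  $\exp(lp - \overline{lp})$ with the margin-implied mean, so the stated
  event rates remain marginal rates rather than reference-individual rates.
* **Published-table quirks.** The Swedish incarceration-length percentages
  print as 69/16/10/4 (sum 99) and are renormalised; the 31% printed on the
  adjacent row is read as the Swedish immigrant-status prevalence. The
  English length margins are renormalised over observed rows.

A green test against this generator establishes that the *pipeline*
(scoring → imputation → metrics → recalibration) is correct in a world
whose ground truth we control. It does not establish the real-world
performance of the score: the headline real-data numbers cannot be
reproduced because the cohort is not available.

## Numerical and statistical choices

* **AUC** is the Mann–Whitney statistic with ties counted half, computed
  via midranks (O(n log n)); its interval uses the DeLong asymptotic
  variance. An O(n²) brute-force oracle exists in the test suite and the
  two are required to agree to 1e-12.
* **"Calibration-in-the-large"** is reported in *both* senses, labelled:
  `oe_ratio` (observed/predicted event ratio, the definition used in the
  validation this package models, 1 = ideal) and `citl` intercept (the
  conventional logit-offset intercept, 0 = ideal). The two conventions are
  easy to confuse — and one published figure even labels the ratio E:O —
  so every report states the orientation.
* **Recalibration** defaults to a Cox fit on time-to-event data (per the
  published validation protocol), giving one slope for both horizons. A
  `binary` mode fits per-horizon cloglog models, reproducing the structure
  of the published updated-model table, which prints two horizon-specific
  slopes; for proportional-hazards data both modes recover the same truth,
  and the tests check this. How one Cox fit yields two distinct printed
  slopes is not stated in the source; both modes are provided and reports
  say which was used.
* **Updated baselines are root-solved**, not read off the survival-curve
  estimator: given the fitted slope $b$, $S_t$ solves
  $\operatorname{mean}_i\!\left(1 - S_t^{\exp(b x_i)}\right) = \bar{y}_t$
  (monotone in $S_t$; bisection to 1e-12). This makes post-update mean
  calibration exact by construction, which is the contract the pipeline's
  invariants test.
* **Imputation** uses chained equations with logistic conditional models
  (approximate-posterior coefficient draws via the observed information)
  and a continuation-ratio stack of logistic fits for multi-level factors.
  Outcome indicators are always included as covariates — excluding them
  biases predictor–outcome associations toward zero. Degenerate fits fall
  back to marginal draws rather than failing an entire imputation.
* **Pooling** follows Rubin's rules. AUC is pooled on its original scale
  with the DeLong variance; the O:E ratio on the log scale; fitted
  recalibration parameters as means across imputations. Whether the source
  pooled by Rubin or stacked data is unstated; Rubin is the default here
  and per-imputation results are retained in the audit log.
* **Ties and boundaries.** A score equal to a threshold or cut-off is
  test-positive / the higher category, everywhere. Decile groups break
  score ties by stable row order so group sizes are exactly equal.
* **Undefined quantities stay undefined.** PPV with no predicted positives
  is `NA`, not 0; a constant-outcome calibration fit is returned flagged
  (`converged = FALSE`) rather than as numbers.

## Known limitations

* With the published England slopes ($s_1 = 0.6745 > s_2 = 0.5372$) the
  1- and 2-year risk curves cross at bracket ≈ 2.27 — a region where
  1-year risk already exceeds 97%, far beyond any realistic individual,
  but formally the 2-year-≥-1-year ordering is not global under
  horizon-specific slopes. The common-slope (Cox) mode does not have this
  artefact.
* The generator draws predictors independently (see above); calibration
  curves from it are smoother than real ones.
* Placeholder betas make the presets structurally faithful but numerically
  incomplete outside the published constants; synthetic studies set their
  own truth, so nothing here depends on the placeholders.
* MNAR missingness and congeniality of the imputation models are out of
  scope; the MAR hook conditions only on fully observed fields.
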