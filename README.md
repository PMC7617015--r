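# oxrecval

Tools for externally validating and recalibrating **OxRec**, a
proportional-hazards risk score that estimates the probability of violent
reoffending within 12 and 24 months of release from prison. The package is
aimed at researchers running external validations of clinical prediction
models in criminal-justice or epidemiological settings: it implements the
score itself, the full incremental validation workflow, and a synthetic
cohort generator so that every stage can be exercised without access to
real criminal-justice data (which is not publicly shareable).

## The model

For an individual with linear predictor `lp = Σ βⱼ·RFⱼ` over 14
sociodemographic, criminal-history and clinical risk factors, the risk of a
violent reoffence by horizon *t* ∈ {12, 24} months is

```
risk_t = 1 − S_t ^ exp( s_t · (a + lp) )
```

* `S_t` — baseline survival at the horizon (probability of no reoffence for
  an individual whose bracket `a + lp` is zero);
* `s_t` — a multiplicative recalibration slope (1 in the original
  parameterisation);
* `a` — an adjustment constant absorbing predictors that are wholly
  unavailable in the validation setting: each absent predictor contributes
  `Σ βⱼ·pⱼ`, its weights times its derivation-sample prevalences, which is
  equivalent to folding its average effect into the baseline risk.

Two configuration presets ship with the package: `sweden_original`
(S₁ = 0.7992, S₂ = 0.6775, slopes 1, no absent predictors) and
`england_updated` (S₁ = 0.4643, S₂ = 0.3509, slopes 0.6745 / 0.5372, with
education, disposable income and severe mental disorder absorbed through
`a ≈ 0.3255`). Betas not published alongside these constants are shipped as
clearly flagged placeholders — see `?oxrec_preset`.

The validation workflow is incremental: **(1)** simple validation — apply
the original model unchanged and compute discrimination (AUC with DeLong
intervals, sensitivity/specificity/PPV/NPV with Wilson intervals at a
threshold grid) and calibration (observed:expected ratio, calibration slope
and intercept, Brier score, decile calibration); **(2)** if miscalibrated,
update the baseline risk and fit a multiplicative recalibration slope (a
Cox model on the original bracket, or per-horizon complementary-log-log
fits); **(3)** compare revalidated per-predictor coefficients against the
originals — re-estimation is reported, never applied. Partially missing
predictors are handled with multiple imputation by chained equations
(default m = 20) and Rubin pooling.

## Worked example

```r
library(oxrecval)

# a synthetic English-style cohort: 1770 releases, ~31%/43% reoffend by
# 12/24 months, published missingness rates, three absent predictors
spec <- cohort_preset("england", n = 1770, seed = 42)
cohort <- simulate_cohort(spec)

model <- oxrec_preset("england_updated")
res <- validate_incremental(cohort, model, m = 5, seed = 42)
res$step_reached
#> [1] 2
```

Step 1 found the model miscalibrated on this cohort (the generator's world
is not the world the preset was calibrated to — that is the point), so the
update step ran. Pooled across the 5 imputations:

| horizon | pre AUC | pre O:E | pre slope | post O:E | updated S_t | fitted slope |
|---|---|---|---|---|---|---|
| 12 m | 0.671 | 0.52 | 1.105 | 1.000 | 0.7733 | 0.9804 |
| 24 m | 0.680 | 0.62 | 1.366 | 1.000 | 0.6683 | 0.9804 |

O:E (observed:expected) of 0.52 means the preset over-predicted risk about
two-fold here; after updating, mean predicted risk equals the observed rate
by construction (O:E = 1.000) while the AUC is unchanged, since a positive
recalibration slope is a monotone transform. `res$updated_model` is a
complete configuration that can be written back with
`write_oxrec_config()`.

Scoring alone:

```r
scored <- score_cohort(na.omit(cohort), model)
head(scored[, c("lp", "risk_12m", "risk_24m", "category_24m")])
```

## Command line

```sh
Rscript inst/cli/oxrec.R simulate --preset england --n 1770 --seed 1 --out cohort.csv
Rscript inst/cli/oxrec.R validate --input cohort.csv --preset england_updated \
    --m 20 --seed 1 --out results/validation
Rscript inst/cli/oxrec.R score --input imputed.csv --preset england_updated --out scored.csv
```

Subcommands: `simulate`, `score`, `impute`, `validate`, `recalibrate`,
`report`. Every output carries a provenance sidecar (seed, configuration
hash, package version).

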