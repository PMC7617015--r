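# Scoring core: linear predictor, adjustment constant, risk transform,
# categories.

test_that("linear predictor sums active-level betas", {
  coefs <- toy_coefs()
  ref_profile <- data.frame(previous_violent_crime = "no",
                            drug_use_disorder = "no",
                            incarceration_length = "<6m",
                            age_at_release = 0)
  expect_identical(linear_predictor(ref_profile, coefs), 0)

  one <- ref_profile
  one$previous_violent_crime <- "yes"
  expect_identical(linear_predictor(one, coefs), 0.7)

  set.seed(41)
  for (i in 1:25) {
    pr <- random_toy_profile()
    expect_equal(linear_predictor(pr, coefs), lp_oracle(pr, coefs),
                 tolerance = 1e-12)
  }
})

test_that("linear predictor rejects unknown levels and missing markers", {
  coefs <- toy_coefs()
  bad <- data.frame(previous_violent_crime = "maybe", drug_use_disorder = "no",
                    incarceration_length = "<6m", age_at_release = 30)
  expect_error(linear_predictor(bad, coefs), "unknown level 'maybe'")
  na <- data.frame(previous_violent_crime = NA, drug_use_disorder = "no",
                   incarceration_length = "<6m", age_at_release = 30)
  expect_error(linear_predictor(na, coefs), "imputation")
})

test_that("absent predictors contribute through the adjustment constant only", {
  model <- oxrec_preset("england_updated")
  # no education / income / severe-disorder columns needed for the lp
  pr <- england_complete(5, seed = 3, model)
  lp <- linear_predictor(pr, model$coefs)
  expect_length(lp, 5)
  expect_false("education" %in% names(pr))
})

test_that("adjustment constant matches independent arithmetic", {
  expect_identical(adjustment_constant(toy_coefs()), 0)

  # the seven published beta-by-prevalence products, summed independently
  products <- c(-0.1838 * 0.4263, -0.4282 * 0.0569, 0.5251 * 0.0523,
                0.5176 * 0.4903, 0.3712 * 0.3738, 0.4509 * 0.0109,
                0.0953 * 0.0347)
  model <- oxrec_preset("england_updated")
  expect_equal(adjustment_constant(model$coefs), sum(products),
               tolerance = 1e-12)
  expect_equal(adjustment_constant(model$coefs), 0.3255, tolerance = 5e-5)

  single <- oxrec_coefs(
    beta = list(any_severe_mental_disorder = c(yes = 2.0)),
    absent = "any_severe_mental_disorder",
    absent_prevalence = list(any_severe_mental_disorder = c(yes = 0.5)))
  expect_identical(adjustment_constant(single), 1.0)

  expect_error(oxrec_coefs(
    beta = list(any_severe_mental_disorder = c(yes = 2.0)),
    absent = "any_severe_mental_disorder",
    absent_prevalence = list(any_severe_mental_disorder = c(yes = 1.4))),
    "\\[0, 1\\]")
})

test_that("risk transform reproduces 1 - S_t at zero bracket", {
  eng <- oxrec_preset("england_updated")
  swe <- oxrec_preset("sweden_original")
  a <- eng$spec$adjustment
  expect_equal(risk_probability(-a, eng$spec, 12), 1 - 0.4643, tolerance = 1e-12)
  expect_equal(risk_probability(-a, eng$spec, 24), 1 - 0.3509, tolerance = 1e-12)
  expect_equal(risk_probability(0, swe$spec, 12), 1 - 0.7992, tolerance = 1e-12)
  expect_equal(risk_probability(0, swe$spec, 24), 1 - 0.6775, tolerance = 1e-12)
  # direct closed-form evaluation at lp = 0 for the updated model
  expect_equal(risk_probability(0, eng$spec, 12),
               1 - 0.4643^exp(0.6745 * a), tolerance = 1e-12)
  expect_equal(risk_probability(0, eng$spec, 12), 0.6154, tolerance = 1e-4)
  expect_error(risk_probability(0, eng$spec, 18), "horizon")
})

test_that("risk is strictly increasing in lp and ordered across horizons", {
  eng <- oxrec_preset("england_updated")
  swe <- oxrec_preset("sweden_original")
  grid <- seq(-4, 4, by = 0.05)
  expect_true(all(diff(risk_probability(grid, eng$spec, 12)) > 0))
  expect_true(all(diff(risk_probability(grid, swe$spec, 24)) > 0))
  # with a common slope (original parameterisation) 2-year risk dominates
  # 1-year risk everywhere
  lp <- seq(-2, 2, by = 0.1)
  expect_true(all(risk_probability(lp, swe$spec, 24) >=
                    risk_probability(lp, swe$spec, 12)))
  # the updated parameterisation has horizon-specific slopes (0.6745 vs
  # 0.5372), so the horizons cross near bracket x ~ 2.27 (lp ~ 1.94, where
  # 1-year risk already exceeds 97%); ordering holds below that point
  lp <- seq(-2, 1.9, by = 0.1)
  expect_true(all(risk_probability(lp, eng$spec, 24) >=
                    risk_probability(lp, eng$spec, 12)))
  expect_lt(risk_probability(2.5, eng$spec, 24),
            risk_probability(2.5, eng$spec, 12))
})

test_that("updated formula with slope 1 and adjustment 0 is the original formula", {
  spec <- oxrec_spec(c("12" = 0.7992, "24" = 0.6775))
  lp <- seq(-3, 3, by = 0.01)
  expect_identical(risk_probability(lp, spec, 12), 1 - 0.7992^exp(lp))
})

test_that("scoring is pure", {
  model <- oxrec_preset("england_updated")
  pr <- england_complete(50, seed = 9, model)
  expect_identical(score_cohort(pr, model), score_cohort(pr, model))
})

test_that("risk categories follow the boundary-up convention", {
  cut <- c(0.2, 0.5)
  expect_identical(risk_category(0, cut), "low")
  expect_identical(risk_category(0.5, cut), "high")
  expect_identical(risk_category(0.2, cut), "medium")
  # exhaustive comparison with a brute-force interval lookup
  probs <- seq(0, 1, by = 0.005)
  brute <- vapply(probs, function(p) {
    if (p < cut[1]) "low" else if (p < cut[2]) "medium" else "high"
  }, "")
  expect_identical(risk_category(probs, cut), brute)
  expect_error(risk_category(0.5, c(0.5, 0.4)), "increasing")
})

test_that("score_cohort appends lp, risks and categories", {
  model <- oxrec_preset("england_updated")
  tab <- england_complete(20, seed = 2, model)
  sc <- score_cohort(tab, model)
  expect_true(all(c("lp", "risk_12m", "risk_24m", "category_12m",
                    "category_24m") %in% names(sc)))
  expect_identical(sc$risk_12m, risk_probability(sc$lp, model$spec, 12))
  expect_true(all(sc$category_12m %in% c("low", "medium", "high")))
})
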