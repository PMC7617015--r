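# Incremental validation: simple validation, baseline update, coefficient
# comparison.

test_that("a cohort drawn from the model itself validates cleanly and gates at step 1", {
  model <- oxrec_preset("england_updated")
  tab <- bernoulli_world(20000, seed = 51, model)
  rep1 <- simple_validation(tab, model)
  for (h in names(rep1)) {
    expect_lt(abs(rep1[[h]]$oe_ratio - 1), 0.05)
    expect_lt(abs(rep1[[h]]$calibration$slope - 1), 0.06)
  }
  out <- update_model(tab, model, mode = "binary")
  expect_identical(out$step_reached, 1L)
  expect_identical(out$model, model)  # spec returned unmodified
})

test_that("simple validation reports the constructed O:E inflation", {
  model <- oxrec_preset("sweden_original")
  spec <- cohort_spec(n = 20000, margins = margins_preset("sweden"),
                      true_coefs = model$coefs,
                      baseline = baseline_from_rates(0.12, 0.21), seed = 52)
  comp <- simulate_cohort(spec, inject = FALSE)
  scored <- score_cohort(comp, model)
  set.seed(520)
  # events at 2.5x the predicted probability
  comp$outcome_12m <- as.integer(runif(20000) < pmin(scored$risk_12m * 2.5, 1))
  comp$outcome_24m <- pmax(comp$outcome_12m,
                           as.integer(runif(20000) < pmin(scored$risk_24m * 1.2, 1)))
  rep1 <- simple_validation(comp, model)
  expect_equal(rep1[["12"]]$oe_ratio,
               mean(comp$outcome_12m) / mean(scored$risk_12m),
               tolerance = 1e-12)
  expect_gt(rep1[["12"]]$oe_ratio, 2)
  expect_error(simple_validation(comp[0, ], model), "empty")
})

test_that("cox recalibration recovers a known slope and restores mean calibration", {
  model <- oxrec_preset("england_updated")
  world <- make_slope_world(20000, true_slope = 0.65, seed = 53, model)
  out <- update_model(world, model, mode = "cox")
  expect_identical(out$step_reached, 2L)
  expect_lt(abs(out$fitted_slope[["12"]] - 0.65), 0.05)
  expect_identical(out$fitted_slope[["12"]], out$fitted_slope[["24"]])
  for (h in c("12", "24")) {
    expect_gt(out$post[[h]]$oe_ratio, 0.97)
    expect_lt(out$post[[h]]$oe_ratio, 1.03)
    # mean calibration within 0.5 percentage points by construction
    expect_lt(abs(out$post[[h]]$mean_predicted - out$post[[h]]$observed_rate),
              0.005)
    # monotone update leaves discrimination unchanged
    expect_identical(out$post[[h]]$auc$auc, out$pre[[h]]$auc$auc)
  }
})

test_that("binary-mode recalibration fits horizon-specific slopes", {
  model <- oxrec_preset("england_updated")
  world <- make_slope_world(20000, true_slope = 0.65, seed = 54, model)
  out <- update_model(world, model, mode = "binary")
  expect_identical(out$step_reached, 2L)
  # the generating world is proportional hazards, so both horizon slopes
  # should recover the same truth
  expect_lt(abs(out$fitted_slope[["12"]] - 0.65), 0.07)
  expect_lt(abs(out$fitted_slope[["24"]] - 0.65), 0.07)
  for (h in c("12", "24")) {
    expect_lt(abs(out$post[[h]]$oe_ratio - 1), 0.03)
  }
})

test_that("recalibrating data from the original survival model recovers it", {
  model <- oxrec_preset("england_updated")
  comp <- england_complete(20000, seed = 55, model)
  x <- model$spec$adjustment + linear_predictor(comp, model$coefs)
  # event times from the model's own survival curve: Weibull through the
  # configured (S_12, S_24) with covariate effect slope * x
  b <- baseline_from_rates(1 - model$spec$baseline_survival[["12"]],
                           1 - model$spec$baseline_survival[["24"]])
  set.seed(550)
  tE <- b$scale * (rexp(20000) / exp(model$spec$recalibration_slope[["12"]] * x))^(1 / b$shape)
  comp$event_time <- pmin(tE, 24)
  comp$event <- as.integer(tE <= 24)
  comp$outcome_12m <- as.integer(tE <= 12)
  comp$outcome_24m <- as.integer(tE <= 24)
  out <- update_model(comp, model, mode = "cox", force = TRUE)
  expect_lt(abs(out$fitted_slope[["12"]] - 0.6745), 0.05)
  expect_lt(abs(out$updated_baseline[["12"]] - 0.4643), 0.02)
  expect_lt(abs(out$updated_baseline[["24"]] - 0.3509), 0.02)
})

test_that("update errors without events and flags non-positive slopes", {
  model <- oxrec_preset("england_updated")
  comp <- england_complete(200, seed = 56, model)
  comp$event_time <- rep(24, 200); comp$event <- 0L
  comp$outcome_12m <- 0L; comp$outcome_24m <- 0L
  expect_error(update_model(comp, model, mode = "cox", force = TRUE),
               "no events")
})

test_that("coefficient comparison flags only genuinely shifted predictors", {
  model <- oxrec_preset("england_updated")
  spec <- cohort_spec(n = 20000, margins = margins_preset("england"),
                      true_coefs = model$coefs,
                      absent_fields = model$coefs$absent, seed = 57)
  tab <- simulate_cohort(spec, inject = FALSE)
  cmp <- compare_coefficients(tab, model$coefs)
  expect_true(all(c("predictor", "original", "revalidated", "flagged") %in% names(cmp)))
  ok <- !is.na(cmp$flagged)
  expect_gte(mean(!cmp$flagged[ok]), 0.9)

  # double one beta in the generating truth; the comparison against the
  # original weights must flag that predictor
  coefs2 <- model$coefs
  coefs2$beta$previous_violent_crime <- c(yes = 1.0)
  spec2 <- cohort_spec(n = 20000, margins = margins_preset("england"),
                       true_coefs = coefs2,
                       absent_fields = model$coefs$absent, seed = 58)
  tab2 <- simulate_cohort(spec2, inject = FALSE)
  cmp2 <- compare_coefficients(tab2, model$coefs)
  row <- cmp2[cmp2$predictor == "previous_violent_crime", ]
  expect_true(isTRUE(row$flagged))

  tab$event <- 0L
  expect_error(compare_coefficients(tab, model$coefs), "outcome variation")
})

test_that("pooled incremental validation runs end to end on incomplete data", {
  model <- oxrec_preset("england_updated")
  spec <- cohort_preset("england", n = 1200, seed = 59)
  tab <- simulate_cohort(spec)
  res <- validate_incremental(tab, model, m = 2, seed = 60)
  expect_identical(res$step_reached, 2L)
  expect_identical(res$m, 2L)
  for (h in c("12", "24")) {
    expect_lt(abs(res$post[[h]]$oe_ratio - 1), 0.05)
    expect_true(is.finite(res$pre[[h]]$auc$se))
  }
  expect_s3_class(res$updated_model, "oxrec_model")
  expect_true(any(grepl("FIRED", res$audit)))
})
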