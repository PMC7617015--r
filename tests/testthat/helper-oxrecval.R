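# Shared fixtures, all built in code.

# Small synthetic coefficient set over a handful of predictors.
toy_coefs <- function() {
  oxrec_coefs(
    beta = list(
      previous_violent_crime = c(yes = 0.7),
      drug_use_disorder = c(yes = 0.4),
      incarceration_length = c("6-12m" = 0.1, "12-24m" = 0.25, ">=24m" = 0.45),
      age_at_release = -0.015
    ),
    reference_levels = c(previous_violent_crime = "no", drug_use_disorder = "no",
                         incarceration_length = "<6m")
  )
}

toy_spec <- function(adjustment = 0) {
  oxrec_spec(c("12" = 0.69, "24" = 0.55),
             c("12" = 1, "24" = 1), adjustment = adjustment)
}

# Draw a random profile over the toy predictors.
random_toy_profile <- function() {
  data.frame(
    previous_violent_crime = sample(c("no", "yes"), 1),
    drug_use_disorder = sample(c("no", "yes"), 1),
    incarceration_length = sample(c("<6m", "6-12m", "12-24m", ">=24m"), 1),
    age_at_release = runif(1, 18, 70),
    stringsAsFactors = FALSE
  )
}

# Independent per-level summation oracle for the linear predictor.
lp_oracle <- function(profile, coefs) {
  total <- 0
  schema <- oxrec_predictors()
  for (p in names(coefs$beta)) {
    b <- coefs$beta[[p]]
    if (schema[[p]]$type == "continuous") {
      total <- total + b * profile[[p]]
    } else {
      lvl <- as.character(profile[[p]])
      for (l in names(b)) if (identical(lvl, l)) total <- total + b[[l]]
    }
  }
  total
}

# Complete (no missingness) cohort drawn from the England margins.
england_complete <- function(n, seed, model = oxrec_preset("england_updated")) {
  spec <- cohort_spec(n = n, margins = margins_preset("england"),
                      true_coefs = model$coefs,
                      absent_fields = model$coefs$absent, seed = seed)
  simulate_cohort(spec, inject = FALSE)
}

# World with a known multiplicative recalibration slope: event times from
# an exponential baseline with hazard multiplier exp(slope * (x - mean x)),
# where x is the model's bracket (adjustment + linear predictor).  The
# baseline rate 0.05/month inflates event rates well above the model's
# predictions, so step-1 validation is miscalibrated by construction.
make_slope_world <- function(n, true_slope, seed, model, lam0 = 0.05) {
  comp <- england_complete(n, seed, model)
  x <- model$spec$adjustment + linear_predictor(comp, model$coefs)
  set.seed(seed + 1000L)
  t_event <- rexp(n) / (lam0 * exp(true_slope * (x - mean(x))))
  comp$event_time <- pmin(t_event, 24)
  comp$event <- as.integer(t_event <= 24)
  comp$outcome_12m <- as.integer(t_event <= 12)
  comp$outcome_24m <- as.integer(t_event <= 24)
  comp
}

# World whose outcomes are drawn exactly from the model's own predicted
# risks (nested across horizons), so the model is perfectly calibrated.
bernoulli_world <- function(n, seed, model) {
  comp <- england_complete(n, seed, model)
  scored <- score_cohort(comp, model)
  set.seed(seed + 5000L)
  r12 <- scored$risk_12m
  r24 <- scored$risk_24m
  comp$outcome_12m <- as.integer(runif(n) < r12)
  extra <- (r24 - r12) / (1 - r12)
  comp$outcome_24m <- pmax(comp$outcome_12m, as.integer(runif(n) < extra))
  comp
}
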