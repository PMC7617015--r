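# Synthetic cohort generator.

null_coefs <- function() {
  oxrec_coefs(beta = list(previous_violent_crime = c(yes = 0)),
              reference_levels = c(previous_violent_crime = "no"))
}

test_that("null model with 12-month baseline survival 0.69 yields ~31% events", {
  spec <- cohort_spec(n = 1000, margins = margins_preset("england"),
                      true_coefs = null_coefs(),
                      baseline = baseline_from_rates(0.31),
                      absent_fields = c("education", "disposable_income",
                                        "any_severe_mental_disorder"),
                      seed = 101)
  tab <- simulate_cohort(spec, inject = FALSE)
  expect_equal(mean(tab$outcome_12m), 0.31, tolerance = 0.03 / 0.31)
  expect_true(all(tab$event_time <= 24))
})

test_that("simulation is deterministic given the seed", {
  spec <- cohort_preset("england", n = 300, seed = 77)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  spec2 <- cohort_preset("england", n = 300, seed = 78)
  expect_false(identical(simulate_cohort(spec), simulate_cohort(spec2)))
})

test_that("12-month events are nested in 24-month events", {
  for (s in 1:3) {
    tab <- simulate_cohort(cohort_preset("england", n = 500, seed = s))
    expect_true(all(tab$outcome_24m >= tab$outcome_12m))
  }
})

test_that("simulated level frequencies recover the margins within 3 SE", {
  n <- 10000
  spec <- cohort_preset("england", n = n, seed = 202)
  tab <- simulate_cohort(spec, inject = FALSE)
  for (p in names(spec$margins)) {
    m <- spec$margins[[p]]
    if (is.list(m)) next
    for (lev in names(m)) {
      phat <- mean(tab[[p]] == lev)
      se <- sqrt(m[[lev]] * (1 - m[[lev]]) / n)
      expect_lt(abs(phat - m[[lev]]), 3 * se + 1e-9,
                label = sprintf("|%.4f - %.4f| for %s=%s", phat, m[[lev]], p, lev))
    }
  }
})

test_that("higher true linear predictor means higher event rate", {
  coefs <- oxrec_coefs(beta = list(previous_violent_crime = c(yes = 1.0)),
                       reference_levels = c(previous_violent_crime = "no"))
  margins <- margins_preset("england")
  margins$previous_violent_crime <- c(no = 0.5, yes = 0.5)
  spec <- cohort_spec(n = 10000, margins = margins, true_coefs = coefs,
                      baseline = baseline_from_rates(0.31),
                      absent_fields = c("education", "disposable_income",
                                        "any_severe_mental_disorder"),
                      seed = 303)
  tab <- simulate_cohort(spec, inject = FALSE)
  hi <- mean(tab$outcome_12m[tab$previous_violent_crime == "yes"])
  lo <- mean(tab$outcome_12m[tab$previous_violent_crime == "no"])
  expect_gt(hi, lo)
})

test_that("degenerate margins are rejected", {
  expect_error(cohort_spec(n = 10, margins = list(employment = c(no = 0, yes = 0)),
                           true_coefs = null_coefs(), seed = 1),
               "degenerate")
  expect_error(cohort_spec(n = 10, margins = list(employment = c(no = 0.6, yes = 0.6)),
                           true_coefs = null_coefs(), seed = 1),
               "sum to 1")
})

test_that("missingness injection hits the configured rates", {
  spec <- cohort_preset("england", n = 10000, seed = 404)
  spec$missingness$rates["employment"] <- 0.15
  tab <- simulate_cohort(spec)
  expect_equal(mean(is.na(tab$employment)), 0.15, tolerance = 0.01 / 0.15)
  # all-zero rates leave the table unchanged
  spec0 <- cohort_preset("england", n = 500, seed = 405)
  spec0$missingness$rates[] <- 0
  tab0 <- simulate_cohort(spec0)
  expect_false(anyNA(tab0[setdiff(names(tab0), c("education"))]))
})

test_that("MCAR flags are independent of the outcome", {
  spec <- cohort_preset("england", n = 10000, seed = 505)
  tab <- simulate_cohort(spec)
  flag <- as.integer(is.na(tab$employment))
  expect_lt(abs(cor(flag, tab$outcome_12m)), 0.05)
})

test_that("MAR mechanism validates its conditioning fields", {
  spec <- cohort_preset("england", n = 2000, seed = 606)
  spec$missingness$mechanism <- list(
    employment = list(type = "MAR", dependent_on = "civil_status"))
  # civil_status is itself subject to missingness -> configuration error
  expect_error(simulate_cohort(spec), "themselves")

  spec$missingness$rates <- c(employment = 0.15)
  spec$missingness$mechanism <- list(
    employment = list(type = "MAR", dependent_on = "age_at_release",
                      strength = 1))
  tab <- simulate_cohort(spec)
  expect_equal(mean(is.na(tab$employment)), 0.15, tolerance = 0.25)
  # MAR: missingness rate varies with the conditioning field
  young <- tab$age_at_release < stats::median(tab$age_at_release)
  expect_false(isTRUE(all.equal(mean(is.na(tab$employment[young])),
                                mean(is.na(tab$employment[!young])),
                                tolerance = 0.01)))
})

test_that("cohort files carry a metadata sidecar", {
  tab <- simulate_cohort(cohort_preset("england", n = 50, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_identical(meta$seed, 7L)
  expect_identical(meta$n, 50L)
  expect_true(nzchar(meta$spec_hash))
})
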