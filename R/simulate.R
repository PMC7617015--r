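# Synthetic cohort generator: seeded predictor draws from configurable
# margins, proportional-hazards event times, fixed-horizon binary outcomes
# and injected missingness.  Stands in for unavailable criminal-justice
# cohorts at desk scale.

#' Marginal predictor distributions for the shipped cohort presets
#'
#' \code{"england"} mirrors a validation cohort of people released from
#' prison in England (92\% male, median age 33, 31\% incarcerated 24+
#' months, 63\% employed, education / disposable income / severe mental
#' disorder unavailable); \code{"sweden"} mirrors the original derivation
#' cohort (93\% male, median age 36, 69\% incarcerated under 6 months, 25\%
#' employed, all predictors observed).  Note the England source table
#' prints incarceration-length percentages that sum to 97\% because of
#' partial missingness; they are renormalised over observed rows here, and
#' the Swedish immigrant-status row (31\%) is read as belonging to the
#' immigrant predictor, not the length block.
#'
#' Continuous predictors: age is log-normal (matched to the printed
#' median/IQR, truncated at 18); neighbourhood deprivation is normal
#' (matched to the printed median/IQR).
#'
#' @param name preset name.
#' @return named list of per-predictor margin descriptions.
#' @export
margins_preset <- function(name = c("england", "sweden")) {
  name <- match.arg(name)
  bin <- function(p) c(no = 1 - p, yes = p)
  if (name == "england") {
    list(
      gender = c(male = 0.92, female = 0.08),
      # median 33, IQR 27-40 -> meanlog log(33), sdlog log(40/27)/1.349
      age_at_release = list(dist = "lognormal", meanlog = log(33),
                            sdlog = log(40 / 27) / 1.349, min = 18),
      immigrant_status = bin(0.07),
      incarceration_length = c("<6m" = 658, "6-12m" = 253, "12-24m" = 269,
                               ">=24m" = 545) / (658 + 253 + 269 + 545),
      violent_index_offence = bin(0.34),
      previous_violent_crime = bin(0.62),
      civil_status = c(unmarried = 1299, other = 321) / (1299 + 321),
      employment = bin(0.63),
      # median 0.67, IQR 0.13-1.04
      neighbourhood_deprivation = list(dist = "normal", mean = 0.67,
                                       sd = (1.04 - 0.13) / 1.349),
      alcohol_use_disorder = bin(0.14),
      drug_use_disorder = bin(0.36),
      any_mental_disorder = bin(0.35)
    )
  } else {
    list(
      gender = c(male = 0.93, female = 0.07),
      age_at_release = list(dist = "lognormal", meanlog = log(36),
                            sdlog = log(46 / 27) / 1.349, min = 18),
      immigrant_status = bin(0.31),
      # printed percentages sum to 99 (rounding); renormalised
      incarceration_length = c("<6m" = 0.69, "6-12m" = 0.16, "12-24m" = 0.10,
                               ">=24m" = 0.04) / 0.99,
      violent_index_offence = bin(0.38),
      previous_violent_crime = bin(0.53),
      civil_status = c(unmarried = 0.65, other = 0.35),
      education = c("<9y" = 0.48, "9-11y" = 0.46, ">=12y" = 0.06),
      employment = bin(0.25),
      disposable_income = c(negative = 0.01, zero = 0.06, low = 0.53,
                            medium = 0.40, high = 0.01) / 1.01,
      neighbourhood_deprivation = list(dist = "normal", mean = 0.39,
                                       sd = (1.47 + 1.18) / 1.349),
      alcohol_use_disorder = bin(0.22),
      drug_use_disorder = bin(0.23),
      any_mental_disorder = bin(0.22),
      any_severe_mental_disorder = bin(0.03)
    )
  }
}

#' Baseline hazard from fixed-horizon event rates
#'
#' With only a 12-month event rate, returns an exponential baseline; with
#' both 12- and 24-month rates, returns the Weibull baseline that matches
#' both (shape below 1 when early hazard dominates).
#'
#' @param rate_12m probability of an event within 12 months at zero linear
#'   predictor.
#' @param rate_24m optional 24-month event probability.
#' @return a baseline description list (\code{dist}, parameters in months).
#' @export
baseline_from_rates <- function(rate_12m, rate_24m = NULL) {
  stopifnot(rate_12m > 0, rate_12m < 1)
  if (is.null(rate_24m)) {
    return(list(dist = "exponential", rate = -log(1 - rate_12m) / 12))
  }
  stopifnot(rate_24m > rate_12m, rate_24m < 1)
  shape <- log(log(1 - rate_24m) / log(1 - rate_12m)) / log(2)
  scale <- 12 / (-log(1 - rate_12m))^(1 / shape)
  list(dist = "weibull", shape = shape, scale = scale)
}

#' Specify a synthetic cohort
#'
#' @param n cohort size.
#' @param margins per-predictor margins as from \code{\link{margins_preset}};
#'   predictors without a margin and not declared absent default to their
#'   reference level.
#' @param true_coefs \code{\link{oxrec_coefs}} generating the event-time
#'   hazard via the multiplier \eqn{\exp(lp - \bar{lp})}.
#' @param baseline baseline hazard description
#'   (\code{\link{baseline_from_rates}}); applies to an individual at the
#'   centred linear predictor.
#' @param censor_months administrative censoring (default 24).
#' @param missingness named list: \code{rates} (per-predictor missingness
#'   probability) and optional \code{mechanism} — \code{"MCAR"} (default) or
#'   \code{list(type = "MAR", dependent_on = <observed fields>, strength)}
#'   per predictor.
#' @param absent_fields predictors wholly unavailable (ABSENT on all rows).
#' @param dropout_rate optional probability of loss to follow-up before 24
#'   months (default 0: complete follow-up).
#' @param center_lp subtract the margin-implied mean linear predictor from
#'   the hazard multiplier so the baseline rates stay marginal (default
#'   TRUE).
#' @param seed integer seed; every random draw for the cohort flows from it.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n, margins, true_coefs, baseline = baseline_from_rates(0.31),
                        censor_months = 24, missingness = list(rates = numeric()),
                        absent_fields = character(), dropout_rate = 0,
                        center_lp = TRUE, seed = 1L) {
  stopifnot(n >= 1, inherits(true_coefs, "oxrec_coefs"))
  schema <- oxrec_predictors()
  for (p in names(margins)) {
    m <- margins[[p]]
    if (is.null(schema[[p]])) stop("margin given for unknown predictor '", p, "'")
    if (is.numeric(m) && !is.list(m)) {
      if (any(m < 0)) stop("negative margin probability for '", p, "'")
      if (all(m == 0)) stop("degenerate margins for '", p, "': all levels have probability 0")
      if (abs(sum(m) - 1) > 1e-6) stop("margins for '", p, "' must sum to 1")
      bad <- setdiff(names(m), schema[[p]]$levels)
      if (length(bad)) stop("margin level(s) unknown for '", p, "': ",
                            paste(bad, collapse = ", "))
    }
  }
  rates <- missingness$rates %||% numeric()
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  structure(list(n = as.integer(n), margins = margins, true_coefs = true_coefs,
                 baseline = baseline, censor_months = censor_months,
                 missingness = missingness, absent_fields = absent_fields,
                 dropout_rate = dropout_rate, center_lp = center_lp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort spec preset
#'
#' Bundles \code{\link{margins_preset}} margins, the matching model preset's
#' coefficients as simulation truth, a Weibull baseline matched to the
#' preset's published 12-/24-month violent-reoffending rates (31\%/43\% for
#' England, 12\%/21\% for the Swedish derivation cohort), and — for England —
#' the published per-predictor missingness rates and wholly absent fields.
#'
#' @param name \code{"england"} or \code{"sweden"}.
#' @param n cohort size (default: the preset cohort's size).
#' @param seed integer seed.
#' @return a \code{\link{cohort_spec}}.
#' @export
cohort_preset <- function(name = c("england", "sweden"), n = NULL, seed = 1L) {
  name <- match.arg(name)
  if (name == "england") {
    model <- oxrec_preset("england_updated")
    cohort_spec(
      n = n %||% 1770,
      margins = margins_preset("england"),
      true_coefs = model$coefs,
      baseline = baseline_from_rates(0.31, 0.43),
      missingness = list(rates = c(
        immigrant_status = 1 / 1770, incarceration_length = 45 / 1770,
        violent_index_offence = 18 / 1770, civil_status = 150 / 1770,
        employment = 258 / 1770)),
      absent_fields = c("education", "disposable_income",
                        "any_severe_mental_disorder"),
      seed = seed
    )
  } else {
    model <- oxrec_preset("sweden_original")
    cohort_spec(
      n = n %||% 37100,
      margins = margins_preset("sweden"),
      true_coefs = model$coefs,
      baseline = baseline_from_rates(0.12, 0.21),
      seed = seed
    )
  }
}

# Mean linear predictor implied by the margins (analytic, no sampling).
margin_mean_lp <- function(margins, coefs) {
  schema <- oxrec_predictors()
  total <- 0
  for (p in names(coefs$beta)) {
    if (p %in% names(margins)) {
      m <- margins[[p]]
    } else {
      next  # reference level or absent: contributes 0
    }
    b <- coefs$beta[[p]]
    if (schema[[p]]$type == "continuous") {
      ev <- if (m$dist == "lognormal") {
        exp(m$meanlog + m$sdlog^2 / 2)
      } else {
        m$mean
      }
      total <- total + b * ev
    } else {
      lv <- intersect(names(m), names(b))
      total <- total + sum(b[lv] * m[lv])
    }
  }
  total
}

draw_predictor <- function(p, m, n) {
  if (is.list(m)) {
    if (m$dist == "lognormal") {
      x <- rlnorm(n, m$meanlog, m$sdlog)
      if (!is.null(m$min)) x <- pmax(x, m$min)
      x
    } else if (m$dist == "normal") {
      rnorm(n, m$mean, m$sd)
    } else {
      stop("unknown continuous distribution '", m$dist, "' for '", p, "'")
    }
  } else {
    sample(names(m), n, replace = TRUE, prob = m)
  }
}

#' Simulate a cohort
#'
#' Draws predictors independently from the margins, event times from a
#' proportional-hazards model with hazard multiplier
#' \eqn{\exp(lp - \bar{lp})} under the spec's true coefficients, binarises
#' outcomes at 12 and 24 months, and injects missingness.  Reproducible
#' given the spec's seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param inject if \code{FALSE}, skip missingness injection (useful to
#'   keep the complete table as simulator truth).
#' @return data.frame with predictor columns plus \code{event_time}
#'   (months, capped at \code{censor_months}), \code{event},
#'   \code{outcome_12m} and \code{outcome_24m}; attributes \code{spec},
#'   \code{seed}, \code{true_lp} and \code{empirical_margins}.
#' @export
simulate_cohort <- function(spec, inject = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  schema <- oxrec_predictors()
  tab <- data.frame(row.names = seq_len(n))
  for (p in names(schema)) {
    if (p %in% spec$absent_fields) next
    if (p %in% names(spec$margins)) {
      tab[[p]] <- draw_predictor(p, spec$margins[[p]], n)
    } else if (schema[[p]]$type == "continuous") {
      tab[[p]] <- rep(0, n)
    } else {
      tab[[p]] <- rep(schema[[p]]$levels[1], n)
    }
  }
  lp <- linear_predictor(tab, spec$true_coefs)
  center <- if (spec$center_lp) margin_mean_lp(spec$margins, spec$true_coefs) else 0
  mult <- exp(lp - center)

  e <- rexp(n)  # unit-exponential; T solves cumulative hazard * mult = e
  b <- spec$baseline
  t_event <- switch(b$dist,
    exponential = e / (b$rate * mult),
    weibull = b$scale * (e / mult)^(1 / b$shape),
    stop("unknown baseline distribution '", b$dist, "'"))

  cens <- spec$censor_months
  if (spec$dropout_rate > 0) {
    drop <- runif(n) < spec$dropout_rate
    cens_i <- ifelse(drop, runif(n, 0, cens), cens)
  } else {
    cens_i <- rep(cens, n)
  }
  tab$event_time <- pmin(t_event, cens_i)
  tab$event <- as.integer(t_event <= cens_i)
  tab$outcome_12m <- as.integer(t_event <= 12 & cens_i >= pmin(t_event, 12))
  tab$outcome_24m <- as.integer(t_event <= 24 & cens_i >= pmin(t_event, 24))
  tab$outcome_24m <- pmax(tab$outcome_24m, tab$outcome_12m)

  if (inject) tab <- inject_missingness(tab, spec, reseed = FALSE)

  emp <- lapply(names(spec$margins), function(p) {
    if (is.list(spec$margins[[p]])) NULL else prop.table(table(tab[[p]], useNA = "no"))
  })
  names(emp) <- names(spec$margins)
  attr(tab, "spec") <- spec
  attr(tab, "seed") <- spec$seed
  attr(tab, "true_lp") <- lp
  attr(tab, "empirical_margins") <- emp[!vapply(emp, is.null, logical(1))]
  tab
}

#' Inject missingness into a cohort table
#'
#' Replaces observed values with \code{NA} at the configured per-predictor
#' rates.  MCAR flags are independent of everything; MAR flags follow a
#' logistic model on the listed observed fields, calibrated so the marginal
#' rate matches the target.  Fields configured as conditioning variables
#' must not themselves be subject to missingness.
#'
#' @param table cohort data.frame.
#' @param spec a \code{\link{cohort_spec}} carrying the missingness block.
#' @param reseed reset the RNG from \code{spec$seed + 1} (default); set
#'   \code{FALSE} when called inside \code{\link{simulate_cohort}}.
#' @return the table with \code{NA} markers injected.
#' @export
inject_missingness <- function(table, spec, reseed = TRUE) {
  rates <- spec$missingness$rates %||% numeric()
  if (!length(rates) || all(rates == 0)) return(table)
  if (reseed) set.seed(spec$seed + 1L)
  mech <- spec$missingness$mechanism %||% "MCAR"
  for (p in names(rates)) {
    r <- rates[[p]]
    if (r == 0) next
    if (!p %in% names(table)) stop("missingness configured for absent column '", p, "'")
    m_p <- if (is.list(mech) && !is.null(mech[[p]])) mech[[p]] else mech
    if (is.list(m_p) && identical(m_p$type, "MAR")) {
      dep <- m_p$dependent_on
      bad <- intersect(dep, names(rates)[rates > 0])
      if (length(bad)) {
        stop("MAR mechanism for '", p, "' conditions on field(s) themselves ",
             "subject to missingness: ", paste(bad, collapse = ", "))
      }
      if (!all(dep %in% names(table))) {
        stop("MAR mechanism for '", p, "' conditions on unobserved field(s)")
      }
      strength <- m_p$strength %||% 1
      z <- rowSums(vapply(dep, function(d) {
        x <- table[[d]]
        x <- if (is.numeric(x)) x else as.numeric(factor(x))
        as.numeric(scale(x))
      }, numeric(nrow(table))))
      eta <- qlogis(r) + strength * (z - mean(z))
      pr <- plogis(eta)
      pr <- pr * r / mean(pr)  # hold the marginal rate at the target
      flag <- runif(nrow(table)) < pmin(pr, 1)
    } else {
      flag <- runif(nrow(table)) < r
    }
    table[[p]][flag] <- NA
  }
  table
}

#' Write a cohort with a metadata sidecar
#'
#' @param table simulated cohort.
#' @param path CSV destination; a \code{<path>.meta.json} sidecar records
#'   the seed, spec hash and empirical margins.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  spec <- attr(table, "spec")
  meta <- list(
    seed = attr(table, "seed"),
    n = nrow(table),
    spec_hash = if (!is.null(spec)) spec_hash(spec),
    package_version = as.character(packageVersion("oxrecval")),
    empirical_margins = lapply(attr(table, "empirical_margins"), as.list)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Stable content hash of a spec (polynomial rolling hash over its deparsed
# form; avoids a digest dependency).
spec_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
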