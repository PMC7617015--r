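# Scoring: linear predictor, survival-baseline risk transform and
# categorical risk levels.

#' Linear predictor for one or more individuals
#'
#' Sums the log-hazard weights of each individual's active predictor
#' levels; continuous predictors contribute \code{weight * value}.  Wholly
#' absent predictors contribute 0 here — their derivation-sample average
#' enters through the adjustment constant in the survival spec instead.
#'
#' @param profile a one-row data.frame (or list) of predictor values, or a
#'   multi-row cohort table; missing markers (\code{NA}) on non-absent
#'   predictors are an error, since imputation happens upstream.
#' @param coefs an \code{\link{oxrec_coefs}} object.
#' @return numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(profile, coefs) {
  stopifnot(inherits(coefs, "oxrec_coefs"))
  if (!is.data.frame(profile)) profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  schema <- oxrec_predictors()
  lp <- numeric(nrow(profile))
  for (p in names(coefs$beta)) {
    if (p %in% coefs$absent) next
    if (!p %in% names(profile)) {
      stop("profile lacks predictor '", p, "'")
    }
    x <- profile[[p]]
    if (anyNA(x)) {
      stop("predictor '", p, "' has missing values; run imputation ",
           "(mice_impute) before scoring")
    }
    b <- coefs$beta[[p]]
    if (schema[[p]]$type == "continuous") {
      lp <- lp + b * x
    } else {
      x <- as.character(x)
      ref <- coefs$reference_levels[[p]]
      known <- c(ref, names(b), schema[[p]]$levels)
      unknown <- setdiff(unique(x), known)
      if (length(unknown)) {
        stop("unknown level '", unknown[1], "' for predictor '", p, "'")
      }
      contrib <- b[x]
      contrib[is.na(contrib)] <- 0  # reference / unweighted levels
      lp <- lp + unname(contrib)
    }
  }
  lp
}

#' Fixed-horizon risk probability
#'
#' Evaluates \eqn{1 - S_t^{\exp(s_t (a + lp))}} where \eqn{S_t} is the
#' baseline survival at the requested horizon, \eqn{s_t} the multiplicative
#' recalibration slope and \eqn{a} the absent-predictor adjustment constant.
#' With slope 1 and adjustment 0 this reduces to the original
#' \eqn{1 - S_t^{\exp(lp)}}.
#'
#' @param lp numeric vector of linear predictors.
#' @param spec an \code{\link{oxrec_spec}}.
#' @param horizon months; must be one of \code{spec$horizons}.
#' @return numeric vector of probabilities in (0, 1).
#' @export
risk_probability <- function(lp, spec, horizon) {
  stopifnot(inherits(spec, "oxrec_spec"))
  key <- as.character(horizon)
  if (!key %in% names(spec$baseline_survival)) {
    stop("horizon ", horizon, " months not in spec (available: ",
         paste(names(spec$baseline_survival), collapse = ", "), ")")
  }
  s_t <- spec$baseline_survival[[key]]
  if (s_t <= 0 || s_t >= 1) stop("baseline survival must lie strictly in (0, 1)")
  slope <- spec$recalibration_slope[[key]]
  1 - s_t ^ exp(slope * (spec$adjustment + lp))
}

#' Categorical risk level
#'
#' Maps probabilities to \code{low} / \code{medium} / \code{high} using two
#' strictly increasing cut-offs; a probability exactly at a cut-off is
#' assigned the higher category (the \eqn{\ge} convention used for
#' test-positivity throughout the package).
#'
#' @param prob numeric vector of probabilities.
#' @param cutoffs length-2 strictly increasing numeric in (0, 1).
#' @return character vector in \code{c("low", "medium", "high")}.
#' @export
risk_category <- function(prob, cutoffs) {
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0 ||
      any(cutoffs <= 0 | cutoffs >= 1)) {
    stop("cutoffs must be two strictly increasing values in (0, 1)")
  }
  c("low", "medium", "high")[findInterval(prob, cutoffs) + 1L]
}

#' Score a cohort table
#'
#' Appends linear predictor, per-horizon risk probabilities and categorical
#' risk levels to a cohort table.
#'
#' @param table cohort data.frame with predictor columns (imputed: no
#'   missing markers on non-absent predictors).
#' @param model an \code{\link{oxrec_model}}.
#' @return the table with columns \code{lp}, \code{risk_<h>m} and
#'   \code{category_<h>m} for each horizon \code{h} appended.
#' @export
score_cohort <- function(table, model) {
  stopifnot(inherits(model, "oxrec_model"))
  validate_cohort(table, absent = model$coefs$absent, allow_missing = TRUE)
  table$lp <- linear_predictor(table, model$coefs)
  for (h in model$spec$horizons) {
    p <- risk_probability(table$lp, model$spec, h)
    table[[sprintf("risk_%dm", h)]] <- p
    table[[sprintf("category_%dm", h)]] <- risk_category(p, model$cutoffs)
  }
  table
}
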