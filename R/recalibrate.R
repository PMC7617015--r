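# Incremental external validation: (1) simple validation of the original
# model; (2) baseline-risk update with a multiplicative recalibration
# slope; (3) coefficient comparison gating any re-estimation (which is
# itself out of scope: the comparison reports, it never modifies the
# scoring model).

#' Full performance battery for a scored cohort at each horizon
#'
#' @param table cohort data.frame with imputed predictors and
#'   \code{outcome_<h>m} columns.
#' @param model \code{\link{oxrec_model}} used for prediction.
#' @param thresholds probability thresholds for the threshold table.
#' @return object of class \code{performance_report}: per horizon, AUC with
#'   interval, threshold metrics, observed:expected ratio, calibration
#'   slope/intercept, Brier score and decile table.
#' @export
performance_report <- function(table, model,
                               thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  scored <- score_cohort(table, model)
  out <- list()
  for (h in model$spec$horizons) {
    ocol <- sprintf("outcome_%dm", h)
    if (!ocol %in% names(scored)) next
    p <- scored[[sprintf("risk_%dm", h)]]
    y <- scored[[ocol]]
    out[[as.character(h)]] <- list(
      horizon = h,
      n = length(y),
      observed_rate = mean(y),
      mean_predicted = mean(p),
      auc = auc(p, y),
      oe_ratio = oe_ratio(p, y),
      calibration = calibration_slope_and_intercept(p, y),
      brier = brier(p, y),
      deciles = decile_calibration(p, y),
      thresholds = lapply(thresholds, function(t) threshold_metrics(p, y, t))
    )
  }
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  for (h in names(x)) {
    r <- x[[h]]
    cat(sprintf("Horizon %s months (n = %d, observed rate %.1f%%)\n",
                h, r$n, 100 * r$observed_rate))
    cat(sprintf("  AUC %.3f (%.3f-%.3f)   O:E %.2f   slope %.3f   intercept %.3f   Brier %.4f\n",
                r$auc$auc, r$auc$ci_low, r$auc$ci_high, r$oe_ratio,
                r$calibration$slope, r$calibration$intercept, r$brier))
    for (tm in r$thresholds) {
      cat(sprintf("  thr %2.0f%%: sens %3.0f%% spec %3.0f%% ppv %3.0f%% npv %3.0f%%\n",
                  100 * tm$threshold, 100 * tm$sensitivity$estimate,
                  100 * tm$specificity$estimate, 100 * tm$ppv$estimate,
                  100 * tm$npv$estimate))
    }
  }
  invisible(x)
}

#' Step 1: simple validation of the original model
#'
#' Applies the model with all coefficients at their configured values
#' (including the baseline risk) and computes the full metric battery on
#' the unmodified predictions.
#'
#' @param cohort imputed cohort data.frame with outcome columns.
#' @param model \code{\link{oxrec_model}}.
#' @param thresholds threshold grid.
#' @return a \code{\link{performance_report}}.
#' @export
simple_validation <- function(cohort, model,
                              thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (!nrow(cohort)) stop("empty cohort")
  if (!any(grepl("^outcome_\\d+m$", names(cohort)))) {
    stop("cohort has no outcome columns (outcome_12m / outcome_24m)")
  }
  performance_report(cohort, model, thresholds)
}

#' Miscalibration trigger
#'
#' Decides whether step-1 performance warrants updating the model:
#' advance when |log O:E| exceeds \code{log(oe_tol)} or the calibration
#' slope leaves \code{slope_band} at any horizon.
#'
#' @param report \code{\link{performance_report}} from step 1.
#' @param oe_tol multiplicative O:E tolerance (default 1.1).
#' @param slope_band acceptable slope interval (default c(0.9, 1.1)).
#' @return logical, TRUE when the update step should run.
#' @export
needs_update <- function(report, oe_tol = 1.1, slope_band = c(0.9, 1.1)) {
  any(vapply(report, function(r) {
    abs(log(r$oe_ratio)) > log(oe_tol) ||
      (!is.na(r$calibration$slope) &&
         (r$calibration$slope < slope_band[1] || r$calibration$slope > slope_band[2]))
  }, logical(1)))
}

# Solve for the baseline survival S_t making mean predicted risk equal the
# observed event rate given slope b and bracket values x = adjustment + lp.
solve_baseline <- function(x, b, observed_rate) {
  f <- function(s) mean(1 - s ^ exp(b * x)) - observed_rate
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Step 2: baseline-risk update with multiplicative recalibration
#'
#' Fits a recalibration model on the cohort with the original bracket
#' \eqn{x = a + lp} (adjustment constant plus linear predictor) as the sole
#' covariate, then re-derives the baseline survival at each horizon so that
#' mean predicted risk equals the observed event rate on the fitting data.
#'
#' Modes: \code{"cox"} (default when \code{event_time}/\code{event} are
#' present) fits one proportional-hazards slope shared across horizons, per
#' the validation protocol; \code{"binary"} fits one complementary-log-log
#' model per horizon, yielding horizon-specific slopes (the structure of
#' published updated-model tables).  Both re-derive \eqn{S_t} exactly, so
#' the post-update observed:expected ratio is 1 by construction on the
#' fitting data.
#'
#' @param cohort imputed cohort with outcomes (and, for cox mode,
#'   \code{event_time} and \code{event} columns in months).
#' @param model original \code{\link{oxrec_model}}.
#' @param mode \code{"auto"}, \code{"cox"} or \code{"binary"}.
#' @param thresholds threshold grid for the pre/post reports.
#' @param force run the update even when step-1 metrics pass the trigger.
#' @param oe_tol,slope_band trigger tolerances, see \code{\link{needs_update}}.
#' @return object of class \code{recalibration_outcome}: \code{step_reached}
#'   (1 when no update was needed), \code{fitted_slope} and
#'   \code{updated_baseline} per horizon, \code{model} (updated or
#'   original), \code{pre} and \code{post} performance reports, \code{audit}
#'   log lines.
#' @export
update_model <- function(cohort, model, mode = c("auto", "cox", "binary"),
                         thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         force = FALSE, oe_tol = 1.1, slope_band = c(0.9, 1.1)) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (all(c("event_time", "event") %in% names(cohort))) "cox" else "binary"
  }
  ocols <- grep("^outcome_\\d+m$", names(cohort), value = TRUE)
  if (length(ocols) &&
      all(vapply(ocols, function(cc) sum(cohort[[cc]]) == 0, logical(1)))) {
    stop("no events in cohort; cannot recalibrate")
  }
  audit <- character()
  pre <- simple_validation(cohort, model, thresholds)
  for (h in names(pre)) {
    audit <- c(audit, sprintf(
      "step1 horizon %s: O:E %.3f, slope %.3f", h, pre[[h]]$oe_ratio,
      pre[[h]]$calibration$slope))
  }
  trigger <- needs_update(pre, oe_tol, slope_band)
  audit <- c(audit, sprintf("step1 trigger (|log O:E| > log %.2f or slope outside [%.2f, %.2f]): %s",
                            oe_tol, slope_band[1], slope_band[2],
                            if (trigger) "FIRED" else "passed"))
  if (!trigger && !force) {
    return(structure(list(step_reached = 1L, fitted_slope = NULL,
                          updated_baseline = NULL, model = model,
                          pre = pre, post = pre, mode = mode, audit = audit),
                     class = "recalibration_outcome"))
  }

  x <- model$spec$adjustment + linear_predictor(cohort, model$coefs)
  horizons <- model$spec$horizons
  slopes <- setNames(numeric(0), character(0))
  slope_se <- setNames(numeric(0), character(0))
  baselines <- setNames(numeric(0), character(0))

  if (mode == "cox") {
    if (!all(c("event_time", "event") %in% names(cohort))) {
      stop("cox recalibration needs event_time and event columns")
    }
    if (sum(cohort$event) == 0) stop("no events in cohort; cannot recalibrate")
    fit <- survival::coxph(survival::Surv(event_time, event) ~ x,
                           data = data.frame(event_time = cohort$event_time,
                                             event = cohort$event, x = x))
    b <- unname(coef(fit))
    if (!is.finite(b) || b <= 0) {
      stop("fitted recalibration slope is not positive (", format(b),
           "); the score does not rank hazard in this cohort")
    }
    se <- sqrt(vcov(fit)[1, 1])
    for (h in horizons) {
      key <- as.character(h)
      ocol <- sprintf("outcome_%dm", h)
      slopes[key] <- b
      slope_se[key] <- se
      baselines[key] <- solve_baseline(x, b, mean(cohort[[ocol]]))
    }
    audit <- c(audit, sprintf("step2 cox: slope %.4f (se %.4f)", b, se))
  } else {
    for (h in horizons) {
      key <- as.character(h)
      ocol <- sprintf("outcome_%dm", h)
      y <- cohort[[ocol]]
      if (sum(y) == 0) stop("no events at horizon ", h, "; cannot recalibrate")
      fit <- glm(y ~ x, family = binomial(link = "cloglog"))
      b <- unname(coef(fit)[2])
      if (!is.finite(b) || b <= 0) {
        stop("fitted recalibration slope at horizon ", h,
             " is not positive (", format(b), ")")
      }
      slopes[key] <- b
      slope_se[key] <- sqrt(vcov(fit)[2, 2])
      baselines[key] <- solve_baseline(x, b, mean(y))
      audit <- c(audit, sprintf("step2 cloglog horizon %s: slope %.4f (se %.4f)",
                                key, b, slope_se[key]))
    }
  }
  for (h in names(baselines)) {
    audit <- c(audit, sprintf("step2 horizon %s: updated S_%s = %.4f", h, h,
                              baselines[h]))
  }

  new_spec <- oxrec_spec(baselines, slopes, adjustment = model$spec$adjustment)
  new_model <- oxrec_model(model$coefs, new_spec, cutoffs = model$cutoffs,
                           name = paste0(model$name, "_updated"),
                           placeholder_betas = model$placeholder_betas)
  post <- performance_report(cohort, new_model, thresholds)
  for (h in names(post)) {
    audit <- c(audit, sprintf("step2 horizon %s post-update: O:E %.4f, slope %.3f",
                              h, post[[h]]$oe_ratio, post[[h]]$calibration$slope))
  }
  structure(list(step_reached = 2L, fitted_slope = slopes,
                 slope_se = slope_se, updated_baseline = baselines,
                 model = new_model, pre = pre, post = post, mode = mode,
                 audit = audit),
            class = "recalibration_outcome")
}

#' @export
print.recalibration_outcome <- function(x, ...) {
  cat("Incremental validation reached step", x$step_reached, "\n")
  cat(x$audit, sep = "\n")
  invisible(x)
}

#' Step 3: coefficient comparison
#'
#' Refits a multivariable proportional-hazards model on the cohort and
#' compares each revalidated coefficient with the original weight: a
#' predictor is flagged when the original beta lies outside the
#' revalidated 95\% confidence interval.  The scoring model is never
#' modified — re-estimation is reported, not applied.
#'
#' @param cohort imputed cohort with \code{event_time} and \code{event}.
#' @param coefs original \code{\link{oxrec_coefs}}.
#' @param conf confidence level for the comparison intervals.
#' @return data.frame with one row per coefficient: \code{predictor},
#'   \code{level}, \code{original}, \code{revalidated}, \code{ci_low},
#'   \code{ci_high}, \code{flagged} (NA when that term did not converge).
#' @export
compare_coefficients <- function(cohort, coefs, conf = 0.95) {
  stopifnot(inherits(coefs, "oxrec_coefs"))
  if (!all(c("event_time", "event") %in% names(cohort))) {
    stop("coefficient comparison needs event_time and event columns")
  }
  if (length(unique(cohort$event)) < 2L && sum(cohort$event) == 0) {
    stop("cohort lacks outcome variation; cannot refit coefficients")
  }
  schema <- oxrec_predictors()
  use <- setdiff(intersect(names(coefs$beta), names(cohort)), coefs$absent)
  df <- data.frame(event_time = cohort$event_time, event = cohort$event)
  for (p in use) {
    if (schema[[p]]$type == "continuous") {
      df[[p]] <- cohort[[p]]
    } else {
      ref <- coefs$reference_levels[[p]]
      lev <- c(ref, setdiff(schema[[p]]$levels, ref))
      f <- factor(cohort[[p]], levels = lev)
      if (nlevels(droplevels(f)) < 2L) next  # no variation; skip term
      df[[p]] <- f
    }
  }
  terms <- setdiff(names(df), c("event_time", "event"))
  if (!length(terms)) stop("no usable predictor terms for comparison")
  fml <- as.formula(paste("survival::Surv(event_time, event) ~",
                          paste(terms, collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = df), error = function(e) e)
  if (inherits(fit, "error")) {
    stop("multivariable refit failed: ", conditionMessage(fit))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf) / 2)
  rows <- list()
  for (p in terms) {
    if (schema[[p]]$type == "continuous") {
      nm <- p
      orig <- coefs$beta[[p]]
      lv <- ""
      pairs <- list(list(nm = nm, lv = lv, orig = orig))
    } else {
      lev <- setdiff(levels(df[[p]]), levels(df[[p]])[1])
      pairs <- lapply(lev, function(l) {
        list(nm = paste0(p, l), lv = l,
             orig = if (!is.null(coefs$beta[[p]]) && l %in% names(coefs$beta[[p]]))
               unname(coefs$beta[[p]][l]) else 0)
      })
    }
    for (pr in pairs) {
      if (!pr$nm %in% names(est) || is.na(est[pr$nm]) || is.na(se[pr$nm])) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = p, level = pr$lv, original = pr$orig,
          revalidated = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          flagged = NA)
        next
      }
      lo <- est[pr$nm] - z * se[pr$nm]
      hi <- est[pr$nm] + z * se[pr$nm]
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, level = pr$lv, original = pr$orig,
        revalidated = unname(est[pr$nm]), ci_low = unname(lo),
        ci_high = unname(hi),
        flagged = pr$orig < lo || pr$orig > hi)
    }
  }
  do.call(rbind, rows)
}

#' Run the incremental validation on (possibly incomplete) data
#'
#' Orchestrates imputation, per-imputation validation and recalibration,
#' and Rubin pooling: AUC and calibration slope are pooled on their
#' original scale using their asymptotic variances, the O:E ratio on the
#' log scale, the Brier score as a mean, and fitted recalibration
#' parameters across imputations.
#'
#' @param cohort cohort data.frame, possibly with missing markers.
#' @param model \code{\link{oxrec_model}}.
#' @param m imputations (default 20; 1 is allowed for complete data).
#' @param seed master seed for imputation.
#' @param thresholds threshold grid.
#' @param mode recalibration mode, see \code{\link{update_model}}.
#' @param oe_tol,slope_band step trigger, see \code{\link{needs_update}}.
#' @return list of class \code{incremental_validation}: \code{step_reached},
#'   pooled \code{pre} and \code{post} summaries per horizon,
#'   \code{updated_model}, \code{imputation} result, \code{audit}.
#' @export
validate_incremental <- function(cohort, model, m = 20, seed = 1L,
                                 thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                 mode = "auto", oe_tol = 1.1,
                                 slope_band = c(0.9, 1.1)) {
  pred_cols <- intersect(names(oxrec_predictors()), names(cohort))
  has_missing <- any(vapply(setdiff(pred_cols, model$coefs$absent),
                            function(p) anyNA(cohort[[p]]), logical(1)))
  if (has_missing) {
    imp <- mice_impute(cohort, m = m, seed = seed, absent = model$coefs$absent)
    tables <- imp$completed
  } else {
    imp <- NULL
    tables <- list(cohort)
  }
  runs <- lapply(tables, function(tab)
    update_model(tab, model, mode = mode, thresholds = thresholds,
                 oe_tol = oe_tol, slope_band = slope_band))
  step <- max(vapply(runs, function(r) r$step_reached, integer(1)))

  pool_metric <- function(reports, h, get_est, get_var) {
    est <- vapply(reports, function(r) get_est(r[[h]]), 0)
    vr <- vapply(reports, function(r) get_var(r[[h]]), 0)
    if (length(est) == 1L) return(list(estimate = est, se = sqrt(vr)))
    p <- pool_estimates(est, vr)
    list(estimate = p$estimate, se = p$se)
  }
  summarise <- function(which) {
    reports <- lapply(runs, function(r) r[[which]])
    out <- list()
    for (h in names(reports[[1]])) {
      out[[h]] <- list(
        auc = pool_metric(reports, h, function(r) r$auc$auc, function(r) r$auc$se^2),
        log_oe = pool_metric(reports, h, function(r) log(r$oe_ratio),
                             function(r) 0),
        slope = pool_metric(reports, h, function(r) r$calibration$slope,
                            function(r) r$calibration$slope_se^2),
        intercept = pool_metric(reports, h, function(r) r$calibration$intercept,
                                function(r) r$calibration$intercept_se^2),
        brier = mean(vapply(reports, function(r) r[[h]]$brier, 0)),
        observed_rate = mean(vapply(reports, function(r) r[[h]]$observed_rate, 0)),
        mean_predicted = mean(vapply(reports, function(r) r[[h]]$mean_predicted, 0))
      )
      out[[h]]$oe_ratio <- exp(out[[h]]$log_oe$estimate)
    }
    out
  }

  updated_model <- model
  if (step >= 2L) {
    hkeys <- names(runs[[1]]$fitted_slope)
    slopes <- setNames(vapply(hkeys, function(h)
      mean(vapply(runs, function(r) r$fitted_slope[[h]], 0)), numeric(1)), hkeys)
    bases <- setNames(vapply(hkeys, function(h)
      mean(vapply(runs, function(r) r$updated_baseline[[h]], 0)), numeric(1)), hkeys)
    new_spec <- oxrec_spec(bases, slopes, adjustment = model$spec$adjustment)
    updated_model <- oxrec_model(model$coefs, new_spec, cutoffs = model$cutoffs,
                                 name = paste0(model$name, "_updated"),
                                 placeholder_betas = model$placeholder_betas)
  }

  structure(list(step_reached = step,
                 pre = summarise("pre"),
                 post = summarise("post"),
                 updated_model = updated_model,
                 m = length(tables),
                 imputation = imp,
                 audit = unlist(lapply(seq_along(runs), function(i)
                   paste0("[imp ", i, "] ", runs[[i]]$audit)))),
            class = "incremental_validation")
}
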