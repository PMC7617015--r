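# Discrimination and calibration battery: AUC with DeLong intervals,
# threshold tables with Wilson intervals, observed:expected ratio,
# calibration slope/intercept, Brier score and decile calibration.

#' Area under the ROC curve (concordance probability)
#'
#' Mann-Whitney estimator with ties counted half, equal to the c-index for
#' binary outcomes at a fixed horizon.  The confidence interval uses the
#' DeLong asymptotic variance.
#'
#' @param scores numeric predictions (any monotone scale).
#' @param outcomes binary 0/1 vector; both classes must be present.
#' @param conf confidence level (default 0.95).
#' @return list with \code{auc}, \code{ci_low}, \code{ci_high}, \code{se}.
#' @export
auc <- function(scores, outcomes, conf = 0.95) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  if (!length(x) || !length(y)) {
    stop("AUC requires both outcome classes to be present")
  }
  m <- length(x); n <- length(y)
  # midranks give the Mann-Whitney statistic and the DeLong components
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # P(X_i > Y) + half-ties
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # P(X > Y_j) + half-ties
  a <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = a, ci_low = max(0, a - z * se), ci_high = min(1, a + z * se),
       se = se)
}

# O(n^2) concordance oracle used only by tests.
auc_bruteforce <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, @param n trials, @param conf confidence level.
#' @return c(low, high); \code{NA} when \code{n} is 0.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Confusion counts and threshold metrics
#'
#' Applies the \eqn{\ge} convention (a score at the threshold is
#' test-positive) and reports sensitivity, specificity, PPV and NPV with
#' Wilson intervals.  When no individual is predicted positive the PPV is
#' undefined and reported as \code{NA}, not 0.
#'
#' @param scores predicted probabilities.
#' @param outcomes binary 0/1.
#' @param threshold probability threshold in (0, 1).
#' @return list of class \code{threshold_metrics}: counts \code{tp},
#'   \code{fp}, \code{tn}, \code{fn} and each proportion with its interval.
#' @export
threshold_metrics <- function(scores, outcomes, threshold) {
  stopifnot(length(scores) == length(outcomes),
            threshold > 0, threshold < 1)
  outcomes <- as.integer(outcomes)
  pos <- scores >= threshold
  tp <- sum(pos & outcomes == 1)
  fp <- sum(pos & outcomes == 0)
  fn <- sum(!pos & outcomes == 1)
  tn <- sum(!pos & outcomes == 0)
  prop <- function(k, n) {
    ci <- wilson_ci(k, n)
    list(estimate = if (n > 0) k / n else NA_real_,
         ci_low = ci[1], ci_high = ci[2])
  }
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = prop(tp, tp + fn),
                 specificity = prop(tn, tn + fp),
                 ppv = prop(tp, tp + fp),
                 npv = prop(tn, tn + fn)),
            class = "threshold_metrics")
}

#' Predictive values from prevalence, sensitivity and specificity
#'
#' Bayes identities: \eqn{PPV = se \cdot \pi / (se \cdot \pi + (1-sp)(1-\pi))}
#' and \eqn{NPV = sp (1-\pi) / (sp (1-\pi) + (1-se) \pi)}.  Used to check
#' the internal consistency of published threshold tables.
#'
#' @param prevalence event prevalence \eqn{\pi}.
#' @param sensitivity,specificity proportions.
#' @return list with \code{ppv} and \code{npv}.
#' @export
bayes_ppv_npv <- function(prevalence, sensitivity, specificity) {
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  list(ppv = ppv, npv = npv)
}

#' Observed:expected event ratio
#'
#' The calibration-in-the-large measure used here: the ratio of the
#' observed event rate to the mean predicted risk.  1 means perfect mean
#' calibration; above 1 means the model under-predicts.
#'
#' @param scores predicted probabilities.
#' @param outcomes binary 0/1.
#' @return the ratio (a single number).
#' @export
oe_ratio <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes), length(scores) >= 1)
  ms <- mean(scores)
  if (ms == 0) stop("mean predicted risk is 0; O:E ratio undefined")
  mean(as.integer(outcomes)) / ms
}

#' Calibration slope and recalibration intercept
#'
#' Refits the outcomes on the logit of the predictions: the slope is the
#' coefficient of \code{logit(score)} in a logistic fit (1 is ideal, below
#' 1 means predictions too extreme); the intercept is estimated with the
#' logit of the score as a fixed offset (the conventional
#' calibration-in-the-large intercept, 0 ideal).
#'
#' @param scores predicted probabilities, strictly inside (0, 1).
#' @param outcomes binary 0/1.
#' @return list with \code{slope}, \code{intercept}, standard errors, and
#'   \code{converged}; degenerate fits (single-class outcomes, constant
#'   scores) are flagged rather than silently returned.
#' @export
calibration_slope_and_intercept <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  if (any(scores <= 0 | scores >= 1)) {
    stop("scores must lie strictly in (0, 1) for logit recalibration")
  }
  outcomes <- as.integer(outcomes)
  out <- list(slope = NA_real_, slope_se = NA_real_,
              intercept = NA_real_, intercept_se = NA_real_,
              converged = FALSE)
  if (length(unique(outcomes)) < 2L || length(unique(scores)) < 2L) {
    out$message <- "degenerate fit: constant outcomes or constant scores"
    return(out)
  }
  lg <- qlogis(scores)
  f_slope <- glm(outcomes ~ lg, family = binomial())
  f_int <- glm(outcomes ~ 1 + offset(lg), family = binomial())
  out$slope <- unname(coef(f_slope)[2])
  out$slope_se <- sqrt(vcov(f_slope)[2, 2])
  out$intercept <- unname(coef(f_int)[1])
  out$intercept_se <- sqrt(vcov(f_int)[1, 1])
  out$converged <- f_slope$converged && f_int$converged
  out
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary
#' outcome; 0 is perfect, 0.25 is an uninformative constant 0.5.
#'
#' @param scores predicted probabilities.
#' @param outcomes binary 0/1.
#' @return a single number in [0, 1].
#' @export
brier <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  mean((scores - as.integer(outcomes))^2)
}

#' Decile calibration table
#'
#' Sorts individuals into ten equal-count risk groups (ties broken by
#' stable row order) and reports mean predicted risk versus observed event
#' rate per group.  With fewer than 10 rows, fewer groups are formed with a
#' warning.
#'
#' @param scores predicted probabilities.
#' @param outcomes binary 0/1.
#' @param groups number of groups (default 10).
#' @return data.frame with \code{group}, \code{n}, \code{mean_predicted},
#'   \code{observed_rate}.
#' @export
decile_calibration <- function(scores, outcomes, groups = 10) {
  stopifnot(length(scores) == length(outcomes))
  n <- length(scores)
  if (n < groups) {
    warning("fewer rows (", n, ") than groups (", groups, "); using ", n, " groups")
    groups <- n
  }
  g <- ceiling(rank(scores, ties.method = "first") * groups / n)
  out <- data.frame(
    group = seq_len(groups),
    n = as.integer(tabulate(g, nbins = groups)),
    mean_predicted = vapply(seq_len(groups), function(i) mean(scores[g == i]), 0),
    observed_rate = vapply(seq_len(groups),
                           function(i) mean(as.integer(outcomes)[g == i]), 0)
  )
  out
}

#' Calibration plot
#'
#' Mean predicted versus observed rate per risk decile with the identity
#' line, mirroring the standard validation-figure layout.
#'
#' @param decile_table output of \code{\link{decile_calibration}}.
#' @param main plot title.
#' @export
plot_calibration <- function(decile_table, main = "Calibration") {
  plot(decile_table$mean_predicted, decile_table$observed_rate,
       xlim = c(0, 1), ylim = c(0, 1), pch = 19,
       xlab = "Mean predicted risk", ylab = "Observed event rate",
       main = main)
  graphics::abline(0, 1, lty = 2)
  invisible(decile_table)
}

#' ROC curve plot
#'
#' @param scores predicted probabilities.
#' @param outcomes binary 0/1.
#' @param main plot title.
#' @export
plot_roc <- function(scores, outcomes, main = "ROC") {
  outcomes <- as.integer(outcomes)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[outcomes == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[outcomes == 0] >= t), 0)
  plot(c(0, fpr, 1), c(0, sens, 1), type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity", main = main)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
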