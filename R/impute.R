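# Multiple imputation by chained equations for partially missing
# predictors, derivation-average handling for wholly absent predictors,
# and Rubin pooling of downstream estimates.

# Design: binary variables use a logistic conditional model with an
# approximate posterior draw of the coefficients (normal around the MLE
# with the estimated covariance); multi-level factors use a
# continuation-ratio stack of such logistic fits in level order.  Outcome
# indicators are always included as covariates in the conditional models.

#' Multiple imputation by chained equations
#'
#' Produces \code{m} completed copies of a cohort table.  Observed cells
#' are preserved byte-identically; only originally missing cells differ
#' across imputations.  Each imputation runs \code{maxit} chained cycles
#' from its own seed substream of \code{seed}.
#'
#' @param table cohort data.frame; missing markers are \code{NA}.
#' @param m number of imputations (default 20).
#' @param maxit chained-equation cycles per imputation (default 10).
#' @param seed master seed.
#' @param absent predictors wholly absent by design (ignored here; they are
#'   handled through the adjustment constant, see
#'   \code{\link{absent_predictor_policy}}).
#' @return object of class \code{imputation_result}: \code{m},
#'   \code{completed} (list of m data.frames), \code{diagnostics}
#'   (per-variable observed vs imputed level frequencies), \code{seed}.
#' @export
mice_impute <- function(table, m = 20, maxit = 10, seed = 1L,
                        absent = character()) {
  stopifnot(is.data.frame(table), m >= 1)
  schema <- oxrec_predictors()
  vars <- intersect(names(schema), names(table))
  vars <- setdiff(vars, absent)
  miss_frac <- vapply(vars, function(v) mean(is.na(table[[v]])), 0)
  fully_missing <- vars[miss_frac == 1]
  if (length(fully_missing)) {
    stop("variable(s) 100% missing but not declared absent: ",
         paste(fully_missing, collapse = ", "),
         "; use absent-predictor handling (absent_predictor_policy) instead")
  }
  target_vars <- vars[miss_frac > 0]
  outcome_cols <- intersect(c("outcome_12m", "outcome_24m"), names(table))

  if (!length(target_vars)) {
    return(structure(list(m = m, completed = replicate(m, table, simplify = FALSE),
                          diagnostics = NULL, seed = seed),
                     class = "imputation_result"))
  }

  miss_idx <- lapply(target_vars, function(v) which(is.na(table[[v]])))
  names(miss_idx) <- target_vars
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(as.integer(seed) + i * 1009L)
    cur <- table
    # initial fill: sample from the observed marginal distribution
    for (v in target_vars) {
      obs <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]), replace = TRUE)
    }
    for (cycle in seq_len(maxit)) {
      for (v in target_vars) {
        idx <- miss_idx[[v]]
        covars <- setdiff(c(vars, outcome_cols), v)
        x_all <- impute_design(cur[covars], schema)
        obs_rows <- setdiff(seq_len(nrow(cur)), idx)
        cur[[v]][idx] <- draw_conditional(
          y = cur[[v]], x = x_all, obs_rows = obs_rows, mis_rows = idx,
          info = schema[[v]])
      }
    }
    completed[[i]] <- cur
  }

  diag <- do.call(rbind, lapply(target_vars, function(v) {
    info <- schema[[v]]
    if (info$type == "continuous") {
      data.frame(variable = v, level = "(mean)",
                 observed = mean(table[[v]], na.rm = TRUE),
                 imputed = mean(vapply(completed, function(ct)
                   mean(ct[[v]][miss_idx[[v]]]), 0)))
    } else {
      lev <- info$levels
      obs_f <- prop.table(table(factor(table[[v]], lev)))
      imp_vals <- unlist(lapply(completed, function(ct) ct[[v]][miss_idx[[v]]]))
      imp_f <- prop.table(table(factor(imp_vals, lev)))
      data.frame(variable = v, level = lev,
                 observed = as.numeric(obs_f), imputed = as.numeric(imp_f))
    }
  }))

  structure(list(m = m, completed = completed, diagnostics = diag, seed = seed),
            class = "imputation_result")
}

# Main-effects design matrix for the conditional models; constant columns
# are dropped to keep the fits full rank.
impute_design <- function(df, schema) {
  for (v in names(df)) {
    if (!is.null(schema[[v]]) && schema[[v]]$type != "continuous") {
      df[[v]] <- factor(df[[v]], levels = schema[[v]]$levels)
      df[[v]] <- droplevels(df[[v]])
      if (nlevels(df[[v]]) < 2L) df[[v]] <- NULL
    } else if (is.numeric(df[[v]])) {
      if (length(unique(df[[v]])) < 2L) df[[v]] <- NULL
    } else {
      df[[v]] <- NULL
    }
  }
  if (!length(df)) return(matrix(1, nrow = nrow(df)))
  model.matrix(~ ., data = df)
}

# Logistic fit with an approximate Bayesian coefficient draw; falls back to
# marginal sampling when the fit is degenerate.
draw_logistic <- function(y01, x, obs_rows, mis_rows) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(x[obs_rows, , drop = FALSE], y01[obs_rows],
                             family = binomial())),
    error = function(e) NULL)
  ok <- !is.null(fit) && !any(is.na(coef(fit)))
  if (ok) {
    b <- coef(fit)
    # observed information from the IRLS weights
    w <- fit$weights
    xt <- x[obs_rows, , drop = FALSE]
    info <- crossprod(xt * sqrt(w))
    v <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (!is.null(v)) {
      b <- b + drop(t(chol(v)) %*% rnorm(length(b)))
      p <- plogis(drop(x[mis_rows, , drop = FALSE] %*% b))
      return(runif(length(mis_rows)) < p)
    }
  }
  # fallback: marginal draw
  runif(length(mis_rows)) < mean(y01[obs_rows])
}

draw_conditional <- function(y, x, obs_rows, mis_rows, info) {
  if (info$type == "continuous") {
    # Bayesian linear regression draw
    xt <- x[obs_rows, , drop = FALSE]
    yt <- y[obs_rows]
    fit <- tryCatch(lm.fit(xt, yt), error = function(e) NULL)
    if (is.null(fit) || any(is.na(coef(fit)))) {
      return(sample(yt, length(mis_rows), replace = TRUE))
    }
    df_res <- length(obs_rows) - ncol(xt)
    sigma2 <- sum(fit$residuals^2) / max(df_res, 1) *
      df_res / stats::rchisq(1, max(df_res, 1))
    v <- tryCatch(chol2inv(chol(crossprod(xt))), error = function(e) NULL)
    b <- coef(fit)
    if (!is.null(v)) b <- b + drop(t(chol(v * sigma2)) %*% rnorm(length(b)))
    drop(x[mis_rows, , drop = FALSE] %*% b) + rnorm(length(mis_rows), 0, sqrt(sigma2))
  } else if (length(info$levels) == 2L) {
    lev <- info$levels
    y01 <- as.integer(y == lev[2])
    drawn <- draw_logistic(y01, x, obs_rows, mis_rows)
    lev[drawn + 1L]
  } else {
    # continuation-ratio stack: P(level k | level >= k) in level order
    lev <- info$levels
    res <- rep(NA_character_, length(mis_rows))
    active_mis <- seq_along(mis_rows)
    active_obs <- obs_rows
    for (k in seq_len(length(lev) - 1L)) {
      if (!length(active_mis)) break
      y01 <- as.integer(y == lev[k])
      sub_obs <- active_obs[y[active_obs] %in% lev[k:length(lev)]]
      if (length(unique(y01[sub_obs])) < 2L) {
        p <- mean(y01[sub_obs])
        drawn <- runif(length(active_mis)) < p
      } else {
        drawn <- draw_logistic(y01, x, sub_obs, mis_rows[active_mis])
      }
      res[active_mis[drawn]] <- lev[k]
      active_mis <- active_mis[!drawn]
    }
    res[is.na(res)] <- lev[length(lev)]
    res
  }
}

#' Adjustment constant for wholly absent predictors
#'
#' Policy wrapper: predictors that are missing for every individual are
#' assigned their derivation-sample average, which adds the constant
#' \eqn{\sum \beta_j p_j} to every linear predictor — equivalent to folding
#' their effect into the baseline risk.  Delegates to
#' \code{\link{adjustment_constant}}.
#'
#' @param coefs \code{\link{oxrec_coefs}} with absent predictors declared
#'   and their derivation prevalences populated.
#' @return the adjustment constant.
#' @export
absent_predictor_policy <- function(coefs) {
  adjustment_constant(coefs)
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Pooled estimate is the mean of the per-imputation estimates; pooled
#' variance is the mean within-imputation variance plus
#' \eqn{(1 + 1/m)} times the between-imputation variance.
#'
#' @param estimates numeric vector of per-imputation estimates (m >= 2).
#' @param variances matching numeric vector of within-imputation variances.
#' @return list with \code{estimate}, \code{variance}, \code{se},
#'   \code{within}, \code{between}, \code{m}.
#' @export
pool_estimates <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (m < 2) stop("pooling requires at least 2 imputations")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- var(estimates)
  total <- w + (1 + 1 / m) * b
  list(estimate = qbar, variance = total, se = sqrt(total),
       within = w, between = b, m = m)
}
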