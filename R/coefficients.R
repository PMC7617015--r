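# Coefficient sets, survival-model specifications and their configuration
# files.  A model configuration bundles the per-level log-hazard weights
# (betas), reference levels, prevalences of wholly absent predictors in the
# derivation sample, horizon-indexed baseline survival, multiplicative
# recalibration slopes and the probability cut-offs for categorical risk.

#' Construct an OxRec coefficient set
#'
#' @param beta named list mapping predictor name to either a named numeric
#'   vector of per-level log-hazard weights (discrete predictors; the
#'   reference level carries weight 0 and may be omitted) or a single
#'   numeric weight (continuous predictors, linear term).
#' @param reference_levels named character vector, one entry per discrete
#'   predictor with a beta, giving the zero-weight reference level.
#' @param absent character vector of wholly absent predictors (subset of
#'   education, disposable_income, any_severe_mental_disorder).
#' @param absent_prevalence named list mapping each absent predictor to a
#'   named numeric vector of derivation-sample prevalences for its
#'   non-reference levels.
#' @return object of class \code{oxrec_coefs}.
#' @export
oxrec_coefs <- function(beta, reference_levels = NULL, absent = character(),
                        absent_prevalence = list()) {
  schema <- oxrec_predictors()
  unknown <- setdiff(names(beta), names(schema))
  if (length(unknown)) {
    stop("beta given for unknown predictor(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(reference_levels)) {
    reference_levels <- vapply(
      names(beta)[vapply(names(beta), function(p) schema[[p]]$type != "continuous",
                         logical(1))],
      function(p) schema[[p]]$levels[1], character(1))
  }
  for (p in names(beta)) {
    info <- schema[[p]]
    b <- beta[[p]]
    if (info$type == "continuous") {
      if (!is.numeric(b) || length(b) != 1L) {
        stop("continuous predictor '", p, "' needs a single numeric weight")
      }
    } else {
      bad <- setdiff(names(b), info$levels)
      if (length(bad)) {
        stop("unknown level(s) in betas for '", p, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  bad_absent <- setdiff(absent, absent_allowed())
  if (length(bad_absent)) {
    stop("predictor(s) may not be declared absent: ", paste(bad_absent, collapse = ", "))
  }
  for (p in absent) {
    prev <- absent_prevalence[[p]]
    if (is.null(prev)) {
      stop("absent predictor '", p, "' lacks derivation-sample prevalences")
    }
    if (any(prev < 0 | prev > 1)) {
      stop("prevalences for '", p, "' must lie in [0, 1]")
    }
    if (sum(prev) > 1 + 1e-9) {
      stop("prevalences for '", p, "' sum to more than 1")
    }
    if (is.null(beta[[p]]) || !all(names(prev) %in% names(beta[[p]]))) {
      stop("absent predictor '", p, "' lacks betas for its prevalence levels")
    }
  }
  structure(list(beta = beta,
                 reference_levels = reference_levels,
                 absent = absent,
                 absent_prevalence = absent_prevalence),
            class = "oxrec_coefs")
}

#' Construct a survival-model specification
#'
#' Holds the horizon-indexed baseline survival values \eqn{S_t}, the
#' multiplicative recalibration slopes \eqn{s_t}, and the adjustment
#' constant for wholly absent predictors.  Predicted risk at horizon
#' \eqn{t} is \eqn{1 - S_t^{\exp(s_t (a + lp))}}.
#'
#' @param baseline_survival named numeric, names are horizons in months
#'   (e.g. \code{c("12" = 0.4643, "24" = 0.3509)}), values in (0, 1).
#' @param recalibration_slope named numeric over the same horizons;
#'   strictly positive.  Defaults to 1 at every horizon.
#' @param adjustment adjustment constant (sum of beta times prevalence over
#'   absent-predictor levels); see \code{\link{adjustment_constant}}.
#' @return object of class \code{oxrec_spec}.
#' @export
oxrec_spec <- function(baseline_survival, recalibration_slope = NULL,
                       adjustment = 0) {
  if (is.null(names(baseline_survival))) {
    stop("baseline_survival must be named by horizon (months)")
  }
  if (any(baseline_survival <= 0 | baseline_survival >= 1)) {
    stop("baseline survival values must lie strictly in (0, 1)")
  }
  if (is.null(recalibration_slope)) {
    recalibration_slope <- setNames(rep(1, length(baseline_survival)),
                                    names(baseline_survival))
  }
  if (!setequal(names(recalibration_slope), names(baseline_survival))) {
    stop("recalibration_slope horizons must match baseline_survival horizons")
  }
  if (any(recalibration_slope <= 0)) {
    stop("recalibration slopes must be strictly positive")
  }
  structure(list(horizons = as.numeric(names(baseline_survival)),
                 baseline_survival = baseline_survival,
                 recalibration_slope = recalibration_slope[names(baseline_survival)],
                 adjustment = adjustment),
            class = "oxrec_spec")
}

#' Missing-predictor adjustment constant
#'
#' For predictors wholly absent from the validation data, every individual
#' is assigned the derivation-sample average: the score gains a constant
#' \eqn{\sum \beta_j p_j} over the non-reference levels of the absent
#' predictors, equivalent to folding their effect into the baseline risk.
#'
#' @param coefs an \code{\link{oxrec_coefs}} object.
#' @return the adjustment constant (0 when no predictor is absent).
#' @export
adjustment_constant <- function(coefs) {
  stopifnot(inherits(coefs, "oxrec_coefs"))
  total <- 0
  for (p in coefs$absent) {
    prev <- coefs$absent_prevalence[[p]]
    if (any(prev < 0 | prev > 1)) {
      stop("prevalences for '", p, "' must lie in [0, 1]")
    }
    total <- total + sum(coefs$beta[[p]][names(prev)] * prev)
  }
  total
}

#' Bundle coefficients, survival spec and category cut-offs
#'
#' @param coefs \code{\link{oxrec_coefs}}.
#' @param spec \code{\link{oxrec_spec}}; its adjustment constant is
#'   recomputed from \code{coefs} unless supplied explicitly there.
#' @param cutoffs length-2 increasing numeric in (0,1): low/medium and
#'   medium/high probability boundaries.
#' @param name configuration name.
#' @param placeholder_betas character vector naming predictors whose betas
#'   are placeholders (not sourced from the development study tables).
#' @return object of class \code{oxrec_model}.
#' @export
oxrec_model <- function(coefs, spec, cutoffs = c(0.3, 0.6),
                        name = "custom", placeholder_betas = character()) {
  stopifnot(inherits(coefs, "oxrec_coefs"), inherits(spec, "oxrec_spec"))
  if (length(cutoffs) != 2L || any(diff(cutoffs) <= 0) ||
      any(cutoffs <= 0 | cutoffs >= 1)) {
    stop("cutoffs must be two strictly increasing values in (0, 1)")
  }
  structure(list(coefs = coefs, spec = spec, cutoffs = cutoffs, name = name,
                 placeholder_betas = placeholder_betas),
            class = "oxrec_model")
}

#' @export
print.oxrec_model <- function(x, ...) {
  cat("OxRec model configuration '", x$name, "'\n", sep = "")
  cat("  horizons (months):", paste(x$spec$horizons, collapse = ", "), "\n")
  cat("  baseline survival:",
      paste(sprintf("S_%s = %.4f", names(x$spec$baseline_survival),
                    x$spec$baseline_survival), collapse = ", "), "\n")
  cat("  recalibration slopes:",
      paste(sprintf("%.4f", x$spec$recalibration_slope), collapse = ", "), "\n")
  cat("  adjustment constant:", format(x$spec$adjustment), "\n")
  cat("  absent predictors:",
      if (length(x$coefs$absent)) paste(x$coefs$absent, collapse = ", ") else "none",
      "\n")
  if (length(x$placeholder_betas)) {
    cat("  PLACEHOLDER betas (not from the development study):",
        paste(x$placeholder_betas, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a model configuration file
#'
#' Configurations are JSON with blocks \code{betas},
#' \code{reference_levels}, \code{absent_prevalences},
#' \code{baseline_survival}, \code{recalibration_slopes} and
#' \code{category_cutoffs}.
#'
#' @param path file path.
#' @return an \code{\link{oxrec_model}}.
#' @export
read_oxrec_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (blk in c("betas", "baseline_survival")) {
    if (is.null(raw[[blk]])) stop("configuration lacks required block '", blk, "'")
  }
  beta <- lapply(raw$betas, function(b) {
    if (is.list(b)) unlist(b) else b
  })
  coefs <- oxrec_coefs(
    beta = beta,
    reference_levels = unlist(raw$reference_levels),
    absent = names(raw$absent_prevalences) %||% character(),
    absent_prevalence = lapply(raw$absent_prevalences, unlist)
  )
  bs <- unlist(raw$baseline_survival)
  sl <- if (!is.null(raw$recalibration_slopes)) unlist(raw$recalibration_slopes)
  spec <- oxrec_spec(bs, sl, adjustment = adjustment_constant(coefs))
  cut <- unname(unlist(raw$category_cutoffs %||% c(0.3, 0.6)))
  oxrec_model(coefs, spec, cutoffs = cut,
              name = raw$name %||% basename(path),
              placeholder_betas = unlist(raw$placeholder_betas) %||% character())
}

#' Write a model configuration file
#'
#' Inverse of \code{\link{read_oxrec_config}}; numeric values are written at
#' full precision so that a read/write cycle is bit-exact.
#'
#' @param model an \code{\link{oxrec_model}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_oxrec_config <- function(model, path) {
  stopifnot(inherits(model, "oxrec_model"))
  out <- list(
    name = model$name,
    placeholder_betas = model$placeholder_betas,
    betas = lapply(model$coefs$beta, function(b) as.list(b)),
    reference_levels = as.list(model$coefs$reference_levels),
    absent_prevalences = lapply(model$coefs$absent_prevalence, as.list),
    baseline_survival = as.list(model$spec$baseline_survival),
    recalibration_slopes = as.list(model$spec$recalibration_slope),
    category_cutoffs = model$cutoffs
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped model presets
#'
#' \code{"england_updated"}: the updated parameterisation for an English
#' validation cohort — baseline survival S_12 = 0.4643, S_24 = 0.3509,
#' multiplicative recalibration slopes 0.6745 (1 year) and 0.5372
#' (2 years), with education, disposable income and any severe mental
#' disorder wholly absent and absorbed through the adjustment constant
#' (seven beta-by-prevalence products summing to about 0.3255).
#' \code{"sweden_original"}: the original parameterisation — S_12 = 0.7992,
#' S_24 = 0.6775, slopes fixed at 1, no absent predictors.
#'
#' In both presets, betas for predictors other than the three absorbed ones
#' are clearly flagged placeholders: the development-study weights are not
#' reproduced here.  Replace them with the published development weights
#' before any real-data use.
#'
#' @param name preset name.
#' @return an \code{\link{oxrec_model}}.
#' @export
oxrec_preset <- function(name = c("england_updated", "sweden_original")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "oxrecval",
                      mustWork = TRUE)
  read_oxrec_config(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
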