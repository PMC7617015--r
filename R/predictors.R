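# Predictor schema shared by scoring, simulation and imputation.

#' OxRec predictor schema
#'
#' Describes the predictors entering the score: their type (binary,
#' categorical or continuous) and, for discrete predictors, the ordered set
#' of levels.  Binary predictors use levels \code{"no"}/\code{"yes"}.
#' Only \code{education}, \code{disposable_income} and
#' \code{any_severe_mental_disorder} may be declared wholly absent in a
#' validation dataset.
#'
#' @return A named list; each element has \code{type} and (for discrete
#'   predictors) \code{levels}.
#' @export
oxrec_predictors <- function() {
  bin <- function() list(type = "binary", levels = c("no", "yes"))
  list(
    gender                     = list(type = "categorical", levels = c("male", "female")),
    age_at_release             = list(type = "continuous"),
    immigrant_status           = bin(),
    incarceration_length       = list(type = "categorical",
                                      levels = c("<6m", "6-12m", "12-24m", ">=24m")),
    violent_index_offence      = bin(),
    previous_violent_crime     = bin(),
    civil_status               = list(type = "categorical", levels = c("unmarried", "other")),
    education                  = list(type = "categorical", levels = c("<9y", "9-11y", ">=12y")),
    employment                 = bin(),
    disposable_income          = list(type = "categorical",
                                      levels = c("negative", "zero", "low", "medium", "high")),
    neighbourhood_deprivation  = list(type = "continuous"),
    alcohol_use_disorder       = bin(),
    drug_use_disorder          = bin(),
    any_mental_disorder        = bin(),
    any_severe_mental_disorder = bin()
  )
}

# Predictors that may legally be wholly absent from a cohort.
absent_allowed <- function() {
  c("education", "disposable_income", "any_severe_mental_disorder")
}

#' Validate a cohort table against the predictor schema
#'
#' Checks that every non-absent predictor column is present, that discrete
#' columns only contain known levels (or \code{NA} missing markers), and
#' that ages are adult.  Absent predictors may be missing entirely or be
#' all-\code{NA} columns.
#'
#' @param table data.frame with one row per individual.
#' @param absent character vector of wholly absent predictors.
#' @param allow_missing if \code{FALSE}, any \code{NA} in a non-absent
#'   predictor is an error (scoring requires imputed data).
#' @return the table, invisibly.
#' @export
validate_cohort <- function(table, absent = character(), allow_missing = TRUE) {
  schema <- oxrec_predictors()
  bad_absent <- setdiff(absent, absent_allowed())
  if (length(bad_absent)) {
    stop("predictor(s) not allowed to be wholly absent: ",
         paste(bad_absent, collapse = ", "))
  }
  for (p in names(schema)) {
    if (p %in% absent) next
    if (!p %in% names(table)) {
      stop("cohort is missing predictor column '", p,
           "' (declare it in `absent` if wholly unavailable)")
    }
    x <- table[[p]]
    if (!allow_missing && anyNA(x)) {
      stop("predictor '", p, "' contains missing values; impute first ",
           "(see mice_impute())")
    }
    info <- schema[[p]]
    if (info$type == "continuous") {
      if (!is.numeric(x)) stop("predictor '", p, "' must be numeric")
    } else {
      vals <- unique(as.character(x[!is.na(x)]))
      unknown <- setdiff(vals, info$levels)
      if (length(unknown)) {
        stop("unknown level(s) for predictor '", p, "': ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  if ("age_at_release" %in% names(table)) {
    a <- table$age_at_release
    if (any(!is.na(a) & a < 18)) stop("age_at_release must be >= 18")
  }
  invisible(table)
}
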