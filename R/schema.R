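#' Covariate schema for a cohort
#'
#' A schema records which columns of a person-period table are exposures and
#' which are categorical covariates, together with each covariate's allowed
#' category labels. The first label of each covariate is its reference level,
#' used for treatment coding in all model fits.
#'
#' @param covariates Named list; each element is a character vector of allowed
#'   category labels, the first being the reference level.
#' @param exposures Character vector of exposure column names (annual means).
#'
#' @return An object of class `airmix_schema`.
#' @examples
#' cohort_schema(covariates = list(sex = c("male", "female")))
#' @export
cohort_schema <- function(covariates = list(), exposures = c("pm25", "o3", "temp")) {
  stopifnot(is.list(covariates))
  if (length(covariates) > 0 && (is.null(names(covariates)) || any(names(covariates) == ""))) {
    abort("every covariate in the schema must be named")
  }
  for (v in names(covariates)) {
    lev <- covariates[[v]]
    if (!is.character(lev) || length(lev) < 1 || anyDuplicated(lev)) {
      abort(paste0("covariate '", v, "' needs a character vector of distinct levels"))
    }
  }
  structure(
    list(exposures = exposures, covariates = covariates),
    class = "airmix_schema"
  )
}

#' @export
print.airmix_schema <- function(x, ...) {
  cat("<airmix_schema>\n")
  cat("  exposures: ", paste(x$exposures, collapse = ", "), "\n", sep = "")
  for (v in names(x$covariates)) {
    cat("  ", v, ": ", paste(x$covariates[[v]], collapse = " | "),
        "  (ref = ", x$covariates[[v]][1], ")\n", sep = "")
  }
  invisible(x)
}

#' Default covariate category probabilities
#'
#' Category frequencies of the adjustment covariates in a Chinese ageing-cohort
#' population of adults aged 50+, used as the synthetic generator's default
#' margins. Each element is a named probability vector over the covariate's
#' levels; the first level is the modelling reference.
#'
#' @return Named list of named numeric vectors, each summing to 1.
#' @examples
#' sapply(default_covariate_margins(), sum)
#' @export
default_covariate_margins <- function() {
  list(
    age_group  = c("50-64" = 0.6525, "65+" = 0.3475),
    sex        = c("male" = 0.4789, "female" = 0.5211),
    urbanicity = c("rural" = 0.5743, "urban" = 0.4257),
    region     = c("south" = 0.6194, "north" = 0.3806),
    marital    = c("married" = 0.8645, "unmarried" = 0.1355),
    bmi_group  = c("normal" = 0.5516, "overweight" = 0.3265, "obese" = 0.1219),
    fuel       = c("clean" = 0.5466, "unclean" = 0.4534),
    smoking    = c("never" = 0.6680, "ever" = 0.3320),
    drinking   = c("never" = 0.6801, "ever" = 0.3199),
    income     = c("high" = 0.5072, "low" = 0.4928),
    education  = c("none" = 0.3997, "primary" = 0.2122, "middle_plus" = 0.3881)
  )
}

#' Default cohort schema
#'
#' Schema matching [default_covariate_margins()]: the standard adjustment set
#' (age group, sex, urbanicity, region, marital status, BMI class, cooking
#' fuel, smoking, drinking, income, education) plus the three exposure columns
#' `pm25`, `o3` and `temp`.
#'
#' @return An `airmix_schema`.
#' @export
default_schema <- function() {
  margins <- default_covariate_margins()
  cohort_schema(covariates = lapply(margins, names))
}

schema_covariate_names <- function(schema) names(schema$covariates)

assert_schema <- function(schema) {
  if (!inherits(schema, "airmix_schema")) abort("`schema` must be an `airmix_schema`")
  invisible(schema)
}
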