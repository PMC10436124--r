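#' Person-period cohort tables
#'
#' A cohort is a tibble in counting-process (start-stop) form: one row per
#' subject-interval with columns `subject_id`, `start`, `stop`, `event`, one
#' numeric column per exposure and one categorical column per covariate.
#' Within a subject the intervals `(start, stop]` are non-overlapping and
#' ordered, and at most the last interval carries `event = 1`. Time is
#' measured in years on study.
#'
#' @name cohort
NULL

required_cohort_cols <- c("subject_id", "start", "stop", "event")

#' Validate a person-period cohort table
#'
#' Checks the counting-process contract: required columns present, `start <
#' stop` on every row, `event` binary, at most one event per subject and only
#' on the subject's last interval, no missing values in the exposure or
#' covariate columns, and covariate labels drawn from the schema.
#'
#' @param data Person-period tibble.
#' @param schema An [cohort_schema()]; defaults to the schema attached to
#'   `data` (as attribute `"schema"`), if any.
#' @return `data`, invisibly, with covariates converted to schema-levelled
#'   factors and the schema attached.
#' @export
validate_cohort <- function(data, schema = attr(data, "schema")) {
  missing_cols <- setdiff(required_cohort_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(data$start < data$stop))
  if (length(bad) > 0) {
    abort(paste0("start >= stop at row(s) ", paste(head(bad, 5), collapse = ", ")))
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("`event` must be 0 or 1 on every row")
  }
  ord <- order(data$subject_id, data$start)
  sid <- data$subject_id[ord]
  new_subj <- c(TRUE, sid[-1] != sid[-length(sid)])
  overlap <- !new_subj & data$start[ord] < c(-Inf, data$stop[ord][-length(ord)])
  if (any(overlap)) {
    abort("overlapping intervals within a subject")
  }
  last_of_subj <- c(new_subj[-1], TRUE)
  if (any(data$event[ord] == 1 & !last_of_subj)) {
    abort("event = 1 on a non-final interval of a subject")
  }
  ev_per_subj <- tapply(data$event, data$subject_id, sum)
  if (any(ev_per_subj > 1)) {
    abort("a subject has more than one event record")
  }

  if (!is.null(schema)) {
    assert_schema(schema)
    for (v in names(schema$covariates)) {
      if (!v %in% names(data)) {
        abort(paste0("cohort is missing schema covariate '", v, "'"))
      }
      lev <- schema$covariates[[v]]
      vals <- as.character(data[[v]])
      if (anyNA(vals)) abort(paste0("missing values in covariate '", v, "'"))
      unknown <- setdiff(unique(vals), lev)
      if (length(unknown) > 0) {
        abort(paste0("covariate '", v, "' has label(s) outside the schema: ",
                     paste(unknown, collapse = ", ")))
      }
      data[[v]] <- factor(vals, levels = lev)
    }
    for (e in intersect(schema$exposures, names(data))) {
      if (anyNA(data[[e]])) abort(paste0("missing values in exposure '", e, "'"))
    }
    attr(data, "schema") <- schema
  }
  invisible(data)
}

#' Read a person-period cohort from CSV
#'
#' @param path CSV file with a header row; required columns `subject_id`,
#'   `start`, `stop`, `event`, plus one column per exposure and covariate in
#'   the schema.
#' @param schema An [cohort_schema()] describing the covariate columns.
#' @return A validated cohort tibble with the schema attached.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  assert_schema(schema)
  # base read.csv: its double parsing is correctly rounded, so a
  # write_cohort() round trip is exact to the last bit
  data <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(
    c(required_cohort_cols, schema$exposures, names(schema$covariates)),
    names(data)
  )
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- validate_cohort(tibble::as_tibble(data), schema)
  out
}

#' Write a person-period cohort to CSV
#'
#' Numeric columns are written at full precision so that a
#' write/read round trip reproduces the cohort exactly.
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- data
  for (v in names(out)) {
    if (is.double(out[[v]])) out[[v]] <- sprintf("%.17g", out[[v]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Total person-years of follow-up
#'
#' @param data Cohort tibble.
#' @return Sum of `stop - start` over all records.
#' @export
person_years <- function(data) sum(data$stop - data$start)

#' Expand subject-level follow-up into counting-process records
#'
#' Splits each subject's follow-up `(0, time]` (years on study) at calendar
#' year boundaries and attaches the matching annual exposure means, producing
#' one record per subject-calendar-year intersected with follow-up. Exposure
#' columns are constant within a record; the event indicator sits on the
#' record containing the event time. Intervals are half-open `(start, stop]`,
#' so censoring exactly at a year boundary emits no zero-length record.
#'
#' @param followup Subject-level tibble: `subject_id`, `time` (exit time in
#'   years since baseline, > 0), `event` (0/1), plus any covariate columns to
#'   carry through.
#' @param annual_exposures Tibble of `subject_id`, `year` (calendar year) and
#'   one column per exposure; must cover every calendar year intersecting each
#'   subject's follow-up.
#' @param baseline_year Calendar year containing study time 0.
#' @return Person-period cohort tibble.
#' @export
expand_counting_process <- function(followup, annual_exposures, baseline_year = 2008) {
  stopifnot(all(c("subject_id", "time", "event") %in% names(followup)),
            all(c("subject_id", "year") %in% names(annual_exposures)))
  if (any(followup$time <= 0)) abort("follow-up `time` must be positive")

  n_rec <- ceiling(followup$time)
  idx <- rep.int(seq_len(nrow(followup)), n_rec)
  k <- sequence(n_rec) - 1L                      # year-on-study index, 0-based
  start <- as.numeric(k)
  stop <- pmin(k + 1, followup$time[idx])

  out <- followup[idx, , drop = FALSE]
  out$start <- start
  out$stop <- stop
  out$event <- ifelse(stop == followup$time[idx], followup$event[idx], 0L)
  out$year <- baseline_year + k
  out$time <- NULL

  merged <- dplyr::left_join(out, annual_exposures, by = c("subject_id", "year"))
  expo_cols <- setdiff(names(annual_exposures), c("subject_id", "year"))
  for (e in expo_cols) {
    if (anyNA(merged[[e]])) {
      miss <- merged[is.na(merged[[e]]), c("subject_id", "year")]
      abort(paste0("no exposure value for subject ", miss$subject_id[1],
                   " in calendar year ", miss$year[1]))
    }
  }
  cols <- c("subject_id", "start", "stop", "event", "year", expo_cols,
            setdiff(names(merged), c("subject_id", "start", "stop", "event", "year", expo_cols)))
  tibble::as_tibble(merged[, cols])
}
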