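#' Quartile cut points for an exposure
#'
#' Computes the 25th/50th/75th percentiles of an exposure over all
#' person-period records (type-7 linear interpolation), for use in quartile
#' coding. Since the fitted covariate is the record-level annual mean, the
#' percentiles are taken over records, not subjects.
#'
#' @param data Cohort tibble (or any data frame holding the column).
#' @param exposure Name of the exposure column.
#' @return A `quantile_spec`: list with `exposure`, `cuts` (length-3 ascending)
#'   and `source = "empirical"`.
#' @export
quantile_cuts <- function(data, exposure) {
  x <- data[[exposure]]
  if (is.null(x)) abort(paste0("no column '", exposure, "' in the data"))
  cuts <- unname(quantile(x, probs = c(0.25, 0.50, 0.75), type = 7, names = FALSE))
  quantile_spec(exposure, cuts, source = "empirical")
}

#' Construct a quantile specification
#'
#' @param exposure Exposure name.
#' @param cuts Three strictly increasing finite cut points (q25, q50, q75).
#' @param source `"empirical"` or `"fixed"`.
#' @return A `quantile_spec` object.
#' @export
quantile_spec <- function(exposure, cuts, source = "fixed") {
  cuts <- as.numeric(cuts)
  if (length(cuts) != 3 || any(!is.finite(cuts))) {
    abort("`cuts` must be three finite values (q25, q50, q75)")
  }
  if (any(diff(cuts) <= 0)) {
    abort(paste0("degenerate quantiles for '", exposure,
                 "': cut points must be strictly increasing"))
  }
  structure(list(exposure = exposure, cuts = cuts, source = source),
            class = "quantile_spec")
}

#' @export
print.quantile_spec <- function(x, ...) {
  cat("<quantile_spec> ", x$exposure, " (", x$source, "): ",
      paste(signif(x$cuts, 6), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Serialize / read a quantile specification as JSON
#'
#' @param spec A `quantile_spec`.
#' @param path JSON file path.
#' @return `write_quantile_spec()` returns `path` invisibly;
#'   `read_quantile_spec()` returns the `quantile_spec`.
#' @export
write_quantile_spec <- function(spec, path) {
  jsonlite::write_json(list(exposure = spec$exposure, cuts = spec$cuts,
                            source = spec$source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quantile_spec
#' @export
read_quantile_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  quantile_spec(x$exposure, x$cuts, source = x$source)
}

#' Quartile-code an exposure
#'
#' Adds an integer column `<exposure>_q` with quartile codes 0-3 using
#' right-closed bins: `x <= q25 -> 0`, `q25 < x <= q50 -> 1`,
#' `q50 < x <= q75 -> 2`, `x > q75 -> 3`. Values exactly at a cut point fall
#' in the lower category. Coding is monotone in the exposure.
#'
#' @param data Cohort tibble.
#' @param exposure Exposure column name.
#' @param spec A `quantile_spec`, or `"empirical"` (default) to derive cut
#'   points from `data` via [quantile_cuts()].
#' @return `data` with the added `<exposure>_q` column; the spec used is
#'   attached as attribute `"quantile_spec_<exposure>"`.
#' @examples
#' d <- tibble::tibble(pm25 = c(1, 2, 3, 4))
#' quantize(d, "pm25")$pm25_q
#' @export
quantize <- function(data, exposure, spec = "empirical") {
  if (identical(spec, "empirical")) spec <- quantile_cuts(data, exposure)
  if (!inherits(spec, "quantile_spec")) abort("`spec` must be a quantile_spec or \"empirical\"")
  x <- data[[exposure]]
  if (is.null(x)) abort(paste0("no column '", exposure, "' in the data"))
  if (anyNA(x)) abort(paste0("missing values in exposure '", exposure, "'"))
  data[[paste0(exposure, "_q")]] <- quantile_code(x, spec$cuts)
  attr(data, paste0("quantile_spec_", exposure)) <- spec
  data
}

# right-closed binning against three ascending cuts
quantile_code <- function(x, cuts) {
  (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
}
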