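#' Calibration response functions
#'
#' A `response_function` holds a fitted (or exactly specified) calibration
#' model linking concentration to instrument response:
#' `response = slope * concentration + intercept`. Supported model kinds:
#'
#' * `ols_linear` — unweighted least squares;
#' * `single_point_origin` — a line through the origin through the mean
#'   response of the top standard (one-point calibration);
#' * `weighted_1_over_x`, `weighted_1_over_x2` — weighted least squares with
#'   weights `1/C` and `1/C^2` (optional candidates, off by default in
#'   [compare_response_models()]).
#'
#' @param model_kind One of the kinds above.
#' @param slope,intercept Line coefficients; `slope` must be non-zero for an
#'   invertible calibration.
#' @param se_slope,se_intercept Standard errors (NA where undefined; a
#'   single-point model has no intercept uncertainty).
#' @param r_squared Coefficient of determination, in `[0, 1]` where defined.
#' @param n_points Number of standards used.
#' @param series_id Label of the series the fit belongs to, or `"pooled"`.
#' @return An object of class `response_function`.
#' @export
response_function <- function(model_kind, slope, intercept = 0,
                              se_slope = NA_real_, se_intercept = NA_real_,
                              r_squared = NA_real_, n_points = NA_integer_,
                              series_id = "pooled") {
  kinds <- c("single_point_origin", "ols_linear",
             "weighted_1_over_x", "weighted_1_over_x2")
  model_kind <- match.arg(model_kind, kinds)
  check_number(slope, "slope", allow_zero = FALSE)
  check_number(intercept, "intercept")
  if (model_kind == "single_point_origin" && intercept != 0) {
    stop_design("a single-point model has intercept exactly 0")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop_fit("`r_squared` must lie in [0, 1]")
  }
  structure(
    list(model_kind = model_kind, slope = slope, intercept = intercept,
         se_slope = se_slope, se_intercept = se_intercept,
         r_squared = r_squared, n_points = n_points,
         series_id = as.character(series_id)),
    class = "response_function"
  )
}

#' Fit a calibration response function
#'
#' @param standards A data frame with columns `concentration` and `response`.
#' @param model_kind Model to fit; see [response_function()]. Least-squares
#'   kinds need at least two distinct concentrations; `single_point_origin`
#'   uses only the standards at the highest concentration.
#' @param series_id Label stored on the fit (`"pooled"` by default).
#' @return A [response_function].
#' @examples
#' std <- tibble::tibble(concentration = 1:3, response = c(2, 4, 6))
#' fit_response(std, "ols_linear")
#' @export
fit_response <- function(standards,
                         model_kind = c("ols_linear", "single_point_origin",
                                        "weighted_1_over_x",
                                        "weighted_1_over_x2"),
                         series_id = "pooled") {
  model_kind <- match.arg(model_kind)
  check_columns(standards, c("concentration", "response"), "`standards`")
  standards <- dplyr::filter(standards, !is.na(.data$concentration),
                             !is.na(.data$response))
  if (nrow(standards) == 0L) stop_fit("no usable standards")

  if (model_kind == "single_point_origin") {
    top <- max(standards$concentration)
    if (top <= 0) stop_fit("top standard concentration must be positive")
    y <- standards$response[standards$concentration == top]
    return(response_function("single_point_origin",
                             slope = mean(y) / top, intercept = 0,
                             n_points = length(y), series_id = series_id))
  }

  if (length(unique(standards$concentration)) < 2L) {
    stop_fit("least-squares fit needs at least two distinct concentrations")
  }
  w <- switch(model_kind,
    ols_linear = NULL,
    weighted_1_over_x = 1 / standards$concentration,
    weighted_1_over_x2 = 1 / standards$concentration^2
  )
  if (!is.null(w) && any(!is.finite(w))) {
    stop_fit("weighted fits require strictly positive concentrations")
  }
  fit <- lm(response ~ concentration, data = standards, weights = w)
  sm <- quiet_lm_summary(fit)
  response_function(
    model_kind,
    slope = unname(coef(fit)[["concentration"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    se_slope = sm$coefficients["concentration", "Std. Error"],
    se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared,
    n_points = nrow(standards),
    series_id = series_id
  )
}

#' Back-calculate concentrations by inverse prediction
#'
#' @param fn A [response_function].
#' @param response Numeric vector of instrument responses.
#' @return Concentrations, `(response - intercept) / slope`.
#' @export
back_calculate <- function(fn, response) {
  stopifnot(inherits(fn, "response_function"))
  if (fn$slope == 0) stop_fit("response function is not invertible (slope 0)")
  (response - fn$intercept) / fn$slope
}

#' Convert a level (% of nominal) to a medium concentration
#'
#' The nominal (100%) concentration is the one reached when the full label
#' dose dissolves in the vessel: `label_dose * 1000 / medium_volume` ug/mL
#' (55.56 ug/mL for a 50 mg tablet in 900 mL).
#'
#' @param level_pct Level(s) as % of nominal.
#' @param label_dose_mg Label claim of the dosage unit, mg.
#' @param medium_volume_ml Dissolution medium volume, mL.
#' @param digits Decimals for the reported value (default 2, the convention
#'   for concentration tables); use `NULL` for full precision.
#' @return Concentration(s), ug/mL.
#' @examples
#' percent_to_concentration(c(5, 100, 120)) # 2.78, 55.56, 66.67
#' @export
percent_to_concentration <- function(level_pct, label_dose_mg = 50,
                                     medium_volume_ml = 900, digits = 2) {
  if (any(level_pct <= 0)) stop_design("`level_pct` must be positive")
  check_number(label_dose_mg, "label_dose_mg", lower = 1e-12)
  check_number(medium_volume_ml, "medium_volume_ml", lower = 1e-12)
  conc <- level_pct / 100 * (label_dose_mg * 1000 / medium_volume_ml)
  if (is.null(digits)) conc else round(conc, digits)
}

#' Regression-based limit of detection
#'
#' `LOD = 3.3 * SD_b / s`, where `SD_b` is the standard error of the fitted
#' intercept and `s` the slope of the calibration line (ICH Q2 style).
#'
#' @param fn A [response_function] with a defined intercept standard error
#'   (i.e. a least-squares kind, not `single_point_origin`).
#' @param nominal_concentration Optional nominal (100%) concentration used to
#'   also express the LOD as % of nominal.
#' @return A one-row tibble with `lod_conc` (ug/mL) and, when the nominal is
#'   supplied, `lod_pct`.
#' @export
lod_from_regression <- function(fn, nominal_concentration = NULL) {
  stopifnot(inherits(fn, "response_function"))
  if (fn$model_kind == "single_point_origin" || is.na(fn$se_intercept)) {
    stop_fit("LOD needs a least-squares fit with an intercept standard error")
  }
  lod <- 3.3 * fn$se_intercept / abs(fn$slope)
  out <- tibble::tibble(lod_conc = lod)
  if (!is.null(nominal_concentration)) {
    check_number(nominal_concentration, "nominal_concentration", lower = 1e-12)
    out$lod_pct <- 100 * lod / nominal_concentration
  }
  out
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function: %s, series %s>\n", x$model_kind,
              x$series_id))
  cat(sprintf("  response = %.6g * C + %.6g", x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("   (r^2 = %.4f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @rdname response_function
#' @param x A `response_function`.
#' @param ... Unused.
#' @export
tidy.response_function <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @rdname response_function
#' @export
glance.response_function <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, series_id = x$series_id,
                 slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, nobs = x$n_points)
}
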