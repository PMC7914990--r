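#' Configuration for simulated calibration and validation experiments
#'
#' Describes the multi-series validation design the simulator emulates: `p`
#' series (days) of `n` replicates at `m` concentration levels expressed as a
#' percentage of the nominal concentration reached when one tablet dissolves
#' completely in the vessel (55.56 ug/mL for a 50 mg tablet in 900 mL).
#'
#' Noise is Gaussian and relative: within-series and between-series effects
#' are specified as a percent RSD of the noise-free value, matching the
#' roughly level-independent RSDs seen in real spectrophotometric assays.
#' The between-series effect is drawn once per series per level (the one-way
#' random-effects model the downstream statistics assume); in addition the
#' calibration simulator perturbs the slope once per series to emulate
#' day-to-day calibration drift.
#'
#' @param nominal_concentration Concentration (ug/mL) corresponding to the
#'   100% level. Default 55.56 (50 mg tablet in 900 mL medium).
#' @param level_percents Concentration levels as % of nominal, strictly
#'   increasing. Default `c(5, 10, 25, 50, 75, 100, 120)`.
#' @param p_series Number of series (days), at least 2.
#' @param n_replicates Replicates per series per level, at least 2.
#' @param true_slope True response per ug/mL of the instrument.
#' @param true_intercept True intercept, response units.
#' @param slope_series_rsd Between-series RSD (%) of the calibration slope.
#' @param relative_bias_per_level True relative bias (%) of the procedure at
#'   each level; a scalar or a vector of length `length(level_percents)`.
#'   The default is the per-level bias pattern typical of a validated
#'   dissolution assay (between -2.3 and +3.5%).
#' @param sigma_within_pct Within-series (repeatability) RSD, %.
#' @param sigma_between_pct Between-series RSD, %.
#' @param seed Integer seed; mandatory, no global random state is consulted.
#'
#' @return An object of class `validation_sim_config`.
#' @seealso [simulate_calibration()], [simulate_validation()]
#' @export
validation_sim_config <- function(nominal_concentration = 55.56,
                                  level_percents = c(5, 10, 25, 50, 75, 100, 120),
                                  p_series = 3,
                                  n_replicates = 3,
                                  true_slope = 3.5,
                                  true_intercept = 0.0015,
                                  slope_series_rsd = 0.1,
                                  relative_bias_per_level =
                                    c(-2.3, 3.3, 1.0, 2.3, 3.5, 0.3, 1.6),
                                  sigma_within_pct = 1.0,
                                  sigma_between_pct = 1.0,
                                  seed = 1L) {
  check_number(nominal_concentration, "nominal_concentration", lower = 1e-12)
  if (!is.numeric(level_percents) || length(level_percents) < 1L ||
      any(level_percents <= 0) || is.unsorted(level_percents, strictly = TRUE)) {
    stop_design("`level_percents` must be positive and strictly increasing")
  }
  p_series <- check_count(p_series, "p_series", lower = 2L)
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 2L)
  check_number(true_slope, "true_slope", allow_zero = FALSE)
  check_number(true_intercept, "true_intercept")
  check_number(slope_series_rsd, "slope_series_rsd", lower = 0)
  check_number(sigma_within_pct, "sigma_within_pct", lower = 0)
  check_number(sigma_between_pct, "sigma_between_pct", lower = 0)
  m <- length(level_percents)
  if (length(relative_bias_per_level) == 1L) {
    relative_bias_per_level <- rep(relative_bias_per_level, m)
  }
  if (length(relative_bias_per_level) != m) {
    stop_design("`relative_bias_per_level` must be scalar or one value per level")
  }
  seed <- check_count(seed, "seed", lower = 0L)

  structure(
    list(
      nominal_concentration = nominal_concentration,
      level_percents = level_percents,
      p_series = p_series,
      n_replicates = n_replicates,
      true_slope = true_slope,
      true_intercept = true_intercept,
      slope_series_rsd = slope_series_rsd,
      relative_bias_per_level = relative_bias_per_level,
      sigma_within_pct = sigma_within_pct,
      sigma_between_pct = sigma_between_pct,
      seed = seed
    ),
    class = "validation_sim_config"
  )
}

sim_concentrations <- function(config) {
  config$level_percents / 100 * config$nominal_concentration
}

#' Simulate a multi-series calibration experiment
#'
#' Generates instrument responses for calibration standards measured in
#' `n_replicates` replicates at each level of each of `p_series` series.
#' Each series draws its own slope (relative Gaussian perturbation of
#' `true_slope` with RSD `slope_series_rsd`), emulating day-wise calibration
#' lines; replicate noise is Gaussian with RSD `sigma_within_pct` of the
#' noise-free response. Output is bit-identical for identical config + seed.
#'
#' @param config A [validation_sim_config()].
#' @return A tibble with columns `series`, `replicate`, `level_pct`,
#'   `concentration` (ug/mL) and `response`.
#' @export
simulate_calibration <- function(config) {
  stopifnot(inherits(config, "validation_sim_config"))
  conc <- sim_concentrations(config)
  withr::with_seed(config$seed, {
    slopes <- config$true_slope *
      (1 + rnorm(config$p_series, 0, config$slope_series_rsd / 100))
    grid <- tidyr::expand_grid(
      series = seq_len(config$p_series),
      level_pct = config$level_percents,
      replicate = seq_len(config$n_replicates)
    )
    grid |>
      dplyr::mutate(
        concentration = .data$level_pct / 100 * config$nominal_concentration,
        clean = slopes[.data$series] * .data$concentration + config$true_intercept,
        response = .data$clean *
          (1 + rnorm(dplyr::n(), 0, config$sigma_within_pct / 100))
      ) |>
      dplyr::select("series", "replicate", "level_pct", "concentration",
                    "response")
  })
}

#' Simulate a multi-series validation experiment
#'
#' Generates responses for validation standards (placebo matrix spiked at
#' known concentrations). The measured quantity is the true concentration
#' distorted by the configured per-level relative bias, a per-series-per-level
#' random effect (RSD `sigma_between_pct`) and replicate noise (RSD
#' `sigma_within_pct`); the response is that quantity read through the true
#' calibration line. Back-calculating through the true line therefore
#' recovers exactly `C * (1 + bias/100) * (1 + series effect + replicate
#' noise)`, so the trueness/precision estimators can be checked against the
#' configured truths.
#'
#' @inheritParams simulate_calibration
#' @return A tibble with columns `series`, `replicate`, `level_pct`,
#'   `true_concentration` (ug/mL) and `response`.
#' @export
simulate_validation <- function(config) {
  stopifnot(inherits(config, "validation_sim_config"))
  bias <- setNames(config$relative_bias_per_level,
                   as.character(config$level_percents))
  withr::with_seed(config$seed, {
    series_effect <- array(
      rnorm(config$p_series * length(config$level_percents),
            0, config$sigma_between_pct / 100),
      dim = c(config$p_series, length(config$level_percents)),
      dimnames = list(NULL, as.character(config$level_percents))
    )
    grid <- tidyr::expand_grid(
      series = seq_len(config$p_series),
      level_pct = config$level_percents,
      replicate = seq_len(config$n_replicates)
    )
    grid |>
      dplyr::mutate(
        true_concentration = .data$level_pct / 100 * config$nominal_concentration,
        biased = .data$true_concentration *
          (1 + unname(bias[as.character(.data$level_pct)]) / 100),
        measured = .data$biased * (
          1 + series_effect[cbind(.data$series,
                                  match(.data$level_pct,
                                        config$level_percents))] +
            rnorm(dplyr::n(), 0, config$sigma_within_pct / 100)
        ),
        response = config$true_slope * .data$measured + config$true_intercept
      ) |>
      dplyr::select("series", "replicate", "level_pct", "true_concentration",
                    "response")
  })
}

#' The true calibration line of a simulation config
#'
#' Convenience constructor for the noise-free [response_function] implied by
#' a simulation config, so simulated validation responses can be
#' back-calculated without calibration-fit uncertainty.
#'
#' @param config A [validation_sim_config()].
#' @return A `response_function`.
#' @export
true_response_function <- function(config) {
  stopifnot(inherits(config, "validation_sim_config"))
  response_function(model_kind = "ols_linear", slope = config$true_slope,
                    intercept = config$true_intercept, series_id = "truth")
}

#' Configuration for simulated dissolution runs
#'
#' Per-unit release follows a first-order profile
#' `F(t) = f_inf * (1 - exp(-k t))`, scaled by a per-unit lognormal-free
#' Gaussian factor (RSD `unit_rsd`) representing tablet-to-tablet
#' variability; each analytical method observes the same trajectories with
#' independent Gaussian measurement noise (RSD `measurement_rsd`).
#'
#' @param n_units Number of dosage units, default 12 (the compendial
#'   "not less than 12 units").
#' @param time_points Sampling times in minutes, strictly increasing.
#' @param f_inf Asymptotic release, % of label claim (0 < f_inf <= 110).
#' @param rate_k First-order rate constant, per minute.
#' @param unit_rsd Between-unit RSD of the release plateau, %.
#' @param measurement_rsd Analytical measurement RSD, %.
#' @param seed Integer seed.
#' @return An object of class `dissolution_sim_config`.
#' @export
dissolution_sim_config <- function(n_units = 12,
                                   time_points = c(5, 10, 15, 20, 30, 60),
                                   f_inf = 100,
                                   rate_k = 0.15,
                                   unit_rsd = 2.5,
                                   measurement_rsd = 1.0,
                                   seed = 1L) {
  n_units <- check_count(n_units, "n_units", lower = 1L)
  if (!is.numeric(time_points) || length(time_points) < 1L ||
      is.unsorted(time_points, strictly = TRUE)) {
    stop_design("`time_points` must be strictly increasing")
  }
  check_number(f_inf, "f_inf", lower = 1e-12, upper = 110)
  check_number(rate_k, "rate_k", lower = 1e-12)
  check_number(unit_rsd, "unit_rsd", lower = 0)
  check_number(measurement_rsd, "measurement_rsd", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(
    list(n_units = n_units, time_points = time_points, f_inf = f_inf,
         rate_k = rate_k, unit_rsd = unit_rsd,
         measurement_rsd = measurement_rsd, seed = seed),
    class = "dissolution_sim_config"
  )
}

#' Simulate a paired dissolution experiment (two analytical methods)
#'
#' Both methods measure the same per-unit first-order release trajectories
#' with independent measurement noise, so the pair is exchangeable under the
#' null hypothesis of no method difference and suitable for paired
#' comparisons.
#'
#' @param config A [dissolution_sim_config()].
#' @return A tibble with columns `method` (`"test"` / `"reference"`), `unit`,
#'   `time_min` and `release_pct`, paired by `unit`.
#' @export
simulate_dissolution_pair <- function(config) {
  stopifnot(inherits(config, "dissolution_sim_config"))
  withr::with_seed(config$seed, {
    unit_factor <- 1 + rnorm(config$n_units, 0, config$unit_rsd / 100)
    traj <- tidyr::expand_grid(
      unit = seq_len(config$n_units),
      time_min = config$time_points
    ) |>
      dplyr::mutate(
        truth = config$f_inf * (1 - exp(-config$rate_k * .data$time_min)) *
          unit_factor[.data$unit]
      )
    out <- tidyr::expand_grid(
      method = c("test", "reference"),
      unit = seq_len(config$n_units),
      time_min = config$time_points
    ) |>
      dplyr::left_join(traj, by = c("unit", "time_min")) |>
      dplyr::mutate(
        release_pct = .data$truth *
          (1 + rnorm(dplyr::n(), 0, config$measurement_rsd / 100))
      ) |>
      dplyr::select("method", "unit", "time_min", "release_pct")
    out
  })
}
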