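# CSV schemas: comma delimiter, dot decimal, header required. Readers are
# strict: missing columns, non-numeric cells and duplicate keys are errors
# naming the offending column/rows; blank lines are ignored.

read_strict_csv <- function(path, numeric_cols, what, key_cols = NULL,
                            optional_numeric = character(0)) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, skip_empty_rows = TRUE)
  check_columns(raw, numeric_cols, sprintf("%s file '%s'", what, path))
  to_num <- intersect(c(numeric_cols, optional_numeric), names(raw))
  for (col in to_num) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop_data(sprintf("%s file '%s': non-numeric value in column '%s', row %d",
                        what, path, col, bad[1L]))
    }
    raw[[col]] <- parsed
  }
  if (!is.null(key_cols) && all(key_cols %in% names(raw))) {
    dup <- duplicated(raw[key_cols])
    if (any(dup)) {
      stop_data(sprintf("%s file '%s': duplicate (%s) at row %d", what, path,
                        paste(key_cols, collapse = ", "), which(dup)[1L]))
    }
  }
  raw
}

#' Read the pipeline's CSV schemas
#'
#' Strict readers for the four tabular inputs: calibration standards
#' (`series`, `level_pct`, `concentration`, `response`), validation
#' standards (`series`, `level_pct`, `true_concentration`, `response`),
#' dissolution samples (`unit`, `time_min`, and `concentration` and/or
#' `release_pct`) and zone-fluidics sequences (the [zf_sequence()] columns).
#' An optional `replicate` column keys duplicate detection in the standard
#' sets. Files use comma delimiters and dot decimals; a blank line at EOF is
#' ignored.
#'
#' @param path Path to a CSV file.
#' @return A typed tibble ([read_zf_sequence_csv()] returns a
#'   [zf_sequence()]).
#' @export
read_calibration_csv <- function(path) {
  read_strict_csv(path, c("series", "level_pct", "concentration", "response"),
                  "calibration", key_cols = c("series", "level_pct", "replicate"),
                  optional_numeric = "replicate")
}

#' @rdname read_calibration_csv
#' @export
read_validation_csv <- function(path) {
  read_strict_csv(path,
                  c("series", "level_pct", "true_concentration", "response"),
                  "validation", key_cols = c("series", "level_pct", "replicate"),
                  optional_numeric = "replicate")
}

#' @rdname read_calibration_csv
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c")))
  value_col <- intersect(c("concentration", "release_pct"), header)
  if (length(value_col) == 0L) {
    stop_data(sprintf(
      "dissolution file '%s' needs a 'concentration' or 'release_pct' column",
      path))
  }
  read_strict_csv(path, c("unit", "time_min", value_col), "dissolution",
                  key_cols = c("unit", "time_min"),
                  optional_numeric = c("concentration", "release_pct"))
}

#' @rdname read_calibration_csv
#' @export
read_zf_sequence_csv <- function(path) {
  raw <- read_strict_csv(path, c("step", "duration_s", "valve_position"),
                         "sequence",
                         optional_numeric = c("flow_rate_ml_min", "volume_ul"))
  check_columns(raw, c("action", "flow_rate_ml_min", "volume_ul"),
                sprintf("sequence file '%s'", path))
  zf_sequence(raw)
}

#' Assemble a pipeline run configuration
#'
#' Collects everything one validation run depends on: the design, the
#' nominal dose/volume, the calibration model candidates and the decision
#' thresholds. Data come either from CSV paths (`calibration_path`,
#' `validation_path`) or from the built-in simulator (`simulate = TRUE`,
#' using `sim_config`).
#'
#' @param design A [validation_design()].
#' @param label_dose_mg,medium_volume_ml Nominal dose (mg) and medium
#'   volume (mL) defining the 100% concentration.
#' @param candidates Calibration model kinds to compare; the first entry is
#'   used when `compare_models = FALSE`.
#' @param compare_models Run [compare_response_models()] and use its
#'   selection (default) instead of the first candidate.
#' @param robustness_threshold_pct,placebo_threshold_pct,q_pct,alpha
#'   Decision thresholds carried into the report.
#' @param simulate Use [simulate_calibration()] / [simulate_validation()]
#'   (default when no paths are given).
#' @param sim_config A [validation_sim_config()] (defaults emulate the
#'   three-series, seven-level captopril design); its `seed` is replaced by
#'   `seed` when that is supplied.
#' @param calibration_path,validation_path CSV paths, see
#'   [read_calibration_csv()].
#' @param seed Optional integer overriding the simulator seed.
#' @param allow_degenerate Tolerate zero-variance levels (idealised
#'   noise-free data) instead of raising a degenerate-data error; see
#'   [level_statistics()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = validation_design(),
                       label_dose_mg = 50,
                       medium_volume_ml = 900,
                       candidates = c("ols_linear", "single_point_origin"),
                       compare_models = TRUE,
                       robustness_threshold_pct = 5,
                       placebo_threshold_pct = 2,
                       q_pct = 80,
                       alpha = 0.05,
                       simulate = is.null(calibration_path),
                       sim_config = NULL,
                       calibration_path = NULL,
                       validation_path = NULL,
                       seed = NULL,
                       allow_degenerate = FALSE) {
  stopifnot(inherits(design, "validation_design"))
  check_number(label_dose_mg, "label_dose_mg", lower = 1e-12)
  check_number(medium_volume_ml, "medium_volume_ml", lower = 1e-12)
  if (simulate) {
    sim_config <- sim_config %||% validation_sim_config(
      nominal_concentration = label_dose_mg * 1000 / medium_volume_ml,
      p_series = design$p, n_replicates = design$n)
    stopifnot(inherits(sim_config, "validation_sim_config"))
    if (!is.null(seed)) sim_config$seed <- check_count(seed, "seed", lower = 0L)
  } else if (is.null(calibration_path) || is.null(validation_path)) {
    stop_design("non-simulated runs need `calibration_path` and `validation_path`")
  }
  structure(
    list(design = design, label_dose_mg = label_dose_mg,
         medium_volume_ml = medium_volume_ml, candidates = candidates,
         compare_models = isTRUE(compare_models),
         thresholds = list(robustness_pct = robustness_threshold_pct,
                           placebo_pct = placebo_threshold_pct,
                           q_pct = q_pct, alpha = alpha),
         simulate = isTRUE(simulate), sim_config = sim_config,
         calibration_path = calibration_path,
         validation_path = validation_path,
         allow_degenerate = isTRUE(allow_degenerate)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `design` and
#' `sim_config` are nested maps passed to [validation_design()] and
#' [validation_sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:`/`y:` key as a boolean; map it back
  fix_keys <- function(lst) {
    names(lst)[names(lst) == "FALSE"] <- "n"
    names(lst)[names(lst) == "TRUE"] <- "y"
    lst
  }
  design <- do.call(validation_design, fix_keys(y$design %||% list()))
  sim_config <- if (!is.null(y$sim_config)) {
    do.call(validation_sim_config, y$sim_config)
  }
  args <- y[setdiff(names(y), c("design", "sim_config"))]
  do.call(run_config, c(list(design = design, sim_config = sim_config), args))
}

#' Run the validation pipeline
#'
#' Executes the stages in order: obtain calibration and validation standards
#' (simulated or read from CSV), fit the candidate response functions per
#' series, back-calculate the validation standards through the selected
#' model's same-series fits, compute per-level statistics and
#' beta-expectation intervals, assemble the accuracy and linearity profiles,
#' and derive the LOD from the pooled calibration fit. Deterministic for a
#' given config (the simulator seed is part of the config).
#'
#' @param config A [run_config()].
#' @return An object of class `validation_report`: a list with the per-level
#'   statistics, profile decisions, LOD/LLOQ/ULOQ, the model comparison (if
#'   run), the fitted response functions and provenance (config hash,
#'   package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design

  if (config$simulate) {
    calibration <- simulate_calibration(config$sim_config)
    validation <- simulate_validation(config$sim_config)
  } else {
    calibration <- read_calibration_csv(config$calibration_path)
    validation <- read_validation_csv(config$validation_path)
  }

  comparison <- NULL
  if (config$compare_models && length(config$candidates) > 1L) {
    comparison <- compare_response_models(
      calibration, validation, design, candidates = config$candidates,
      allow_degenerate = config$allow_degenerate)
    model_kind <- comparison$selected
    if (is.na(model_kind)) model_kind <- config$candidates[[1L]]
  } else {
    model_kind <- config$candidates[[1L]]
  }

  fits <- calibration |>
    dplyr::group_by(.data$series) |>
    dplyr::group_map(function(d, key) {
      fit_response(d, model_kind, series_id = key$series)
    })
  names(fits) <- purrr::map_chr(fits, "series_id")

  back <- validation |>
    dplyr::group_by(.data$series) |>
    dplyr::group_modify(function(d, key) {
      fn <- fits[[as.character(key$series)]]
      if (is.null(fn)) {
        stop_data(sprintf("no calibration series matching validation series %s",
                          key$series))
      }
      dplyr::mutate(d, concentration = back_calculate(fn, .data$response))
    }) |>
    dplyr::ungroup()

  pooled <- fit_response(calibration, "ols_linear", series_id = "pooled")
  nominal <- config$label_dose_mg * 1000 / config$medium_volume_ml
  lod <- lod_from_regression(pooled, nominal_concentration = nominal)

  profile <- accuracy_profile(back, design, lod_conc = lod$lod_conc,
                              allow_degenerate = config$allow_degenerate)
  linearity <- linearity_profile(back, design, profile = profile)

  structure(
    list(
      design = design,
      thresholds = config$thresholds,
      calibration_fits = fits,
      pooled_fit = pooled,
      model_comparison = comparison,
      selected_model = model_kind,
      back_calculated = back,
      level_statistics = profile$levels,
      profile = profile,
      linearity = linearity,
      lod = lod,
      provenance = list(
        config_hash = rlang::hash(config),
        seed = if (config$simulate) config$sim_config$seed,
        package_version = as.character(utils::packageVersion("accuprofile")),
        report_schema = "1.0"
      )
    ),
    class = "validation_report"
  )
}

round_df <- function(df, pct_cols, conc_cols) {
  for (col in intersect(pct_cols, names(df))) df[[col]] <- round(df[[col]], 1)
  for (col in intersect(conc_cols, names(df))) df[[col]] <- round(df[[col]], 2)
  df
}

#' Serialise a validation report to JSON
#'
#' Percent statistics are rounded to one decimal and concentrations to two
#' (the usual table conventions); full-precision values stay available in
#' the report object itself. The JSON carries the schema version and config
#' hash for audit.
#'
#' @param report A `validation_report` from [run_pipeline()].
#' @param path Output path; the JSON is also returned invisibly as a string.
#' @return The JSON string, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  levels <- round_df(
    report$level_statistics,
    pct_cols = c("bias_pct", "s_r_pct", "s_R_pct", "eti_low_pct",
                 "eti_high_pct"),
    conc_cols = c("mu_t", "mu_hat")
  )
  payload <- list(
    schema = report$provenance$report_schema,
    design = unclass(report$design),
    thresholds = report$thresholds,
    selected_model = report$selected_model,
    calibration = purrr::map(report$calibration_fits,
                             ~ unclass(glance(.x))),
    model_comparison = if (!is.null(report$model_comparison)) {
      report$model_comparison$results
    },
    levels = levels,
    profile = list(valid = report$profile$valid,
                   lloq_pct = report$profile$lloq_pct,
                   uloq_pct = report$profile$uloq_pct,
                   lloq_conc = round(report$profile$lloq_conc, 2),
                   uloq_conc = round(report$profile$uloq_conc, 2)),
    linearity = list(slope = report$linearity$slope,
                     intercept = report$linearity$intercept,
                     r_squared = report$linearity$r_squared,
                     valid = report$linearity$valid),
    lod = list(lod_conc = round(report$lod$lod_conc, 2),
               lod_pct = round(report$lod$lod_pct, 1)),
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(as.character(json))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  selected model: %s\n", x$selected_model))
  print(x$profile)
  cat(sprintf("  LOD: %.3g ug/mL (%.2g%% of nominal)\n",
              x$lod$lod_conc, x$lod$lod_pct))
  invisible(x)
}
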