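#' Zone-fluidics analytical sequences
#'
#' A `zf_sequence` is the ordered list of instrument steps one analytical
#' cycle executes on a zone-fluidics manifold: valve selections (pump off),
#' aspirations of reagent/sample zones into the holding coil, and the final
#' delivery of the stacked zones through the reaction coil to the detector.
#' Volumes follow from the pump programme, `volume = flow * duration *
#' 1000/60` uL; stated step volumes are audited against that arithmetic
#' within `volume_tol_ul` (0.5 uL by default, absorbing table rounding).
#'
#' @param steps A data frame with columns `step` (consecutive indices from
#'   1), `duration_s` (> 0), `valve_position`, `action` (`"off"`,
#'   `"aspirate"` or `"deliver"`), `flow_rate_ml_min` and `volume_ul` (both
#'   `NA` for `"off"` steps), and optionally `description`.
#' @param port_map Optional named character vector mapping valve positions
#'   to reagent names, e.g. `c("2" = "Ni(II)")`.
#' @param volume_tol_ul Tolerance for the stated-vs-computed volume check.
#' @return An object of class `zf_sequence`.
#' @seealso [captopril_zf_sequence()], [cycle_time()], [sampling_throughput()],
#'   [reagent_consumption()], [audit_step_volumes()]
#' @export
zf_sequence <- function(steps, port_map = NULL, volume_tol_ul = 0.5) {
  check_columns(steps, c("step", "duration_s", "valve_position", "action",
                         "flow_rate_ml_min", "volume_ul"), "`steps`")
  steps <- tibble::as_tibble(steps)
  if (nrow(steps) == 0L) stop_design("a sequence must have at least one step")
  if (!identical(as.integer(steps$step), seq_len(nrow(steps)))) {
    stop_design("`step` indices must be consecutive from 1")
  }
  if (any(!steps$action %in% c("off", "aspirate", "deliver"))) {
    stop_design("`action` must be one of off/aspirate/deliver")
  }
  if (any(steps$duration_s <= 0)) stop_design("step durations must be positive")
  moving <- steps$action != "off"
  if (any(is.na(steps$flow_rate_ml_min[moving])) ||
      any(is.na(steps$volume_ul[moving]))) {
    stop_design("aspirate/deliver steps need a flow rate and a volume")
  }
  dev <- abs(steps$volume_ul[moving] -
               step_volume(steps$flow_rate_ml_min[moving],
                           steps$duration_s[moving]))
  if (any(dev > volume_tol_ul)) {
    bad <- steps$step[moving][dev > volume_tol_ul]
    stop_design(sprintf(
      "stated volume inconsistent with flow * duration at step(s) %s",
      paste(bad, collapse = ", ")))
  }
  if (!"description" %in% names(steps)) steps$description <- NA_character_
  structure(list(steps = steps, port_map = port_map,
                 volume_tol_ul = volume_tol_ul),
            class = "zf_sequence")
}

#' The captopril determination sequence
#'
#' The eight-step cycle for the automated captopril assay: sequential
#' aspiration of 50 uL Ni(II) reagent, 100 uL dissolution sample and 50 uL
#' aqueous ammonia into the holding coil, then flow reversal delivering the
#' stacked zones through the reaction coil to the UV-Vis detector at
#' 0.9 mL/min for 120 s.
#'
#' @return A [zf_sequence()] with a port-to-reagent map.
#' @export
captopril_zf_sequence <- function() {
  steps <- tibble::tibble(
    step = 1:8,
    duration_s = c(1, 5, 1, 10, 1, 5, 1, 120),
    valve_position = c(2L, 2L, 1L, 1L, 3L, 3L, 4L, 4L),
    action = c("off", "aspirate", "off", "aspirate", "off", "aspirate",
               "off", "deliver"),
    flow_rate_ml_min = c(NA, 0.6, NA, 0.6, NA, 0.6, NA, 0.9),
    volume_ul = c(NA, 50, NA, 100, NA, 50, NA, 1800),
    description = c(
      "Selection of Ni(II) solution port",
      "Aspiration of Ni(II) solution in the HC",
      "Selection of sample port",
      "Aspiration of sample in the HC",
      "Selection of aqueous NH3 solution port",
      "Aspiration of aqueous NH3 solution in the HC",
      "Selection of UV-Vis detector port",
      "Deliver of the reaction mixture to the UV-Vis detector"
    )
  )
  zf_sequence(steps, port_map = c("1" = "sample", "2" = "Ni(II)",
                                  "3" = "NH3", "4" = "detector"))
}

#' Cycle time of a sequence
#'
#' @param seq A [zf_sequence()].
#' @return Total duration of one analytical cycle, seconds.
#' @export
cycle_time <- function(seq) {
  stopifnot(inherits(seq, "zf_sequence"))
  sum(seq$steps$duration_s)
}

#' Sampling throughput of a sequence
#'
#' @param seq A [zf_sequence()].
#' @param round_down Report the integer number of full cycles per hour
#'   (default; pass `FALSE` for the exact rate `3600 / cycle_time`).
#' @return Samples per hour.
#' @export
sampling_throughput <- function(seq, round_down = TRUE) {
  ct <- cycle_time(seq)
  if (ct <= 0) stop_design("cycle time must be positive")
  rate <- 3600 / ct
  if (round_down) floor(rate) else rate
}

#' Volume moved by a pump step
#'
#' @param flow_rate_ml_min Pump flow rate, mL/min (non-negative).
#' @param duration_s Step duration, seconds (non-negative).
#' @return Volume in uL, `flow * duration * 1000 / 60`.
#' @export
step_volume <- function(flow_rate_ml_min, duration_s) {
  if (any(flow_rate_ml_min < 0, na.rm = TRUE) ||
      any(duration_s < 0, na.rm = TRUE)) {
    stop_design("flow rate and duration must be non-negative")
  }
  flow_rate_ml_min * duration_s * 1000 / 60
}

#' Reagent consumption per cycle
#'
#' Sums aspirated volumes per valve port (named through the sequence's port
#' map; unmapped ports are bucketed as `"unknown"` with a warning) and
#' reports the delivered volume separately.
#'
#' @param seq A [zf_sequence()].
#' @return A tibble with columns `port`, `reagent`, `action` and
#'   `volume_ul`; aspirations first, then one `deliver` row (0 uL when the
#'   sequence never delivers).
#' @export
reagent_consumption <- function(seq) {
  stopifnot(inherits(seq, "zf_sequence"))
  steps <- seq$steps
  asp <- dplyr::filter(steps, .data$action == "aspirate")
  map_port <- function(port) {
    key <- as.character(port)
    if (!is.null(seq$port_map) && key %in% names(seq$port_map)) {
      seq$port_map[[key]]
    } else {
      warn(sprintf("valve position %s has no reagent mapping", key))
      "unknown"
    }
  }
  aspirated <- asp |>
    dplyr::summarise(volume_ul = sum(.data$volume_ul),
                     .by = "valve_position") |>
    dplyr::mutate(port = as.character(.data$valve_position),
                  reagent = purrr::map_chr(.data$valve_position, map_port),
                  action = "aspirate") |>
    dplyr::select("port", "reagent", "action", "volume_ul")
  delivered <- tibble::tibble(
    port = NA_character_, reagent = "delivered", action = "deliver",
    volume_ul = sum(steps$volume_ul[steps$action == "deliver"], 0,
                    na.rm = TRUE)
  )
  dplyr::bind_rows(aspirated, delivered)
}

#' Audit stated step volumes against the pump arithmetic
#'
#' @param seq A [zf_sequence()].
#' @param tol_ul Tolerance in uL (defaults to the sequence's own tolerance).
#' @return A tibble with one row per pumping step: stated and computed
#'   volume, absolute deviation and a `pass` flag.
#' @export
audit_step_volumes <- function(seq, tol_ul = NULL) {
  stopifnot(inherits(seq, "zf_sequence"))
  tol_ul <- tol_ul %||% seq$volume_tol_ul
  seq$steps |>
    dplyr::filter(.data$action != "off") |>
    dplyr::mutate(
      computed_ul = step_volume(.data$flow_rate_ml_min, .data$duration_s),
      deviation_ul = abs(.data$volume_ul - .data$computed_ul),
      pass = .data$deviation_ul <= tol_ul
    ) |>
    dplyr::select("step", "action", "flow_rate_ml_min", "duration_s",
                  "volume_ul", "computed_ul", "deviation_ul", "pass")
}

#' @export
print.zf_sequence <- function(x, ...) {
  cat(sprintf("<zf_sequence: %d steps, cycle %g s, throughput %d /h>\n",
              nrow(x$steps), cycle_time(x), sampling_throughput(x)))
  print(x$steps)
  invisible(x)
}
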