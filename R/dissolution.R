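#' Convert a sampled concentration to percent of label claim released
#'
#' `release = 100 * C * V / (dose * 1000)`: the drug mass in the vessel at
#' concentration `C` (ug/mL) in `V` mL, as a percentage of the label dose in
#' mg.
#'
#' @param concentration Concentration(s) in the medium, ug/mL.
#' @param medium_volume_ml Medium volume, mL (default 900).
#' @param label_dose_mg Label claim, mg (default 50).
#' @return Percent of label claim released.
#' @examples
#' percent_release(55.56) # 100.0 for a 50 mg tablet in 900 mL
#' @export
percent_release <- function(concentration, medium_volume_ml = 900,
                            label_dose_mg = 50) {
  check_number(medium_volume_ml, "medium_volume_ml", lower = 1e-12)
  check_number(label_dose_mg, "label_dose_mg", lower = 1e-12)
  100 * concentration * medium_volume_ml / (label_dose_mg * 1000)
}

#' @rdname percent_release
#' @param data A data frame with a `concentration` column; a `release_pct`
#'   column is appended.
#' @export
add_percent_release <- function(data, medium_volume_ml = 900,
                                label_dose_mg = 50) {
  check_columns(data, "concentration", "`data`")
  dplyr::mutate(data,
                release_pct = percent_release(.data$concentration,
                                              medium_volume_ml,
                                              label_dose_mg))
}

#' Stage-1 Q-criterion check of a dissolution profile
#'
#' USP stage-S1 rule at the monograph Q value: every tested unit must have
#' released at least `Q + 5` percent of the label claim at the checkpoint
#' time. Later stages (S2/S3, testing further units against Q and Q - 15)
#' are out of scope.
#'
#' @param profile A data frame with columns `unit`, `time_min` and
#'   `release_pct`.
#' @param t_check Checkpoint time, minutes (must be a sampled time point).
#' @param q_pct The monograph Q value, % (default 80).
#' @return An object of class `q_check` with per-unit results (`$per_unit`),
#'   a one-row summary (`$summary`: mean, SD, minimum, threshold) and the
#'   stage-1 flag (`$pass`).
#' @export
q_criterion_check <- function(profile, t_check = 20, q_pct = 80) {
  check_columns(profile, c("unit", "time_min", "release_pct"), "`profile`")
  check_number(q_pct, "q_pct", lower = 1e-12)
  at <- dplyr::filter(profile, .data$time_min == t_check)
  if (nrow(at) == 0L) {
    stop_data(sprintf("no samples at t = %g min", t_check))
  }
  threshold <- q_pct + 5
  per_unit <- at |>
    dplyr::select("unit", "release_pct") |>
    dplyr::mutate(pass = .data$release_pct >= threshold)
  summary <- tibble::tibble(
    t_check = t_check, q_pct = q_pct, threshold_pct = threshold,
    n_units = nrow(per_unit),
    mean_release = mean(per_unit$release_pct),
    sd_release = sd(per_unit$release_pct),
    min_release = min(per_unit$release_pct)
  )
  structure(list(per_unit = per_unit, summary = summary,
                 pass = all(per_unit$pass)),
            class = "q_check")
}

#' @export
print.q_check <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<q_check at %g min: Q = %g%%, stage-1 threshold %g%%>\n", s$t_check,
    s$q_pct, s$threshold_pct))
  cat(sprintf("  %d units, mean %.1f%% (SD %.1f), min %.1f%% -> %s\n",
              s$n_units, s$mean_release, s$sd_release, s$min_release,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Paired comparison of two analytical methods on dissolution data
#'
#' Classic paired t-test on the per-unit differences between the test and
#' reference methods, per sampling time when a `time_min` column is present.
#' The methods are declared in agreement at a time point when the two-sided
#' p-value exceeds `alpha`. Degenerate data (zero-variance differences) give
#' `p = 1` when the differences are all zero, and `p = 0` with a
#' `degenerate` flag when they are constant but non-zero.
#'
#' @param test,reference Data frames with columns `unit`, `release_pct` and
#'   optionally `time_min`; the unit sets (per time) must match.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per time point (or a single row): means of
#'   both methods, `mean_diff`, `t`, `df`, `p_value`, `agreement` and
#'   `degenerate`.
#' @export
paired_method_comparison <- function(test, reference, alpha = 0.05) {
  check_columns(test, c("unit", "release_pct"), "`test`")
  check_columns(reference, c("unit", "release_pct"), "`reference`")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  has_time <- "time_min" %in% names(test) && "time_min" %in% names(reference)
  if (!has_time) {
    test$time_min <- NA_real_
    reference$time_min <- NA_real_
  }
  joined <- dplyr::inner_join(
    dplyr::select(test, "unit", "time_min", test = "release_pct"),
    dplyr::select(reference, "unit", "time_min", reference = "release_pct"),
    by = c("unit", "time_min")
  )
  if (nrow(joined) != nrow(test) || nrow(joined) != nrow(reference)) {
    stop_data("unit/time sets of the two methods do not match")
  }
  out <- joined |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_test = mean(.data$test),
      mean_reference = mean(.data$reference),
      mean_diff = mean(.data$test - .data$reference),
      sd_diff = sd(.data$test - .data$reference),
      .by = "time_min"
    )
  if (any(out$n < 2L)) stop_data("paired comparison needs at least 2 units")
  stats <- purrr::pmap_dfr(
    list(out$mean_diff, out$sd_diff, out$n),
    function(md, s, n) {
      if (s == 0) {
        if (md == 0) {
          tibble::tibble(t = 0, df = n - 1, p_value = 1, degenerate = FALSE)
        } else {
          tibble::tibble(t = Inf * sign(md), df = n - 1, p_value = 0,
                         degenerate = TRUE)
        }
      } else {
        tstat <- md / (s / sqrt(n))
        tibble::tibble(t = tstat, df = n - 1,
                       p_value = 2 * pt(-abs(tstat), df = n - 1),
                       degenerate = FALSE)
      }
    }
  )
  res <- dplyr::bind_cols(out, stats) |>
    dplyr::mutate(agreement = .data$p_value > alpha)
  if (!has_time) res$time_min <- NULL
  res
}

#' Table-style summary of a paired dissolution experiment
#'
#' Mean (+/- SD) percent release per time point for each method plus the
#' paired-test p-value — the usual layout of a method-comparison dissolution
#' table.
#'
#' @param data A tibble with columns `method` (`"test"` / `"reference"`),
#'   `unit`, `time_min`, `release_pct` (e.g. from
#'   [simulate_dissolution_pair()]).
#' @param alpha Significance level for the agreement flag.
#' @return A tibble with one row per time point.
#' @export
dissolution_summary <- function(data, alpha = 0.05) {
  check_columns(data, c("method", "unit", "time_min", "release_pct"),
                "`data`")
  test <- dplyr::filter(data, .data$method == "test")
  reference <- dplyr::filter(data, .data$method == "reference")
  cmp <- paired_method_comparison(test, reference, alpha = alpha)
  sds <- data |>
    dplyr::summarise(sd = sd(.data$release_pct),
                     .by = c("method", "time_min")) |>
    tidyr::pivot_wider(names_from = "method", values_from = "sd",
                       names_prefix = "sd_")
  dplyr::left_join(cmp, sds, by = "time_min") |>
    dplyr::select("time_min", "mean_test", "sd_test", "mean_reference",
                  "sd_reference", "t", "df", "p_value", "agreement")
}

#' Plot dissolution profiles by method
#'
#' Mean percent release versus time with +/- SD error bars per method.
#'
#' @param data A tibble with columns `method`, `unit`, `time_min`,
#'   `release_pct`.
#' @return A ggplot.
#' @export
plot_dissolution <- function(data) {
  check_columns(data, c("method", "unit", "time_min", "release_pct"),
                "`data`")
  means <- data |>
    dplyr::summarise(mean = mean(.data$release_pct),
                     sd = sd(.data$release_pct),
                     .by = c("method", "time_min"))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$time_min, y = .data$mean,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 1) +
    ggplot2::labs(x = "Time (min)", y = "Release (% of label claim)",
                  title = "Dissolution profiles")
}
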