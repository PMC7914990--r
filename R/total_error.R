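#' Validation design
#'
#' The experimental frame every total-error statistic is conditioned on: `p`
#' series (days) of `n` independent replicates at each of `m` concentration
#' levels, an acceptance limit of `+/- lambda_pct` percent on the relative
#' error, and a tolerance proportion `beta` (the fraction of future results
#' the tolerance interval is expected to contain).
#'
#' @param p Number of series, at least 2.
#' @param n Replicates per series, at least 2.
#' @param m Number of concentration levels, at least 3.
#' @param lambda_pct Acceptance limit on relative error, % (default 10, the
#'   usual choice for dissolution assays of finished products).
#' @param beta Tolerance proportion in (0, 1), default 0.95.
#' @param rsd_reference Whether RSDs are normalised by the estimated mean
#'   `mu_hat` (default, the conventional definition) or by the true value
#'   `mu_t`.
#' @return An object of class `validation_design`.
#' @export
validation_design <- function(p = 3, n = 3, m = 7, lambda_pct = 10,
                              beta = 0.95,
                              rsd_reference = c("mu_hat", "mu_t")) {
  p <- check_count(p, "p", lower = 2L)
  n <- check_count(n, "n", lower = 2L)
  m <- check_count(m, "m", lower = 3L)
  check_number(lambda_pct, "lambda_pct", lower = 1e-12)
  check_number(beta, "beta")
  if (beta <= 0 || beta >= 1) stop_design("`beta` must lie strictly in (0, 1)")
  rsd_reference <- match.arg(rsd_reference)
  structure(list(p = p, n = n, m = m, lambda_pct = lambda_pct, beta = beta,
                 rsd_reference = rsd_reference),
            class = "validation_design")
}

#' Per-level trueness and precision from a balanced series design
#'
#' One-way random-effects ANOVA of the back-calculated concentrations of one
#' level: the within-series variance is the within mean square, the
#' between-series component is `(MSB - MSW) / n` truncated at zero. Relative
#' bias is `100 * (mu_hat - mu_t) / mu_t`; the repeatability RSD uses the
#' within component alone and the intermediate-precision RSD the sum of both
#' components. The Satterthwaite degrees of freedom for the total variance
#' are attached for the tolerance-interval step ([beta_eti()]).
#'
#' @param data A data frame with columns `series` and `concentration`
#'   (back-calculated), balanced: every series with exactly `design$n`
#'   replicates and `design$p` series present.
#' @param mu_t True (introduced) concentration of the level, positive.
#' @param design A [validation_design()].
#' @param allow_degenerate If `TRUE`, data with zero variance everywhere
#'   yield zero RSDs and an infinite-dof level instead of an error (used by
#'   [compare_response_models()] on idealised data); by default zero
#'   within-series variance is a degenerate-data error.
#' @return A one-row tibble with `mu_t`, `mu_hat`, `bias_pct`, the mean
#'   squares, variance components, variance ratio `var_ratio`, `b2`,
#'   `s_r_pct`, `s_R_pct` and `nu`.
#' @export
level_statistics <- function(data, mu_t, design, allow_degenerate = FALSE) {
  stopifnot(inherits(design, "validation_design"))
  check_columns(data, c("series", "concentration"), "`data`")
  check_number(mu_t, "mu_t", lower = 1e-12)
  if (any(is.na(data$concentration))) stop_data("missing back-calculated values")
  counts <- table(data$series)
  if (length(counts) != design$p || any(counts != design$n)) {
    stop_design(sprintf(
      "unbalanced design: need %d series x %d replicates, got series sizes [%s]",
      design$p, design$n, paste(counts, collapse = ", ")))
  }
  p <- design$p
  n <- design$n

  by_series <- data |>
    dplyr::summarise(mean = mean(.data$concentration),
                     ss = sum((.data$concentration - mean(.data$concentration))^2),
                     .by = "series")
  mu_hat <- mean(data$concentration)
  ms_within <- sum(by_series$ss) / (p * (n - 1))
  ms_between <- n * sum((by_series$mean - mu_hat)^2) / (p - 1)

  degenerate <- ms_within <= 0
  if (degenerate && !(allow_degenerate && ms_between <= 0)) {
    stop_data("degenerate data: zero within-series variance")
  }

  sigma2_b <- max(0, (ms_between - ms_within) / n)
  if (degenerate) {
    var_ratio <- 0
    nu <- Inf
  } else {
    var_ratio <- sigma2_b / ms_within
    nu <- satterthwaite_dof(var_ratio, p, n)
  }
  b2 <- (var_ratio + 1) / (n * var_ratio + 1)
  ref <- if (design$rsd_reference == "mu_hat") mu_hat else mu_t

  tibble::tibble(
    mu_t = mu_t,
    mu_hat = mu_hat,
    bias_pct = 100 * (mu_hat - mu_t) / mu_t,
    ms_within = ms_within,
    ms_between = ms_between,
    sigma2_w = ms_within,
    sigma2_b = sigma2_b,
    var_ratio = var_ratio,
    b2 = b2,
    s_r_pct = 100 * sqrt(ms_within) / ref,
    s_R_pct = 100 * sqrt(ms_within + sigma2_b) / ref,
    nu = nu
  )
}

#' Satterthwaite degrees of freedom for the total variance
#'
#' Effective degrees of freedom of `sigma2_B + sigma2_W` estimated from a
#' balanced one-way random-effects ANOVA. `satterthwaite_dof()` takes the
#' variance ratio `R = sigma2_B / sigma2_W`:
#' `nu = (R + 1)^2 / ((R + 1/n)^2 / (p - 1) + (1 - 1/n) / (p * n))`.
#' `satterthwaite_dof_ms()` is the algebraically equivalent mean-squares
#' form, `nu = (a + b)^2 / (a^2/(p-1) + b^2/(p(n-1)))` with `a = MSB/n` and
#' `b = (1 - 1/n) MSW`; the two must agree and are cross-checked in the test
#' suite.
#'
#' @param r_ratio Variance ratio `sigma2_B / sigma2_W`, non-negative.
#' @param p,n Series count and replicates per series.
#' @return Degrees of freedom (positive real, not necessarily integer).
#' @export
satterthwaite_dof <- function(r_ratio, p, n) {
  p <- check_count(p, "p", lower = 2L)
  n <- check_count(n, "n", lower = 2L)
  if (any(r_ratio < 0)) stop_design("`r_ratio` must be non-negative")
  (r_ratio + 1)^2 /
    ((r_ratio + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
}

#' @rdname satterthwaite_dof
#' @param ms_between,ms_within Between- and within-series mean squares.
#' @export
satterthwaite_dof_ms <- function(ms_between, ms_within, p, n) {
  p <- check_count(p, "p", lower = 2L)
  n <- check_count(n, "n", lower = 2L)
  a <- ms_between / n
  b <- (1 - 1 / n) * ms_within
  (a + b)^2 / (a^2 / (p - 1) + b^2 / (p * (n - 1)))
}

#' Coverage factor of the beta-expectation tolerance interval
#'
#' `k = Q_t(nu, (1 + beta)/2) * sqrt(1 + 1/(p * n * B^2))`, where `Q_t` is
#' the Student-t quantile and `B^2 = (R + 1) / (n R + 1)` accounts for the
#' balance between variance components.
#'
#' @param nu Degrees of freedom, positive (non-integer allowed; `Inf` gives
#'   the normal limit).
#' @param beta Tolerance proportion in (0, 1).
#' @param p,n Design counts.
#' @param b2 The factor `B^2`, in (0, 1].
#' @return The coverage factor `k`.
#' @export
tolerance_factor <- function(nu, beta, p, n, b2) {
  if (any(nu <= 0)) stop_design("`nu` must be positive")
  if (beta <= 0 || beta >= 1) stop_design("`beta` must lie in (0, 1)")
  if (any(b2 <= 0 | b2 > 1)) stop_design("`b2` must lie in (0, 1]")
  qt((1 + beta) / 2, df = nu) * sqrt(1 + 1 / (p * n * b2))
}

#' Complete per-level statistics with the beta-expectation interval
#'
#' Attaches the coverage factor and the relative beta-expectation tolerance
#' interval `bias_pct -/+ k * s_R_pct` (the interval expected to contain a
#' proportion `beta` of future individual results, on the relative-error
#' scale) to the output of [level_statistics()]. The multiplier of the
#' coverage factor is the intermediate-precision RSD (within + between
#' components).
#'
#' @param stats A (possibly multi-row) tibble from [level_statistics()].
#' @param design A [validation_design()].
#' @return `stats` with `k_tol`, `eti_low_pct` and `eti_high_pct` appended.
#' @export
beta_eti <- function(stats, design) {
  stopifnot(inherits(design, "validation_design"))
  check_columns(stats, c("bias_pct", "s_R_pct", "nu", "b2"), "`stats`")
  dplyr::mutate(
    stats,
    k_tol = tolerance_factor(.data$nu, design$beta, design$p, design$n,
                             .data$b2),
    eti_low_pct = .data$bias_pct - .data$k_tol * .data$s_R_pct,
    eti_high_pct = .data$bias_pct + .data$k_tol * .data$s_R_pct
  )
}

# Per-level validity and the LLOQ/ULOQ decision shared by profiles built
# from data and from printed intervals. `levels` must be ordered by
# level_pct and carry eti_low_pct / eti_high_pct.
profile_decision <- function(levels, lambda_pct) {
  levels <- dplyr::arrange(levels, .data$level_pct)
  levels$level_valid <- levels$eti_low_pct > -lambda_pct &
    levels$eti_high_pct < lambda_pct

  interp <- function(l0, l1, bound0, bound1, limit) {
    l0 + (bound0 - limit) / (bound0 - bound1) * (l1 - l0)
  }
  crossing_between <- function(bad, good, lower_side) {
    # level at which the violating bound re-enters the acceptance band,
    # linear in level % on that bound; worst (innermost) crossing governs
    xs <- numeric(0)
    if (bad$eti_low_pct <= -lambda_pct) {
      xs <- c(xs, interp(bad$level_pct, good$level_pct,
                         bad$eti_low_pct, good$eti_low_pct, -lambda_pct))
    }
    if (bad$eti_high_pct >= lambda_pct) {
      xs <- c(xs, interp(bad$level_pct, good$level_pct,
                         bad$eti_high_pct, good$eti_high_pct, lambda_pct))
    }
    if (lower_side) max(xs) else min(xs)
  }

  if (!any(levels$level_valid)) {
    return(list(levels = levels, lloq_pct = NA_real_, uloq_pct = NA_real_,
                valid = FALSE))
  }
  first_ok <- which(levels$level_valid)[1L]
  last_ok <- rev(which(levels$level_valid))[1L]
  lloq <- if (first_ok == 1L) {
    levels$level_pct[1L]
  } else {
    crossing_between(levels[first_ok - 1L, ], levels[first_ok, ],
                     lower_side = TRUE)
  }
  uloq <- if (last_ok == nrow(levels)) {
    levels$level_pct[nrow(levels)]
  } else {
    crossing_between(levels[last_ok + 1L, ], levels[last_ok, ],
                     lower_side = FALSE)
  }
  list(levels = levels, lloq_pct = lloq, uloq_pct = uloq,
       valid = all(levels$level_valid))
}

new_accuracy_profile <- function(levels, design, lloq_pct, uloq_pct, valid,
                                 nominal_concentration = NA_real_,
                                 lod_conc = NA_real_) {
  structure(
    list(design = design, levels = levels,
         lloq_pct = lloq_pct, uloq_pct = uloq_pct,
         lloq_conc = lloq_pct / 100 * nominal_concentration,
         uloq_conc = uloq_pct / 100 * nominal_concentration,
         nominal_concentration = nominal_concentration,
         lod_conc = lod_conc, valid = valid),
    class = "accuracy_profile"
  )
}

#' Build an accuracy profile from back-calculated validation data
#'
#' Runs [level_statistics()] and [beta_eti()] on every concentration level,
#' checks each relative tolerance interval against the acceptance band
#' `(-lambda, +lambda)`, and locates the lower and upper limits of
#' quantification. The LLOQ is the lowest level whose interval lies inside
#' the band, or, when lower levels fail, the linear interpolation (in level
#' %) of the violating bound's crossing with the acceptance limit between
#' the last failing and first passing level; the ULOQ is symmetric from the
#' top. The method is declared valid when every level passes.
#'
#' @param data A data frame with columns `series`, `level_pct`,
#'   `true_concentration` and `concentration` (back-calculated), balanced
#'   per level as required by `design`.
#' @param design A [validation_design()].
#' @param lod_conc Optional limit of detection (ug/mL) to carry in the
#'   profile (see [lod_from_regression()]).
#' @param allow_degenerate Passed to [level_statistics()].
#' @return An object of class `accuracy_profile`; see [tidy.accuracy_profile()],
#'   [glance.accuracy_profile()] and [autoplot.accuracy_profile()].
#' @export
accuracy_profile <- function(data, design, lod_conc = NA_real_,
                             allow_degenerate = FALSE) {
  stopifnot(inherits(design, "validation_design"))
  check_columns(data, c("series", "level_pct", "true_concentration",
                        "concentration"), "`data`")
  lv <- sort(unique(data$level_pct))
  if (length(lv) != design$m) {
    stop_design(sprintf("data has %d levels but the design states m = %d",
                        length(lv), design$m))
  }
  levels <- purrr::map_dfr(lv, function(l) {
    d <- dplyr::filter(data, .data$level_pct == l)
    mu_t <- unique(d$true_concentration)
    if (length(mu_t) != 1L) {
      stop_data(sprintf("level %g%% has more than one true concentration", l))
    }
    st <- level_statistics(d, mu_t, design, allow_degenerate = allow_degenerate)
    dplyr::bind_cols(tibble::tibble(level_pct = l), st)
  })
  levels <- beta_eti(levels, design)
  dec <- profile_decision(levels, design$lambda_pct)
  nominal <- mean(100 * levels$mu_t / levels$level_pct)
  new_accuracy_profile(dec$levels, design, dec$lloq_pct, dec$uloq_pct,
                       dec$valid, nominal_concentration = nominal,
                       lod_conc = lod_conc)
}

#' Build an accuracy profile from pre-computed relative intervals
#'
#' Applies the acceptance-band decision and LLOQ/ULOQ location to intervals
#' that were computed elsewhere (for example a published validation table),
#' using the same decision code path as [accuracy_profile()].
#'
#' @param intervals A data frame with columns `level_pct`, `eti_low_pct`,
#'   `eti_high_pct` and optionally `bias_pct`.
#' @param design A [validation_design()].
#' @return An `accuracy_profile` whose per-level ANOVA columns are absent.
#' @export
profile_from_intervals <- function(intervals, design) {
  stopifnot(inherits(design, "validation_design"))
  check_columns(intervals, c("level_pct", "eti_low_pct", "eti_high_pct"),
                "`intervals`")
  intervals <- tibble::as_tibble(intervals)
  if (!"bias_pct" %in% names(intervals)) {
    intervals$bias_pct <- (intervals$eti_low_pct + intervals$eti_high_pct) / 2
  }
  dec <- profile_decision(intervals, design$lambda_pct)
  new_accuracy_profile(dec$levels, design, dec$lloq_pct, dec$uloq_pct,
                       dec$valid)
}

#' Linearity profile of back-calculated versus introduced concentrations
#'
#' Fits an unweighted least-squares line of the back-calculated on the
#' introduced concentrations over all levels and converts the relative
#' tolerance intervals into absolute concentration limits
#' `mu_t * (1 + eti/100)`, compared to the absolute acceptance limits
#' `mu_t * (1 +/- lambda/100)`. The method is linear over the range when
#' every absolute tolerance limit lies inside the acceptance limits.
#'
#' @inheritParams accuracy_profile
#' @param profile Optional pre-computed [accuracy_profile()] for the same
#'   data (recomputed when omitted).
#' @return An object of class `linearity_profile` with the fit coefficients,
#'   a per-level table of absolute limits, and the validity flag.
#' @export
linearity_profile <- function(data, design, profile = NULL,
                              allow_degenerate = FALSE) {
  check_columns(data, c("true_concentration", "concentration"), "`data`")
  if (is.null(profile)) {
    profile <- accuracy_profile(data, design,
                                allow_degenerate = allow_degenerate)
  }
  fit <- lm(concentration ~ true_concentration, data = data)
  sm <- quiet_lm_summary(fit)
  levels <- profile$levels |>
    dplyr::mutate(
      abs_tol_low = .data$mu_t * (1 + .data$eti_low_pct / 100),
      abs_tol_high = .data$mu_t * (1 + .data$eti_high_pct / 100),
      abs_acc_low = .data$mu_t * (1 - design$lambda_pct / 100),
      abs_acc_high = .data$mu_t * (1 + design$lambda_pct / 100),
      level_valid = .data$abs_tol_low > .data$abs_acc_low &
        .data$abs_tol_high < .data$abs_acc_high
    )
  structure(
    list(slope = unname(coef(fit)[["true_concentration"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = sm$r.squared,
         levels = levels,
         design = design,
         valid = all(levels$level_valid)),
    class = "linearity_profile"
  )
}

model_n_params <- function(kind) {
  switch(kind, single_point_origin = 1L, ols_linear = 2L,
         weighted_1_over_x = 2L, weighted_1_over_x2 = 2L)
}

#' Compare candidate calibration models by their accuracy profiles
#'
#' Fits each candidate response function to the calibration standards (one
#' fit per series, mirroring day-wise calibration), back-calculates the
#' validation standards through the same-series fit, builds the accuracy
#' profile, and ranks candidates: widest valid level range first, ties
#' broken by smaller mean interval half-width, then by fewer model
#' parameters. A candidate with no valid level is never selected over one
#' with a valid range.
#'
#' @param calibration Calibration standards: columns `series`, `level_pct`,
#'   `concentration`, `response`.
#' @param validation Validation standards: columns `series`, `level_pct`,
#'   `true_concentration`, `response`.
#' @param design A [validation_design()].
#' @param candidates Character vector of model kinds (see
#'   [response_function()]); weighted kinds are available but not default.
#' @param allow_degenerate Passed to profile construction (needed for
#'   idealised noise-free data).
#' @return An object of class `model_comparison`: a ranking tibble
#'   (`$results`), the per-candidate profiles (`$profiles`) and the selected
#'   model kind (`$selected`, `NA` when no candidate has a valid range).
#' @export
compare_response_models <- function(calibration, validation, design,
                                    candidates = c("ols_linear",
                                                   "single_point_origin"),
                                    allow_degenerate = FALSE) {
  stopifnot(inherits(design, "validation_design"))
  if (length(candidates) < 1L) stop_design("need at least one candidate")
  check_columns(calibration, c("series", "level_pct", "concentration",
                               "response"), "`calibration`")
  check_columns(validation, c("series", "level_pct", "true_concentration",
                              "response"), "`validation`")

  profiles <- lapply(candidates, function(kind) {
    back <- validation |>
      dplyr::group_by(.data$series) |>
      dplyr::group_modify(function(d, key) {
        std <- dplyr::filter(calibration, .data$series == key$series)
        fn <- fit_response(std, kind, series_id = key$series)
        dplyr::mutate(d, concentration = back_calculate(fn, .data$response))
      }) |>
      dplyr::ungroup()
    accuracy_profile(back, design, allow_degenerate = allow_degenerate)
  })
  names(profiles) <- candidates

  results <- purrr::map2_dfr(profiles, candidates, function(pr, kind) {
    tibble::tibble(
      model_kind = kind,
      n_params = model_n_params(kind),
      n_valid_levels = sum(pr$levels$level_valid),
      lloq_pct = pr$lloq_pct,
      uloq_pct = pr$uloq_pct,
      valid_range_width = ifelse(is.na(pr$lloq_pct), 0,
                                 pr$uloq_pct - pr$lloq_pct),
      mean_half_width = mean((pr$levels$eti_high_pct -
                                pr$levels$eti_low_pct) / 2),
      profile_valid = pr$valid
    )
  })
  ranked <- dplyr::arrange(results, dplyr::desc(.data$valid_range_width),
                           .data$mean_half_width, .data$n_params)
  selected <- if (any(results$n_valid_levels > 0)) {
    ranked$model_kind[1L]
  } else {
    NA_character_
  }
  results$selected <- results$model_kind == selected & !is.na(selected)
  structure(list(results = results, profiles = profiles, selected = selected),
            class = "model_comparison")
}

#' Robustness of the method to small parameter variations
#'
#' @param conditions A data frame with columns `parameter`, `value` and
#'   `mean_response`, one row per deliberately varied condition.
#' @param reference_response Mean response at the optimal conditions,
#'   positive.
#' @param threshold_pct Maximum tolerated absolute relative error, %
#'   (default 5).
#' @return `conditions` with `re_pct` (relative error vs the reference) and
#'   `pass` appended.
#' @export
robustness_assess <- function(conditions, reference_response,
                              threshold_pct = 5) {
  check_columns(conditions, c("parameter", "value", "mean_response"),
                "`conditions`")
  check_number(reference_response, "reference_response", lower = 1e-12)
  check_number(threshold_pct, "threshold_pct", lower = 1e-12)
  conditions |>
    tibble::as_tibble() |>
    dplyr::mutate(
      re_pct = 100 * (.data$mean_response - reference_response) /
        reference_response,
      pass = abs(.data$re_pct) <= threshold_pct
    )
}

#' Placebo interference relative to a 100% standard
#'
#' @param placebo_response Response of the excipient-only placebo.
#' @param standard_response Response of the standard at the nominal (100%)
#'   concentration, positive.
#' @param threshold_pct Maximum tolerated interference, % (default 2, the
#'   usual compendial recommendation).
#' @return A one-row tibble with `interference_pct` and `pass`.
#' @export
placebo_interference <- function(placebo_response, standard_response,
                                 threshold_pct = 2) {
  check_number(placebo_response, "placebo_response")
  check_number(standard_response, "standard_response", lower = 1e-12)
  interference <- 100 * placebo_response / standard_response
  tibble::tibble(interference_pct = interference,
                 pass = interference <= threshold_pct)
}
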