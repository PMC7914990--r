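#' @export
print.accuracy_profile <- function(x, ...) {
  d <- x$design
  cat(sprintf("<accuracy_profile: p = %d, n = %d, m = %d, lambda = %.3g%%, beta = %.2f>\n",
              d$p, d$n, d$m, d$lambda_pct, d$beta))
  lv <- x$levels
  for (i in seq_len(nrow(lv))) {
    cat(sprintf("  %6.4g%%  bias %6.1f%%  beta-ETI [%6.2f, %6.2f]  %s\n",
                lv$level_pct[i], lv$bias_pct[i], lv$eti_low_pct[i],
                lv$eti_high_pct[i],
                if (lv$level_valid[i]) "ok" else "OUTSIDE"))
  }
  if (is.na(x$lloq_pct)) {
    cat("  no valid level: profile invalid\n")
  } else {
    cat(sprintf("  LLOQ = %.4g%%, ULOQ = %.4g%%; method %s over the range\n",
                x$lloq_pct, x$uloq_pct,
                if (x$valid) "VALID" else "NOT valid at every level"))
  }
  invisible(x)
}

#' Tidy and summarise accuracy profiles
#'
#' `tidy()` returns the per-level statistics table (one row per
#' concentration level); `glance()` returns the one-row decision summary
#' (acceptance limit, tolerance proportion, LLOQ/ULOQ and validity).
#'
#' @param x An [accuracy_profile()].
#' @param ... Unused.
#' @export
tidy.accuracy_profile <- function(x, ...) {
  x$levels
}

#' @rdname tidy.accuracy_profile
#' @export
glance.accuracy_profile <- function(x, ...) {
  tibble::tibble(
    p = x$design$p, n = x$design$n, m = x$design$m,
    lambda_pct = x$design$lambda_pct, beta = x$design$beta,
    lloq_pct = x$lloq_pct, uloq_pct = x$uloq_pct,
    lloq_conc = x$lloq_conc, uloq_conc = x$uloq_conc,
    lod_conc = x$lod_conc, valid = x$valid
  )
}

#' Plot an accuracy profile
#'
#' Relative bias line with the beta-expectation tolerance band against the
#' acceptance limits `+/- lambda` — the usual accuracy-profile layout.
#'
#' @param object An [accuracy_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_profile <- function(object, ...) {
  lv <- object$levels
  lam <- object$design$lambda_pct
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$level_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eti_low_pct,
                                      ymax = .data$eti_high_pct),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eti_low_pct),
                       colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$eti_high_pct),
                       colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bias_pct), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$bias_pct), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(-lam, lam), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Concentration level (% of nominal)",
                  y = "Relative error (%)",
                  title = "Accuracy profile",
                  subtitle = sprintf("beta = %.2f, acceptance limits +/- %.3g%%",
                                     object$design$beta, lam))
}

#' @export
print.linearity_profile <- function(x, ...) {
  cat(sprintf("<linearity_profile: slope %.4f, intercept %.4g, r^2 %.4f, %s>\n",
              x$slope, x$intercept, x$r_squared,
              if (x$valid) "valid" else "NOT valid"))
  invisible(x)
}

#' @rdname tidy.accuracy_profile
#' @export
tidy.linearity_profile <- function(x, ...) {
  x$levels
}

#' @rdname tidy.accuracy_profile
#' @export
glance.linearity_profile <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, valid = x$valid)
}

#' Plot a linearity profile
#'
#' Back-calculated versus introduced concentrations on the absolute scale:
#' identity line, fitted line, absolute tolerance limits and the acceptance
#' limits `mu_t * (1 +/- lambda/100)`.
#'
#' @param object A [linearity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linearity_profile <- function(object, ...) {
  lv <- object$levels
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$mu_t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$abs_tol_low,
                                      ymax = .data$abs_tol_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$abs_acc_low), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$abs_acc_high), linetype = "dotted") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "Introduced concentration (ug/mL)",
                  y = "Back-calculated concentration (ug/mL)",
                  title = "Linearity profile")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$results)
  cat(sprintf("selected: %s\n",
              if (is.na(x$selected)) "none (no valid range)" else x$selected))
  invisible(x)
}

#' @rdname tidy.accuracy_profile
#' @export
tidy.model_comparison <- function(x, ...) {
  x$results
}
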