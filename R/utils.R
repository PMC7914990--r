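# Internal argument checks. All user-facing errors are classed so callers
# (and the pipeline runner) can distinguish design errors from data errors.

stop_design <- function(msg) abort(msg, class = "accuprofile_design_error")
stop_data   <- function(msg) abort(msg, class = "accuprofile_data_error")
stop_fit    <- function(msg) abort(msg, class = "accuprofile_fit_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_design(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_design(sprintf("`%s` = %g is outside the allowed range", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop_design(sprintf("`%s` must be a whole number", name))
  }
  invisible(as.integer(x))
}

# zero-noise data are legitimate inputs in this package; keep summary.lm
# quiet about exact fits
quiet_lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_data(sprintf("%s is missing required column(s): %s",
                      what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
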