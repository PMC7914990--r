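zero_noise_config <- function(...) {
  validation_sim_config(slope_series_rsd = 0, sigma_within_pct = 0,
                        sigma_between_pct = 0, true_intercept = 0,
                        relative_bias_per_level = 0, seed = 11, ...)
}

test_that("zero-noise calibration satisfies the generating line exactly", {
  cal <- simulate_calibration(zero_noise_config(true_slope = 3.5))
  expect_equal(cal$response, 3.5 * cal$concentration, tolerance = 0)
  expect_equal(nrow(cal), 3 * 7 * 3)
  expect_setequal(unique(cal$level_pct), c(5, 10, 25, 50, 75, 100, 120))
})

test_that("same config and seed give bit-identical outputs", {
  cfg <- validation_sim_config(seed = 42)
  expect_identical(simulate_calibration(cfg), simulate_calibration(cfg))
  expect_identical(simulate_validation(cfg), simulate_validation(cfg))
  dcfg <- dissolution_sim_config(seed = 42)
  expect_identical(simulate_dissolution_pair(dcfg),
                   simulate_dissolution_pair(dcfg))
  # and a different seed changes the draw
  cfg2 <- validation_sim_config(seed = 43)
  expect_false(identical(simulate_validation(cfg), simulate_validation(cfg2)))
})

test_that("zero-noise validation back-calculates to the biased truth exactly", {
  cfg <- zero_noise_config()
  cfg$relative_bias_per_level <- rep(2, 7)
  val <- simulate_validation(cfg)
  back <- back_calculate(true_response_function(cfg), val$response)
  expect_equal(back, 1.02 * val$true_concentration, tolerance = 1e-12)
})

test_that("per-series calibration slopes are recovered without bias", {
  # replicate noise dominates the per-series slope draw, so the slope
  # estimates scatter around the truth; their mean must sit on it
  slopes <- unlist(lapply(1:300, function(s) {
    cfg <- validation_sim_config(sigma_within_pct = 1.5, seed = s)
    cal <- simulate_calibration(cfg)
    vapply(split(cal, cal$series),
           function(d) ols_oracle(d$concentration, d$response)$slope,
           numeric(1))
  }))
  expect_equal(mean(slopes), 3.5, tolerance = 0.005)
  # without replicate noise only the configured slope draw remains, and
  # essentially all fitted slopes fall inside its 3-sigma band
  slopes0 <- unlist(lapply(1:300, function(s) {
    cfg <- validation_sim_config(sigma_within_pct = 0, true_intercept = 0,
                                 seed = s)
    cal <- simulate_calibration(cfg)
    vapply(split(cal, cal$series),
           function(d) ols_oracle(d$concentration, d$response)$slope,
           numeric(1))
  }))
  expect_gte(mean(abs(slopes0 - 3.5) <= 3 * 0.001 * 3.5), 0.99)
})

test_that("validation generator reproduces the configured variance structure", {
  # mean estimated intermediate-precision RSD ~ sqrt(sW^2 + sB^2)
  des <- validation_design(p = 3, n = 3, m = 3)
  s_R <- vapply(1:400, function(s) {
    cfg <- validation_sim_config(level_percents = 100,
                                 relative_bias_per_level = 0,
                                 sigma_within_pct = 1.5,
                                 sigma_between_pct = 1.0, seed = s)
    val <- simulate_validation(cfg)
    val$concentration <- back_calculate(true_response_function(cfg),
                                        val$response)
    level_statistics(val, unique(val$true_concentration), des)$s_R_pct
  }, numeric(1))
  expect_equal(mean(s_R), sqrt(1.5^2 + 1.0^2), tolerance = 0.1 / 1.8)
})

test_that("configured per-level bias is recovered at the lowest level", {
  des <- validation_design(p = 3, n = 3, m = 3)
  bias <- vapply(1:400, function(s) {
    cfg <- validation_sim_config(seed = s) # default bias -2.3% at level 5
    val <- simulate_validation(cfg)
    val <- val[val$level_pct == 5, ]
    val$concentration <- back_calculate(true_response_function(cfg),
                                        val$response)
    level_statistics(val, unique(val$true_concentration), des)$bias_pct
  }, numeric(1))
  expect_equal(mean(bias), -2.3, tolerance = 0.2 / 2.3)
})

test_that("dissolution trajectories follow the first-order closed form", {
  cfg <- dissolution_sim_config(n_units = 4, time_points = c(0, 5, 20),
                                f_inf = 100, rate_k = 0.15, unit_rsd = 0,
                                measurement_rsd = 0, seed = 5)
  pair <- simulate_dissolution_pair(cfg)
  at20 <- pair$release_pct[pair$time_min == 20]
  expect_equal(at20, rep(100 * (1 - exp(-3)), 8), tolerance = 1e-12)
  expect_equal(unique(pair$release_pct[pair$time_min == 0]), 0)
  # zero noise: methods identical, paired comparison degenerate at t = 0
  test <- pair[pair$method == "test", ]
  ref <- pair[pair$method == "reference", ]
  expect_equal(test$release_pct, ref$release_pct, tolerance = 0)
  cmp <- paired_method_comparison(test, ref)
  expect_true(all(cmp$t == 0) && all(cmp$p_value == 1))
})

test_that("invalid simulation configs are rejected", {
  expect_error(validation_sim_config(p_series = 1), class = "accuprofile_design_error")
  expect_error(validation_sim_config(level_percents = c(10, 5)),
               class = "accuprofile_design_error")
  expect_error(validation_sim_config(sigma_within_pct = -1),
               class = "accuprofile_design_error")
  expect_error(validation_sim_config(relative_bias_per_level = c(1, 2)),
               class = "accuprofile_design_error")
  expect_error(dissolution_sim_config(f_inf = 150),
               class = "accuprofile_design_error")
  expect_error(dissolution_sim_config(rate_k = 0),
               class = "accuprofile_design_error")
})
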