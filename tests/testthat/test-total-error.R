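des33 <- validation_design(p = 3, n = 3, m = 3)

level_data <- function(...) {
  groups <- list(...)
  tibble::tibble(
    series = rep(seq_along(groups), lengths(groups)),
    concentration = unlist(groups)
  )
}

test_that("level statistics match the hand ANOVA oracle", {
  d1 <- level_data(c(98, 102), c(96, 104))
  st <- level_statistics(d1, 100, validation_design(p = 2, n = 2, m = 3))
  or <- anova_oracle(d1$series, d1$concentration)
  expect_equal(st$bias_pct, 0)
  expect_equal(st$ms_within, or$ms_within)
  expect_equal(st$ms_within, 20)
  expect_equal(st$sigma2_b, 0) # truncated from (0 - 20)/2 = -10
  expect_equal(st$s_r_pct, 100 * sqrt(20) / 100, tolerance = 1e-12)
  expect_equal(st$s_R_pct, st$s_r_pct)

  d2 <- level_data(c(9, 11), c(10, 12), c(8, 10))
  st2 <- level_statistics(d2, 10, validation_design(p = 3, n = 2, m = 3))
  or2 <- anova_oracle(d2$series, d2$concentration)
  expect_equal(st2$ms_within, 2)
  expect_equal(st2$ms_between, 2)
  expect_equal(st2$ms_within, or2$ms_within)
  expect_equal(st2$ms_between, or2$ms_between)
  expect_equal(st2$sigma2_b, 0)
  expect_equal(st2$bias_pct, 0)
  expect_equal(st2$s_r_pct, 100 * sqrt(2) / 10, tolerance = 1e-12)
})

test_that("level statistics reject degenerate and unbalanced data", {
  flat <- level_data(c(10, 10, 10), c(10, 10, 10), c(10, 10, 10))
  expect_error(level_statistics(flat, 10, des33),
               class = "accuprofile_data_error")
  st <- level_statistics(flat, 10, des33, allow_degenerate = TRUE)
  expect_equal(st$bias_pct, 0)
  expect_equal(st$s_R_pct, 0)
  unbal <- level_data(c(9, 11), c(10, 12, 14), c(8, 10, 9))
  expect_error(level_statistics(unbal, 10, des33),
               class = "accuprofile_design_error")
})

test_that("rsd normalisation can switch between mu_hat and mu_t", {
  d <- level_data(c(108, 112, 110), c(106, 114, 111), c(109, 111, 113))
  by_hat <- level_statistics(d, 100, des33)
  by_t <- level_statistics(
    d, 100, validation_design(p = 3, n = 3, m = 3, rsd_reference = "mu_t"))
  expect_equal(by_t$s_r_pct / by_hat$s_r_pct, by_hat$mu_hat / 100,
               tolerance = 1e-12)
})

test_that("satterthwaite dof: closed form, limits, and form equivalence", {
  expect_equal(satterthwaite_dof(0, 3, 3), 54 / 7, tolerance = 1e-12)
  expect_equal(satterthwaite_dof(1, 3, 3), 108 / 26, tolerance = 1e-12)
  # monotone to the p - 1 limit as the between component dominates
  grid <- satterthwaite_dof(c(0, 0.5, 1, 5, 50, 1e8), 3, 3)
  expect_true(all(diff(grid) < 0))
  expect_equal(grid[length(grid)], 2, tolerance = 1e-6)
  # R-form and mean-squares form agree on random mean squares
  withr::with_seed(7, {
    for (i in 1:400) {
      p <- sample(2:6, 1)
      n <- sample(2:6, 1)
      msw <- runif(1, 0.1, 5)
      msb <- msw * runif(1, 1, 20) # MSB >= MSW so the ratio is non-negative
      r <- (msb - msw) / (n * msw)
      expect_equal(satterthwaite_dof(r, p, n),
                   satterthwaite_dof_ms(msb, msw, p, n), tolerance = 1e-10)
    }
  })
  expect_error(satterthwaite_dof(-0.1, 3, 3),
               class = "accuprofile_design_error")
  expect_error(satterthwaite_dof(1, 1, 3), class = "accuprofile_design_error")
})

test_that("tolerance factor combines the t quantile and design inflation", {
  nu <- 54 / 7
  k <- tolerance_factor(nu, 0.95, 3, 3, b2 = 1)
  expect_equal(k, qt(0.975, nu) * sqrt(1 + 1 / 9), tolerance = 1e-12)
  expect_equal(k, 2.44, tolerance = 0.01)
  # asymptote: infinite dof and infinite p*n*B^2 recover the normal quantile
  expect_equal(tolerance_factor(Inf, 0.95, 1e6, 1e6, 1), qnorm(0.975),
               tolerance = 1e-6)
  # strictly decreasing in p*n*B2 at fixed nu, beta
  ks <- vapply(c(0.1, 0.3, 0.6, 1), function(b2)
    tolerance_factor(10, 0.95, 3, 3, b2), numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_error(tolerance_factor(10, 0.95, 3, 3, 0),
               class = "accuprofile_design_error")
  expect_error(tolerance_factor(0, 0.95, 3, 3, 1),
               class = "accuprofile_design_error")
})

test_that("beta-ETI is symmetric about the bias with half-width k * s_R", {
  stats <- tibble::tibble(bias_pct = 1, s_R_pct = 3, nu = 10, b2 = 0.8)
  out <- beta_eti(stats, des33)
  expect_equal(out$eti_low_pct, 1 - out$k_tol * 3)
  expect_equal(out$eti_high_pct, 1 + out$k_tol * 3)
  # collapsed interval when the spread term vanishes
  flat <- beta_eti(tibble::tibble(bias_pct = 2, s_R_pct = 0, nu = Inf, b2 = 1),
                   des33)
  expect_equal(flat$eti_low_pct, 2)
  expect_equal(flat$eti_high_pct, 2)
  # symmetry invariant on simulated data
  cfg <- validation_sim_config(seed = 21)
  val <- simulate_validation(cfg)
  val$concentration <- back_calculate(true_response_function(cfg),
                                      val$response)
  prof <- accuracy_profile(val, validation_design())
  lv <- prof$levels
  expect_equal(lv$eti_high_pct - lv$bias_pct, lv$bias_pct - lv$eti_low_pct,
               tolerance = 1e-10)
  expect_equal(lv$eti_high_pct - lv$bias_pct, lv$k_tol * lv$s_R_pct,
               tolerance = 1e-10)
  expect_true(all(lv$s_R_pct >= lv$s_r_pct))
})

test_that("profile decision locates LLOQ/ULOQ by interpolating the crossing", {
  des <- validation_design(p = 3, n = 3, m = 3)
  # lower bound -20 at level 5 and -5 at level 10 crosses -lambda at 8.33%
  iv <- tibble::tibble(level_pct = c(5, 10, 25),
                       eti_low_pct = c(-20, -5, -3),
                       eti_high_pct = c(5, 5, 3))
  prof <- profile_from_intervals(iv, des)
  expect_false(prof$valid)
  expect_equal(prof$lloq_pct, 5 + 10 / 15 * 5, tolerance = 1e-12)
  expect_equal(prof$uloq_pct, 25)
  # all-zero intervals: trivially valid over the full range
  zero <- tibble::tibble(level_pct = c(5, 50, 120), eti_low_pct = 0,
                         eti_high_pct = 0)
  pz <- profile_from_intervals(zero, des)
  expect_true(pz$valid)
  expect_equal(pz$lloq_pct, 5)
  expect_equal(pz$uloq_pct, 120)
  # no valid level: profile-invalid result, not an exception
  bad <- tibble::tibble(level_pct = c(5, 50, 120), eti_low_pct = -30,
                        eti_high_pct = 30)
  pb <- profile_from_intervals(bad, des)
  expect_false(pb$valid)
  expect_true(is.na(pb$lloq_pct))
  # an upper-bound violation at the top interpolates the ULOQ from above
  top <- tibble::tibble(level_pct = c(5, 50, 120),
                        eti_low_pct = c(-3, -3, -3),
                        eti_high_pct = c(3, 5, 15))
  pt_ <- profile_from_intervals(top, des)
  expect_equal(pt_$uloq_pct, 50 + (120 - 50) / 2, tolerance = 1e-12)
})

test_that("enlarging lambda never shrinks the valid range", {
  withr::with_seed(31, {
    for (i in 1:40) {
      m <- sample(4:8, 1)
      lv <- sort(runif(m, 5, 120))
      bias <- rnorm(m, 0, 5)
      hw <- runif(m, 1, 12)
      iv <- tibble::tibble(level_pct = lv, eti_low_pct = bias - hw,
                           eti_high_pct = bias + hw)
      d1 <- validation_design(p = 3, n = 3, m = m, lambda_pct = 10)
      d2 <- validation_design(p = 3, n = 3, m = m, lambda_pct = 15)
      p1 <- profile_from_intervals(iv, d1)
      p2 <- profile_from_intervals(iv, d2)
      w1 <- if (is.na(p1$lloq_pct)) 0 else p1$uloq_pct - p1$lloq_pct
      w2 <- if (is.na(p2$lloq_pct)) 0 else p2$uloq_pct - p2$lloq_pct
      expect_gte(w2, w1)
    }
  })
})

test_that("accuracy_profile on generated data carries design metadata", {
  cfg <- validation_sim_config(seed = 8)
  val <- simulate_validation(cfg)
  val$concentration <- back_calculate(true_response_function(cfg),
                                      val$response)
  prof <- accuracy_profile(val, validation_design(), lod_conc = 0.5)
  expect_s3_class(prof, "accuracy_profile")
  expect_equal(nrow(tidy(prof)), 7)
  gl <- glance(prof)
  expect_equal(gl$lambda_pct, 10)
  expect_equal(gl$beta, 0.95)
  expect_equal(gl$lod_conc, 0.5)
  expect_equal(prof$nominal_concentration, 55.56, tolerance = 1e-6)
  expect_equal(gl$lloq_conc, prof$lloq_pct / 100 * 55.56, tolerance = 1e-6)
  # level count must match the declared design
  expect_error(accuracy_profile(val, validation_design(m = 5)),
               class = "accuprofile_design_error")
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
})

test_that("linearity profile recovers exact scalings and absolute limits", {
  cfg <- validation_sim_config(seed = 12, slope_series_rsd = 0,
                               sigma_within_pct = 0, sigma_between_pct = 0,
                               true_intercept = 0,
                               relative_bias_per_level = 0)
  val <- simulate_validation(cfg)
  val$concentration <- back_calculate(true_response_function(cfg),
                                      val$response)
  lp <- linearity_profile(val, validation_design(), allow_degenerate = TRUE)
  expect_equal(lp$slope, 1, tolerance = 1e-10)
  expect_equal(lp$intercept, 0, tolerance = 1e-8)
  expect_equal(lp$r_squared, 1, tolerance = 1e-12)
  expect_true(lp$valid)

  val2 <- val
  val2$concentration <- 1.02 * val2$true_concentration
  lp2 <- linearity_profile(val2, validation_design(), allow_degenerate = TRUE)
  expect_equal(lp2$slope, 1.02, tolerance = 1e-10)
  expect_equal(lp2$intercept, 0, tolerance = 1e-8)

  # random data: fit matches the normal-equations oracle
  withr::with_seed(5, {
    val3 <- val
    val3$concentration <- val3$true_concentration * (1 + rnorm(nrow(val3), 0, 0.02))
    lp3 <- linearity_profile(val3, validation_design())
    or <- ols_oracle(val3$true_concentration, val3$concentration)
    expect_equal(lp3$slope, or$slope, tolerance = 1e-10)
    expect_equal(lp3$intercept, or$intercept, tolerance = 1e-10)
  })
  # absolute tolerance limits are the relative interval rescaled by mu_t
  lv <- lp3$levels
  expect_equal(lv$abs_tol_low, lv$mu_t * (1 + lv$eti_low_pct / 100))
  expect_equal(lv$abs_acc_high, lv$mu_t * 1.1)
})

test_that("model comparison prefers parsimony on ideal data and a single
           candidate is selected iff valid", {
  cfg <- validation_sim_config(seed = 3, slope_series_rsd = 0,
                               sigma_within_pct = 0, sigma_between_pct = 0,
                               true_intercept = 0, relative_bias_per_level = 0)
  cal <- simulate_calibration(cfg)
  val <- simulate_validation(cfg)
  cmp <- compare_response_models(cal, val, validation_design(),
                                 allow_degenerate = TRUE)
  expect_true(all(cmp$results$profile_valid))
  expect_identical(cmp$selected, "single_point_origin")

  one <- compare_response_models(cal, val, validation_design(),
                                 candidates = "ols_linear",
                                 allow_degenerate = TRUE)
  expect_identical(one$selected, "ols_linear")
  expect_true(one$results$selected)
})

test_that("a material intercept breaks the one-point model at low levels", {
  # clean calibration, but an intercept worth ~15% of the lowest-level
  # response: through-origin calibration cannot absorb it
  cfg <- validation_sim_config(seed = 17, true_intercept = 1.5,
                               sigma_within_pct = 0.25,
                               sigma_between_pct = 0.1)
  cal <- simulate_calibration(cfg)
  val <- simulate_validation(cfg)
  cmp <- compare_response_models(cal, val, validation_design())
  res <- cmp$results
  sp <- res[res$model_kind == "single_point_origin", ]
  ols <- res[res$model_kind == "ols_linear", ]
  expect_false(sp$profile_valid)
  expect_gt(sp$lloq_pct, 10) # low levels fall outside the limits
  expect_gt(sp$lloq_pct, ols$lloq_pct) # the full line reaches further down
  expect_identical(cmp$selected, "ols_linear")
})

test_that("robustness and placebo checks apply the relative-error rules", {
  cond <- tibble::tibble(parameter = c("flow", "flow", "Ni"),
                         value = c(0.8, 1.0, 9.5),
                         mean_response = c(100, 104, 94))
  out <- robustness_assess(cond, reference_response = 100)
  expect_equal(out$re_pct, c(0, 4, -6))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_error(robustness_assess(cond, 0), class = "accuprofile_design_error")

  expect_true(placebo_interference(0, 60)$pass)
  expect_equal(placebo_interference(0.9, 60, threshold_pct = 1.5)$interference_pct,
               1.5)
  expect_false(placebo_interference(60, 60, threshold_pct = 5)$pass)
})
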