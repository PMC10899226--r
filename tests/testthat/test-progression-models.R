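# Threshold-versus-age model fitting, selection, and curve inversion.

noiseless_data <- function(family, ages = seq(10, 70, length.out = 40)) {
  truth <- switch(family,
    power       = list(params = c(a = 2, b = 0.8),
                       y = 2 * ages^0.8),
    linear      = list(params = c(c0 = 5, c1 = 0.5),
                       y = 5 + 0.5 * ages),
    logarithmic = list(params = c(c0 = -10, c1 = 15),
                       y = -10 + 15 * log(ages)),
    quadratic   = list(params = c(c0 = 8, c1 = 0.2, c2 = 0.01),
                       y = 8 + 0.2 * ages + 0.01 * ages^2))
  c(truth, list(ages = ages))
}

test_that("noiseless data from each family is recovered exactly", {
  for (fam in model_families()) {
    d <- noiseless_data(fam)
    fit <- fit_model(d$ages, d$y, fam)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(unname(fit$params), unname(d$params), tolerance = 1e-6)
    expect_identical(fit$n, length(d$ages))
    expect_equal(fit$age_range, range(d$ages))
  }
})

test_that("R-squared matches the definitional 1 - SS_res/SS_tot oracle", {
  set.seed(11)
  for (i in 1:25) {
    ages <- runif(60, 10, 70)
    y <- 2 * ages^0.8 + rnorm(60, 0, 3)
    for (fam in model_families()) {
      fit <- fit_model(ages, y, fam)
      pred <- predict(fit, ages)
      r2_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      expect_equal(fit$r_squared, r2_oracle, tolerance = 1e-10)
    }
  }
})

test_that("fit preconditions are enforced", {
  expect_error(fit_model(1:3, c(1, 2, 4), "quadratic"),
               class = "ap_insufficient_data_error")
  expect_error(fit_model(c(-1, 2, 3), c(1, 2, 3), "linear"),
               class = "ap_validation_error")
  expect_error(fit_model(1:10, rep(30, 10), "linear"),
               class = "ap_degenerate_data_error")
})

test_that("select_best maximizes R2 with parameter and order tie-breaks", {
  mk <- function(fam, r2) audioprog:::fitted_model(
    fam, c(a = 1, b = 1, c = 1)[seq_len(
      audioprog:::family_parameter_count(fam))],
    r2, 10L, c(10, 70))
  fits <- list(mk("power", 0.987), mk("quadratic", 0.933),
               mk("logarithmic", 0.930), mk("linear", 0.873))
  expect_identical(select_best(fits)$family, "power")
  expect_identical(select_best(fits[2])$family, "quadratic")
  # identical R2: fewer parameters win
  expect_identical(select_best(list(mk("quadratic", 0.9),
                                    mk("linear", 0.9)))$family, "linear")
  # same R2 and parameter count: fixed family order
  expect_identical(select_best(list(mk("linear", 0.9),
                                    mk("logarithmic", 0.9)))$family,
                   "logarithmic")
  expect_error(select_best(list()), class = "ap_empty_input_error")
})

test_that("crossing_age inverts each monotone family", {
  lin <- fit_model(1:40, 1:40, "linear")  # y = x
  expect_equal(crossing_age(lin, 25)$age, 25, tolerance = 1e-9)
  expect_false(crossing_age(lin, 25)$extrapolated)

  # round trip: crossing_age(predict(x)) = x across families
  for (fam in model_families()) {
    d <- noiseless_data(fam)
    fit <- fit_model(d$ages, d$y, fam)
    for (x in seq(12, 68, length.out = 9)) {
      expect_equal(crossing_age(fit, predict(fit, x))$age, x,
                   tolerance = 1e-6)
    }
  }

  # extrapolation is flagged, not refused
  pw <- fit_model(20:40, 2 * (20:40)^0.8, "power")
  cr <- crossing_age(pw, 60)  # (60/2)^(1/0.8) = 70.2 y, beyond the data
  expect_true(cr$extrapolated)
  expect_equal(cr$age, 30^(1 / 0.8), tolerance = 1e-6)

  # decreasing or unattainable curves raise no-crossing errors
  falling <- fit_model(1:10, 100 - (1:10), "linear")
  expect_error(crossing_age(falling, 25), class = "ap_no_crossing_error")
  shallow <- fit_model(1:10, 10 + 0.01 * (1:10), "linear")
  expect_error(crossing_age(shallow, 60), class = "ap_no_crossing_error")
})

test_that("quadratic inversion picks the smallest positive upward crossing", {
  # y = 50 - 2x + 0.05 x^2: falls to a minimum at x = 20 then rises;
  # upward crossing of 50 dB is at x = 40, not the downward one at x = 0
  fit <- audioprog:::fitted_model("quadratic",
                                  c(c0 = 50, c1 = -2, c2 = 0.05),
                                  NA_real_, 10L, c(5, 60))
  expect_equal(crossing_age(fit, 50)$age, 40, tolerance = 1e-9)
  expect_error(crossing_age(fit, 20), class = "ap_no_crossing_error")
})

test_that("two_point_power_model reproduces its anchors and is symmetric", {
  b_true <- 1.3
  m <- two_point_power_model(c(10, 20), c(10 * 3, 20 * 3^b_true))
  expect_equal(m$params[["b"]], b_true, tolerance = 1e-12)

  m_low <- two_point_power_model(c(26.07, 25), c(65.30, 60))
  expect_equal(predict(m_low, 26.07), 25, tolerance = 1e-9)
  expect_equal(predict(m_low, 65.30), 60, tolerance = 1e-9)
  expect_true(is.na(m_low$r_squared))

  swapped <- two_point_power_model(c(65.30, 60), c(26.07, 25))
  expect_equal(swapped$params, m_low$params, tolerance = 1e-12)

  expect_error(two_point_power_model(c(-1, 20), c(10, 30)),
               class = "ap_domain_error")
  expect_error(two_point_power_model(c(10, 20), c(10, 30)),
               class = "ap_degenerate_data_error")
})

test_that("onset age equals the 25 dB crossing of the fitted curve", {
  lin <- fit_model(1:40, 1:40, "linear")
  expect_equal(onset_age(lin), 25, tolerance = 1e-9)

  x <- seq(10, 70, length.out = 50)
  pw <- fit_model(x, 2 * x^0.8, "power")
  expect_equal(onset_age(pw), (25 / 2)^(1 / 0.8), tolerance = 1e-6)

  anchored <- two_point_power_model(c(19.23, 25), c(41.17, 60))
  expect_equal(onset_age(anchored), 19.23, tolerance = 1e-9)
})

test_that("HPT is the difference of the 60 and 25 dB crossing ages", {
  unit_slope <- fit_model(1:80, (1:80) + 0, "linear")
  expect_equal(hearing_progression_time(unit_slope), 35, tolerance = 1e-9)

  m <- two_point_power_model(c(22.70, 25), c(41.17, 60))
  expect_equal(hearing_progression_time(m), 41.17 - 22.70, tolerance = 1e-9)
  expect_equal(hearing_progression_time(m),
               crossing_age(m, 60)$age - crossing_age(m, 25)$age)

  # invariant under reparameterization of the same curve
  m2 <- two_point_power_model(c(30, predict(m, 30)), c(38, predict(m, 38)))
  expect_equal(hearing_progression_time(m2), hearing_progression_time(m),
               tolerance = 1e-9)
})

test_that("progression_summary recovers a noiseless cohort's band curves", {
  co <- generate_cohort(tbc1d24_profile_spec(noise_sd = 0, seed = 5))
  ps <- progression_summary(co)

  expected <- list(low = c(26.07, 65.30), mid = c(22.70, 41.17),
                   high = c(18.37, 37.74))
  for (nm in names(expected)) {
    expect_equal(ps$bands[[nm]]$age_25, expected[[nm]][1], tolerance = 1e-4)
    expect_equal(ps$bands[[nm]]$age_60, expected[[nm]][2], tolerance = 1e-4)
    expect_equal(ps$bands[[nm]]$hpt,
                 ps$bands[[nm]]$age_60 - ps$bands[[nm]]$age_25)
  }
  # the low-band 60 dB crossing (65.30 y) lies beyond the sampled ages
  expect_true(ps$bands$low$extrapolated)

  # permutation invariance over subjects
  set.seed(9)
  ps_shuffled <- progression_summary(sample(co))
  expect_equal(ps_shuffled, ps)
})

test_that("a band that never reaches 60 dB reports in place", {
  spec <- tbc1d24_profile_spec(noise_sd = 0, seed = 5)
  # flatten the low band: 10 * x^0.1 stays under 20 dB for all ages <= 120
  spec$curves$TBC[["250"]] <- c(10, 0.1)
  spec$curves$TBC[["500"]] <- c(10, 0.1)
  spec$curves$TLDc[["250"]] <- c(10, 0.1)
  spec$curves$TLDc[["500"]] <- c(10, 0.1)
  co <- generate_cohort(spec)
  expect_warning(ps <- progression_summary(co),
                 class = "ap_band_skipped_warning")
  expect_match(ps$bands$low$error, "never attains")
  expect_true(is.na(ps$bands$low$hpt))
  expect_equal(ps$bands$mid$hpt, 41.17 - 22.70, tolerance = 1e-4)
  expect_equal(ps$bands$high$hpt, 37.74 - 18.37, tolerance = 1e-4)
})
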