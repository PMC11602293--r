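test_that("Michaelis-Menten fitting recovers noiseless parameters", {
  S <- c(0.5, 1, 2, 4, 8, 16)
  v <- 10 * S / (2 + S)
  fit <- fit_michaelis_menten(S, v)
  expect_equal(fit$Km, 2, tolerance = 1e-6)
  expect_equal(fit$Vmax, 10, tolerance = 1e-6)
  # at S = Km the rate is half Vmax by definition
  expect_equal(10 * 2 / (2 + 2), 10 / 2)

  # with an enzyme concentration the turnover and efficiency follow
  fit2 <- fit_michaelis_menten(S, v, enzyme_conc = 2)
  expect_equal(fit2$kcat, 5, tolerance = 1e-6)
  expect_equal(fit2$efficiency, fit2$kcat / fit2$Km, tolerance = 1e-9)
})

test_that("Michaelis-Menten preconditions are enforced", {
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)),
               class = "msc_value_error")
  expect_error(fit_michaelis_menten(c(1, 2, 3, 4), c(1, -1, 2, 3)),
               class = "msc_value_error")
})

test_that("first-order decay fitting: exact halving and closed-form residuals", {
  fit <- fit_first_order_decay(c(0, 10, 20), c(100, 50, 25))
  expect_equal(fit$half_life, 10, tolerance = 1e-9)
  expect_equal(fit$k_inact * fit$half_life, log(2), tolerance = 1e-12)
  expect_equal(fit$A0, 100, tolerance = 1e-6)

  # residual activity at 30 min for a 9.80 min half-life, ~12%
  expect_equal(100 * 2^(-30 / 9.80), 11.98, tolerance = 1e-3)

  expect_error(fit_first_order_decay(c(0, 10, 20), c(50, 75, 100)),
               class = "msc_no_decay_error")
  expect_error(fit_first_order_decay(c(0, 10), c(100, 50)),
               class = "msc_value_error")
})

test_that("fold and percent comparisons match the published arithmetic", {
  f <- fold_and_percent(9.80, 55.93)
  expect_equal(round(f$fold, 1), 5.7)
  g <- fold_and_percent(7.10, 9.21)
  expect_equal(round(g$percent_change, 1), 29.7)
  h <- fold_and_percent(5, 5)
  expect_equal(h$fold, 1)
  expect_equal(h$percent_change, 0)
  expect_error(fold_and_percent(0, 5), class = "msc_value_error")
  # consistency: percent = 100 (fold - 1)
  for (pair in list(c(2, 3), c(9.8, 35.36), c(0.5, 0.1))) {
    fp <- fold_and_percent(pair[1], pair[2])
    expect_equal(fp$percent_change, 100 * (fp$fold - 1), tolerance = 1e-12)
  }
})

test_that("profile normalisation scales the maximum to 100%", {
  out <- normalize_profile(c("a", "b", "c"), c(2, 4, 8))
  expect_equal(out$percent, c(25, 50, 100))
  expect_equal(normalize_profile("x", 3)$percent, 100)
  # invariance under positive rescaling
  expect_equal(normalize_profile(1:3, c(2, 4, 8) * 7.3)$percent,
               out$percent)
  expect_error(normalize_profile(1:2, c(0, 0)), class = "msc_value_error")
})

test_that("plate calibration interpolates log-linearly and inverts exactly", {
  cal <- calibrate_plate(c(10, 100), c(50, 100))
  expect_equal(zone_to_activity(cal, 75), 10^1.5, tolerance = 1e-9)
  expect_equal(zone_to_activity(cal, 50), 10, tolerance = 1e-9)
  expect_equal(zone_to_activity(cal, 100), 100, tolerance = 1e-9)
  # order of standards is irrelevant
  cal2 <- calibrate_plate(c(100, 10), c(100, 50))
  expect_equal(cal2$slope, cal$slope, tolerance = 1e-12)
  expect_error(calibrate_plate(c(10, 100), c(50, 50)),
               class = "msc_rank_deficiency_error")
})

test_that("published parameter presets are exposed for all four variants", {
  p <- kinetics_presets()
  expect_setequal(p$variant, c("rAprY", "A216E", "A216K", "A216R"))
  expect_true(all(p$Km > 0 & p$kcat > 0 & p$half_life > 0))
  spec <- kinetics_spec_preset("A216K")
  expect_equal(spec$half_life, 55.93)
  expect_error(kinetics_spec_preset("A217X"), class = "msc_value_error")
})

test_that("noisy Michaelis-Menten recovery is unbiased at the median", {
  spec <- kinetics_spec_preset("rAprY", noise_sd = 0.01)
  kms <- vapply(1:60, function(i) {
    ser <- gen_kinetic_series(spec, seed = i)
    fit_michaelis_menten(ser$mm$substrate, ser$mm$rate)$Km
  }, numeric(1))
  expect_lt(abs(stats::median(kms) / 1.52 - 1), 0.05)
})
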