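test_that("sensitivity regression recovers exact and noisy slopes", {
  f <- seq(1e-6, 8e-6, length.out = 8)
  exact <- sensitivity_from_points(f, 0.71 * f)
  expect_equal(exact$sensitivity_A_per_W, 0.71)
  expect_equal(exact$r_squared, 1)
  # any noiseless slope is recovered to machine precision
  other <- sensitivity_from_points(f, 0.123 * f + 2e-9)
  expect_equal(other$sensitivity_A_per_W, 0.123)
  expect_equal(other$intercept_A, 2e-9)
  # 1% Gaussian noise: slope back within 3 s.e.
  set.seed(5)
  noisy_i <- 0.71 * f * (1 + rnorm(8, sd = 0.01))
  fit <- sensitivity_from_points(f, noisy_i)
  expect_lt(abs(fit$sensitivity_A_per_W - 0.71), 3 * fit$sensitivity_se)
  expect_error(sensitivity_from_points(rep(1e-6, 3), c(1, 2, 3) * 1e-6),
               "distinct")
})

test_that("area scaling is the plain ratio of active areas", {
  expect_equal(area_scaled_flux(92.16e-9, 92.16, 7.5), 7.5e-9)
  expect_equal(area_scaled_flux(1e-6, 5, 5), 1e-6)
  expect_equal(area_scaled_flux(1e-6, 92.16, 7.5), 1e-6 * 7.5 / 92.16)
  expect_equal(area_scaled_flux(1e-6) * 1e9, 81.38, tolerance = 1e-4)
})

test_that("ADC least significant bit matches the published 44 pA", {
  lsb <- adc_lsb_current(5700e-9, 17)
  expect_equal(lsb * 1e12, 43.49, tolerance = 1e-3)
  expect_lt(abs(lsb - 44e-12), 1e-12)          # within 1 pA of the print
  expect_equal(adc_lsb_current(1024e-9, 10), 1e-9)
  expect_error(adc_lsb_current(1e-9, 0))
})

test_that("current-to-flux conversion exposes the sensitivity inconsistency", {
  expect_equal(current_to_flux(0, 0.71), 0)
  expect_equal(current_to_flux(0.71e-9, 0.71), 1e-9)
  # 44 pA at the rounded 0.71 A/W is 61.97 pW, not the printed 61.25 pW;
  # the printed pair implies ~0.7184 A/W, surfaced as a named constant
  expect_equal(current_to_flux(44e-12, 0.71) * 1e12, 61.97, tolerance = 1e-3)
  implied <- phantom_constants()$sensitivity_implied_A_per_W
  expect_equal(implied, 44 / 61.25)
  expect_equal(current_to_flux(44e-12, implied) * 1e12, 61.25)
})

test_that("ppm normalisation reproduces the published amplitudes", {
  expect_equal(flux_to_ppm(0.46e-9, 1.8e-3), 0.2556, tolerance = 1e-3)
  expect_equal(round(flux_to_ppm(0.46e-9, 1.8e-3), 2), 0.26)
  expect_equal(round(flux_to_ppm(0.18e-9, 1.8e-3), 2), 0.10)
  expect_equal(flux_to_ppm(1.8e-3, 1.8e-3), 1e6)
})

test_that("the flux-current-ppm algebra closes in a round trip", {
  s <- 0.71
  flux <- 3.3e-9
  current <- s * flux
  expect_equal(flux_to_ppm(current_to_flux(current, s), 1.8e-3),
               flux_to_ppm(flux, 1.8e-3))
})
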