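test_that("the linear fit recovers an exact line and saturated fits", {
  d <- seq(0.30, 0.50, by = 0.05)
  sw <- fake_sweep(d, 2e-4 - 3e-5 * d)
  fit <- fit_signal_vs_diameter(sw)
  expect_equal(fit$slope, -3e-5)
  expect_equal(fit$intercept, 2e-4)
  expect_equal(fit$r_squared, 1)
  # two points: the interpolating line, zero residual sd
  fit2 <- fit_signal_vs_diameter(fake_sweep(c(0.3, 0.5), c(1e-4, 8e-5)))
  expect_equal(fit2$slope, (8e-5 - 1e-4) / 0.2)
  expect_equal(fit2$residual_sd, 0)
  # a noiseless decreasing sequence has a negative slope
  fit3 <- fit_signal_vs_diameter(fake_sweep(d, rev(sort(runif(5)))))
  expect_lt(fit3$slope, 0)
  expect_error(fit_signal_vs_diameter(fake_sweep(rep(0.4, 3), rep(1e-4, 3))),
               "distinct")
})

test_that("pulsation amplitude follows the fitted-line algebra", {
  d <- seq(0.30, 0.50, by = 0.05)
  fit <- fit_signal_vs_diameter(fake_sweep(d, 1e-4 - 2e-5 * d))
  # full relaxed-to-dilated drop: -slope * 0.4 * 0.04 * 1e6 = 0.32 ppm
  pk <- pulsation_amplitude(fit, 0.4, 0.04, convention = "peak_to_peak")
  expect_equal(pk$amplitude_ppm, 0.32)
  # waveform-amplitude convention reports half the swing
  amp <- pulsation_amplitude(fit, 0.4, 0.04)
  expect_equal(amp$amplitude_ppm, 0.16)
  expect_equal(amp$peak_to_peak_ppm, 0.32)
  # equivalently S(0.400) - S(0.416) on the fitted line
  expect_equal(pk$amplitude_ppm,
               (predict(fit, 0.400) - predict(fit, 0.416)) * 1e6)
  # a flat response has zero amplitude
  flat <- fit_signal_vs_diameter(fake_sweep(d, rep(1e-4, 5)))
  expect_equal(pulsation_amplitude(flat)$amplitude_ppm, 0)
  # dilation beyond the fitted range warns about extrapolation
  expect_warning(pulsation_amplitude(fit, baseline_diameter = 0.49), "extrapolat")
})

test_that("amplitude is exactly linear in the dilation fraction", {
  d <- seq(0.30, 0.50, by = 0.05)
  fit <- fit_signal_vs_diameter(fake_sweep(d, 1e-4 - 2e-5 * d))
  a1 <- pulsation_amplitude(fit, dilation = 0.02)$amplitude_ppm
  a2 <- pulsation_amplitude(fit, dilation = 0.04)$amplitude_ppm
  expect_equal(2 * a1, a2)
})

test_that("a perturbation sweep covers the published diameters and is monotone", {
  sw <- sweep_diameters(2.5, photons = 1e5, seed = 41)
  expect_s3_class(sw, "diameter_sweep")
  expect_equal(sw$table$diameter_mm, seq(0.30, 0.50, by = 0.05))
  expect_equal(nrow(sw$table), 5)
  # blood is the strongest absorber: wider artery, less detected light
  drop <- sw$table$fraction[1] - sw$table$fraction[5]
  se <- sqrt(sw$table$se[1]^2 + sw$table$se[5]^2)
  expect_gt(drop, -3 * se)
  expect_gt(drop, 0)
  fit <- fit_signal_vs_diameter(sw)
  expect_lt(fit$slope, 0)
})

test_that("an invisible artery yields zero slope within Monte Carlo error", {
  fx <- make_fixture("invisible_artery", depth = 3.7)
  sw <- sweep_diameters(3.7, diameters = c(0.3, 0.4, 0.5), photons = 2e4,
                        seed = 19, method = "direct", phantom = fx$phantom)
  fit <- fit_signal_vs_diameter(sw)
  expect_lt(abs(fit$slope), 3 * max(fit$slope_se, 1e-12))
})

test_that("common random numbers shrink the fitted slope uncertainty", {
  # replicate two-diameter sweeps at a deep artery, where most detected
  # packets never touch the lumen: with shared substreams their
  # contributions cancel exactly in the slope, so the replicate-to-
  # replicate spread of the slope must drop well below independent seeds
  ds <- c(0.3, 0.5)
  slope_of <- function(seed, common) {
    sw <- sweep_diameters(6.8, diameters = ds, photons = 1e4, seed = seed,
                          method = "direct", common_seed = common)
    fit_signal_vs_diameter(sw)$slope
  }
  seeds <- 61:66
  sd_crn <- sd(vapply(seeds, slope_of, numeric(1), common = TRUE))
  sd_ind <- sd(vapply(seeds, slope_of, numeric(1), common = FALSE))
  expect_lt(sd_crn, sd_ind)
})

test_that("relative errors against measurement follow the definition", {
  expect_equal(compare_to_measurement(0.23, 0.26), 100 * 0.03 / 0.26,
               tolerance = 1e-12)
  expect_equal(compare_to_measurement(0.1, 0.1), 0)
  expect_equal(compare_to_measurement(0.08, 0.10), 20)
  expect_error(compare_to_measurement(c(1, 2), 1), "length")
  expect_error(compare_to_measurement(0.1, 0), "positive")
})

test_that("a single-depth profile reports that depth as the argmax", {
  pr <- depth_profile(depths = 3.7, photons = 2e4, seed = 2)
  expect_equal(nrow(pr$table), 1)
  expect_equal(pr$argmax_depth_mm, 3.7)
  expect_named(pr$table, c("depth_mm", "amplitude_ppm", "amplitude_se_ppm",
                           "slope", "intercept", "r2", "n_photons", "seed"))
})

test_that("amplitude vanishes as blood approaches the host material", {
  # pMC lets the same recorded paths be reweighted for any contrast
  ph <- build_default_phantom(2.5, 0.5)
  base <- run_simulation(ph, options = tiny_options(n = 5e4, seed = 31,
                                                    record = "cylinders"),
                         record_cylinders = list(axes_z = 2.5,
                                                 radii = c(0.15, 0.2, 0.25)))
  amp_for_blood <- function(mu_a, mu_s_prime) {
    ph$materials$blood <- optical_properties(mu_a = mu_a,
                                             mu_s_prime = mu_s_prime,
                                             g = 0.95)
    sw <- sweep_diameters(2.5, diameters = c(0.3, 0.4, 0.5), photons = 5e4,
                          seed = 31, phantom = ph, baseline = base)
    pulsation_amplitude(fit_signal_vs_diameter(sw))$amplitude_ppm
  }
  skull <- ph$materials$skull
  a_full <- amp_for_blood(1.1, 1.9)
  a_half <- amp_for_blood((1.1 + skull$mu_a) / 2, (1.9 + skull$mu_s_prime) / 2)
  a_zero <- amp_for_blood(skull$mu_a, skull$mu_s_prime)
  expect_equal(a_zero, 0, tolerance = 1e-12)
  expect_lt(abs(a_half), abs(a_full))
  expect_gt(a_full, 0)
})
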