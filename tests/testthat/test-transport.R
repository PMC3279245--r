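test_that("identical seeds give bit-identical tallies", {
  ph <- build_default_phantom(3.7, 0.4)
  r1 <- run_simulation(ph, options = tiny_options(n = 2e4, seed = 9))
  r2 <- run_simulation(ph, options = tiny_options(n = 2e4, seed = 9))
  expect_identical(r1$detected, r2$detected)
  expect_identical(r1$absorbed, r2$absorbed)
  expect_identical(r1$escaped, r2$escaped)
  expect_identical(r1$n_detected, r2$n_detected)
})

test_that("per-packet substreams make runs batch-partition invariant", {
  ph <- build_default_phantom(3.7, 0.4)
  whole <- run_simulation(ph, options = tiny_options(n = 2e4, seed = 5))
  half1 <- run_simulation(ph, options = tiny_options(n = 1e4, seed = 5))
  half2 <- run_simulation(ph, options = tiny_options(n = 1e4, seed = 5,
                                                     packet_offset = 1e4))
  # identical per-packet contributions; only the accumulation order differs
  expect_equal(half1$detected + half2$detected, whole$detected,
               tolerance = 1e-9)
  expect_equal(half1$absorbed + half2$absorbed, whole$absorbed,
               tolerance = 1e-9)
  expect_identical(half1$n_detected + half2$n_detected, whole$n_detected)
})

test_that("weight is conserved to 1e-6 relative for every seed", {
  ph <- build_default_phantom(2.5, 0.4)
  for (seed in c(1, 17, 404)) {
    r <- run_simulation(ph, options = tiny_options(n = 2e4, seed = seed))
    resid <- (r$injected - r$detected - r$absorbed - r$escaped) / r$injected
    expect_lt(abs(resid), 1e-6)
  }
})

test_that("a purely absorbing slab transmits exp(-mu_a d)", {
  fx <- make_fixture("beer_lambert_slab")  # optical depth 1
  r <- run_simulation(fx$phantom, fx$source, fx$detector,
                      transport_options(n_photons = 1e5, seed = 21))
  transmitted <- r$escaped_bottom / r$injected
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / r$injected)
  expect_lt(abs(transmitted - p), 3 * se)
})

test_that("an absorbing-only medium returns no light to the surface", {
  fx <- make_fixture("beer_lambert_slab", mu_a = 0.5, thickness_mm = 20)
  r <- run_simulation(fx$phantom, fx$source, fx$detector,
                      transport_options(n_photons = 1e4, seed = 2))
  expect_identical(r$detected, 0)
})

test_that("a conservative scattering half-space re-emits nearly all weight", {
  fx <- make_fixture("conservative_halfspace")
  r <- run_simulation(fx$phantom, fx$source, fx$detector,
                      transport_options(n_photons = 500, seed = 4,
                                        max_steps = 3e5))
  reemitted <- (r$detected + r$escaped - r$escaped_bottom) / r$injected
  expect_gt(reemitted, 0.97)
  # no absorption anywhere
  expect_equal(r$absorbed, 0)
})

test_that("an optically invisible artery leaves detection unchanged", {
  fx <- make_fixture("invisible_artery", depth = 3.7)
  o <- function(seed) tiny_options(n = 3e4, seed = seed)
  r1 <- run_simulation(set_artery_diameter(fx$phantom, 0.3),
                       options = o(31))
  r2 <- run_simulation(set_artery_diameter(fx$phantom, 0.5),
                       options = o(31))
  se <- sqrt(r1$detected_fraction_se^2 + r2$detected_fraction_se^2)
  expect_lt(abs(r1$detected_fraction - r2$detected_fraction), 3 * se)
})

test_that("voxelized transport agrees with implicit transport", {
  ph <- build_default_phantom(2.5, 0.4)
  ri <- run_simulation(ph, options = tiny_options(n = 6e4, seed = 13,
                                                  geometry = "implicit"))
  rv <- run_simulation(ph, options = tiny_options(n = 6e4, seed = 13,
                                                  geometry = "voxelized"))
  se <- sqrt(ri$detected_fraction_se^2 + rv$detected_fraction_se^2)
  expect_lt(abs(ri$detected_fraction - rv$detected_fraction), 4 * se)
})

test_that("the Fresnel boundary model conserves weight and detects light", {
  ph <- build_default_phantom(3.7, 0.4)
  r <- run_simulation(ph, options = tiny_options(n = 2e4, seed = 6,
                                                 boundary = "fresnel"))
  resid <- (r$injected - r$detected - r$absorbed - r$escaped) / r$injected
  expect_lt(abs(resid), 1e-6)
  expect_gt(r$n_detected, 0)
})

test_that("a detector overlapping the source warns but still runs", {
  ph <- build_default_phantom(3.7, 0.4)
  det <- detector_spec(cx = 0.5, cy = 0)
  expect_warning(
    r <- run_simulation(ph, detector = det, options = tiny_options(n = 5e3)),
    "overlaps")
  expect_gt(r$detected_fraction, 0)
})
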