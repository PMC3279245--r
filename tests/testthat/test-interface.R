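test_that("the shipped config resolves to the published phantom in mm units", {
  path <- system.file("extdata", "phantom_default.yaml", package = "pulseoxmc")
  ph <- load_phantom_config(path)
  expect_equal(ph$materials$skull$mu_a, 0.015)   # 0.15 cm^-1 -> /mm
  expect_equal(ph$materials$skin$mu_s_prime, 1.6)
  expect_equal(ph$artery$depth_mm, 3.7)
  expect_equal(ph$separation_mm, 11)
  expect_equal(ph$voxel_mm, 0.05)
})

test_that("config validation names the offending key", {
  writeln <- function(...) {
    f <- tempfile(fileext = ".yaml"); writeLines(c(...), f); f
  }
  base <- c("materials:",
            "  a: {mu_a_per_cm: 1, mu_s_prime_per_cm: 10}",
            "layers:", "  - {name: a}")
  # defaults fill in: g falls back to 0.95
  ph <- load_phantom_config(writeln(base))
  expect_equal(ph$materials$a$g, 0.95)
  expect_error(load_phantom_config(writeln(base, "bogus_key: 1")),
               "bogus_key")
  expect_error(load_phantom_config(writeln(
    c("materials:", "  a: {mu_a_per_cm: 1, mu_s_prime_per_cm: 10}",
      "layers:", "  - {name: a, thickness_mm: -2}", "  - {name: a}"))),
    "thickness")
  expect_error(load_phantom_config(writeln(
    c("materials:", "  a: {mu_a: 1, mu_s_prime_per_cm: 10}",
      "layers:", "  - {name: a}"))),
    "unit")
  expect_error(load_phantom_config(writeln(
    c("materials:", "  a: {mu_a_per_cm: 1, mu_s_prime_per_cm: 10}",
      "layers:", "  - {name: b}"))),
    "missing")
})

test_that("the JSON echo carries the fully resolved model", {
  ph <- build_default_phantom(2.5, 0.4)
  echo <- jsonlite::fromJSON(echo_config(ph))
  expect_equal(echo$materials$blood$mu_a_per_mm, 1.1)
  expect_equal(echo$artery$depth_mm, 2.5)
  expect_equal(echo$separation_mm, 11)
})

test_that("fixture scenarios resolve to runnable configurations", {
  bl <- make_fixture("beer_lambert_slab")
  expect_equal(bl$reference$transmittance, exp(-1))
  expect_equal(bl$phantom$materials$absorber$mu_s, 0)
  inv <- make_fixture("invisible_artery", depth = 3.7)
  expect_identical(inv$phantom$materials$blood, inv$phantom$materials$skull)
  pd <- make_fixture("paper_default", depth = 2.5)
  expect_equal(pd$phantom$artery$depth_mm, 2.5)
  expect_equal(pd$phantom$artery$diameter_mm, 0.4)
  expect_equal(pd$phantom$separation_mm, 11)
  expect_error(make_fixture("no_such_scenario"))
})

test_that("a result file reproduces itself from its embedded manifest", {
  ph <- build_default_phantom(3.7, 0.4)
  res <- run_simulation(ph, options = tiny_options(n = 5e3, seed = 77))
  path <- tempfile(fileext = ".json")
  write_result(res, path)
  again <- rerun_from_manifest(path)
  expect_identical(again$detected, res$detected)
  expect_identical(again$absorbed, res$absorbed)
  expect_identical(again$n_detected, res$n_detected)
})

test_that("profiles serialise with the documented columns", {
  pr <- depth_profile(depths = c(2.5, 3.7), photons = 2e4, seed = 12)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(pr, path)
  tab <- read.csv(path)
  expect_named(tab, c("depth_mm", "amplitude_ppm", "amplitude_se_ppm",
                      "slope", "intercept", "r2", "n_photons", "seed"))
  expect_equal(tab$depth_mm, c(2.5, 3.7))
})
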