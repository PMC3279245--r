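test_that("optical properties recover the reduced scattering coefficient exactly", {
  op <- optical_properties(mu_a = 0.015, mu_s_prime = 1.8, g = 0.95)
  expect_equal(op$mu_s, 36)
  expect_equal(op$mu_s * (1 - op$g), op$mu_s_prime)
  op2 <- optical_properties(mu_a = 0.1, mu_s = 20, g = 0.9)
  expect_equal(op2$mu_s_prime, 2)
  expect_error(optical_properties(mu_a = -1, mu_s = 1, g = 0.5))
  expect_error(optical_properties(mu_a = 0.1, mu_s = 1, g = 1))
  expect_error(optical_properties(mu_a = 0.1, mu_s = 20, mu_s_prime = 5, g = 0.9),
               "inconsistent")
})

test_that("the default phantom carries the published coefficients in mm^-1", {
  ph <- build_default_phantom(3.7, 0.4)
  expect_equal(ph$materials$skull$mu_s,
               ph$materials$skull$mu_s_prime / (1 - ph$materials$skull$g))
  expect_equal(ph$materials$skull$mu_s, 36)
  expect_equal(ph$materials$skin$mu_a, 0.037)
  expect_equal(ph$materials$brain$mu_a, 0.04)
  expect_equal(ph$materials$blood$mu_a, 1.1)
  expect_equal(ph$materials$blood$mu_s_prime, 1.9)
  expect_equal(ph$layers$boundaries_mm, c(1.5, 6.5))
  # the shallowest artery sits entirely within the 1.5 mm skin layer
  ph12 <- build_default_phantom(1.2, 0.4)
  expect_gte(ph12$artery$depth_mm - ph12$artery$diameter_mm / 2, 0)
  expect_lte(ph12$artery$depth_mm + ph12$artery$diameter_mm / 2, 1.5)
  # protrusion above the surface is rejected
  expect_error(build_default_phantom(0.1, 0.4), "protrudes")
})

test_that("material_at resolves layers and the artery lumen", {
  ph <- build_default_phantom(3.7, 0.4)
  expect_identical(material_at(ph, 0, 0, 0.5), "skin")
  expect_identical(material_at(ph, 5.5, 0, 3.7), "blood")  # on the axis
  expect_identical(material_at(ph, 0, 0, 7.0), "brain")    # below 1.5 + 5.0
  expect_identical(material_at(ph, 0, 0, 3.7), "skull")    # far from artery
  # out of domain signals an escape, not a material
  expect_true(is.na(material_at(ph, 0, 0, -0.1)))
  expect_true(is.na(material_at(ph, 0, 100, 3)))
  # deterministic and vectorised
  expect_identical(material_at(ph, c(0, 5.5), 0, c(0.5, 3.7)),
                   c("skin", "blood"))
})

test_that("material_at is piecewise constant away from boundaries", {
  ph <- build_default_phantom(3.7, 0.4)
  set.seed(42)
  pts <- data.frame(x = runif(200, 0, 11), y = runif(200, -5, 5),
                    z = runif(200, 0.01, 10))
  base <- material_at(ph, pts$x, pts$y, pts$z)
  # distance to nearest boundary: layer planes and the cylinder surface
  d_layer <- pmin(abs(pts$z - 1.5), abs(pts$z - 6.5), pts$z)
  d_cyl <- abs(sqrt((pts$x - 5.5)^2 + (pts$z - 3.7)^2) - 0.2)
  h <- pmin(d_layer, d_cyl) / 2.5
  for (dz in c(-1, 1)) {
    moved <- material_at(ph, pts$x + dz * h / 2, pts$y, pts$z + dz * h / 2)
    expect_identical(moved, base)
  }
})

test_that("Monte Carlo integration of the lumen indicator recovers pi r^2 L", {
  ph <- build_default_phantom(3.7, 0.4)
  set.seed(7)
  n <- 2e5
  # box of 1 x 10 x 1 mm around the artery axis
  x <- runif(n, 5.0, 6.0); y <- runif(n, -5, 5); z <- runif(n, 3.2, 4.2)
  inside <- material_at(ph, x, y, z) == "blood"
  vol_box <- 1 * 10 * 1
  est <- mean(inside) * vol_box
  truth <- pi * 0.2^2 * 10
  se <- sd(inside) * vol_box / sqrt(n)
  expect_lt(abs(est - truth), 3 * se)
})

test_that("voxelized and implicit modes agree except near boundaries", {
  ph <- build_default_phantom(3.7, 0.4)
  set.seed(11)
  n <- 2e4
  x <- runif(n, 4.5, 6.5); y <- runif(n, -1, 1); z <- runif(n, 2.7, 4.7)
  frac_mismatch <- function(voxel) {
    ph$voxel_mm <- voxel
    mean(material_at(ph, x, y, z, "implicit") !=
           material_at(ph, x, y, z, "voxelized"))
  }
  f_coarse <- frac_mismatch(0.4)
  f_default <- frac_mismatch(0.05)
  f_fine <- frac_mismatch(0.01)
  expect_lt(f_default, f_coarse)
  expect_lt(f_fine, f_default)
  expect_lt(f_default, 0.05)
})

test_that("set_artery_diameter dilates the lumen and nothing else", {
  ph <- build_default_phantom(3.7, 0.4)
  expect_identical(set_artery_diameter(set_artery_diameter(ph, 0.4), 0.4), ph)
  # a point 0.205 mm off-axis flips to blood under 4% dilation
  p <- c(x = 5.5 + 0.205, y = 0, z = 3.7)
  expect_identical(material_at(ph, p["x"], p["y"], p["z"]), "skull")
  dil <- set_artery_diameter(ph, 0.416)
  expect_identical(material_at(dil, p["x"], p["y"], p["z"]), "blood")
  expect_identical(dil$layers, ph$layers)
  expect_identical(dil$materials, ph$materials)
  # the published sweep yields five distinct models
  sweep <- lapply(seq(0.30, 0.50, by = 0.05), set_artery_diameter,
                  phantom = ph)
  expect_length(unique(vapply(sweep, function(p) p$artery$diameter_mm,
                              numeric(1))), 5)
  expect_error(set_artery_diameter(build_default_phantom(0.21, 0.4), 0.5),
               "protrudes")
})
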