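test_that("scale_scattering follows the power law and its identities", {
  # identity at the reference wavelength, for any exponent
  for (b in c(0, 0.5, 1.6)) expect_equal(scale_scattering(1.57, 633, 633, b), 1.57)
  # b = 0 removes the wavelength dependence
  expect_equal(scale_scattering(1.57, 633, 473, 0), 1.57)
  # hand arithmetic: 1.57 * (633/473)^1
  expect_equal(scale_scattering(1.57, 633, 473, 1), 1.57 * 633 / 473,
               tolerance = 1e-12)
  expect_equal(round(scale_scattering(1.57, 633, 473, 1), 3), 2.101)
  # strictly decreasing in wavelength for b > 0
  lam <- seq(450, 700, by = 10)
  expect_true(all(diff(scale_scattering(2, 633, lam, 1.2)) < 0))
  expect_error(scale_scattering(1.57, -633, 473, 1), "positive")
  expect_error(scale_scattering(-1, 633, 473, 1), ">= 0")
})

test_that("scale_scattering is multiplicative across wavelength hops", {
  set.seed(101)
  for (i in 1:20) {
    m <- runif(1, 0.5, 5); b <- runif(1, 0, 3)
    l0 <- runif(1, 450, 700); l1 <- runif(1, 450, 700); l2 <- runif(1, 450, 700)
    expect_equal(scale_scattering(scale_scattering(m, l0, l1, b), l1, l2, b),
                 scale_scattering(m, l0, l2, b), tolerance = 1e-12)
  }
})

test_that("blood_absorption matches hand interpolation of the packaged table", {
  tab <- hb_extinction()
  expect_true(all(diff(tab$wavelength_nm) > 0))
  expect_true(min(tab$wavelength_nm) <= 450 && max(tab$wavelength_nm) >= 700)
  expect_true(all(tab$mua_oxy_mm >= 0) && all(tab$mua_deoxy_mm >= 0))

  # no blood, no blood absorption
  expect_equal(blood_absorption(0, 0.5, 500, 0.07), 0.07)

  # hand linear interpolation at 473 nm (between the 470 and 480 grid points)
  i <- match(470, tab$wavelength_nm)
  f <- (473 - 470) / 10
  oxy473 <- (1 - f) * tab$mua_oxy_mm[i] + f * tab$mua_oxy_mm[i + 1]
  deoxy473 <- (1 - f) * tab$mua_deoxy_mm[i] + f * tab$mua_deoxy_mm[i + 1]
  expect_equal(blood_absorption(0.028, 0.62, 473, 0.05),
               0.05 + 0.028 * (0.62 * oxy473 + 0.38 * deoxy473),
               tolerance = 1e-12)

  # S = 1 vs S = 0 differ by B * (oxy - deoxy)
  expect_equal(blood_absorption(0.028, 1, 473, 0) -
                 blood_absorption(0.028, 0, 473, 0),
               0.028 * (oxy473 - deoxy473), tolerance = 1e-12)

  # exact at grid points
  expect_equal(blood_absorption(1, 1, 540, 0), tab$mua_oxy_mm[tab$wavelength_nm == 540])

  # affine-increasing in B
  b_grid <- seq(0, 1, by = 0.1)
  vals <- vapply(b_grid, blood_absorption, numeric(1), S = 0.62,
                 lambda_nm = 473, mua_baseline = 0.02)
  expect_true(all(diff(vals) > 0))
  expect_equal(max(abs(diff(vals, differences = 2))), 0, tolerance = 1e-12)

  expect_error(blood_absorption(0.028, 0.62, 430, 0.05), "range")
  expect_error(blood_absorption(1.2, 0.62, 473, 0.05), "\\[0, 1\\]")
})

test_that("similarity relation converts reduced to full scattering", {
  expect_equal(reduced_to_full(1.57, 0), 1.57)
  expect_equal(reduced_to_full(1.57, 0.9), 15.7)
  expect_equal(reduced_to_full(3.52, 0.9), 35.2)
  expect_error(reduced_to_full(1.57, 1), "g must")
  expect_error(reduced_to_full(-1, 0.5), ">= 0")
})

test_that("effective_mus is exactly direction-independent for equal axes", {
  set.seed(7)
  u <- random_units(1e4)
  for (mode in c("quadratic", "abs_normalized")) {
    vals <- apply(u, 1, function(v) effective_mus(c(15.7, 15.7, 15.7), v,
                                                  mode = mode))
    expect_equal(max(vals) - min(vals), 0)  # exact, not approximate
    expect_equal(vals[1], 15.7)
  }
})

test_that("effective_mus respects bounds and axis selection", {
  expect_equal(effective_mus(c(35.2, 35.2, 15.7), c(0, 0, 1)), 15.7)
  expect_equal(effective_mus(c(35.2, 35.2, 15.7),
                             c(0, sqrt(0.5), sqrt(0.5))), 25.45)
  set.seed(8)
  u <- random_units(500)
  for (mode in c("quadratic", "abs_normalized")) {
    for (i in 1:50) {
      m <- runif(3, 0, 40)
      v <- effective_mus(m, u[i, ], mode = mode)
      expect_gte(v, min(m) - 1e-12)
      expect_lte(v, max(m) + 1e-12)
    }
  }
  expect_error(effective_mus(c(1, 2, 3), c(1, 1, 0)), "unit vector")
})

test_that("build_property_table maps fiber-resolved scattering onto axes", {
  # macaque white matter at the reference wavelength: mus_z = 1.58/0.1,
  # mus_x = mus_y = 3.59/0.1
  wm <- tissue_class("wm", 1L, 1.58, 3.59, g = 0.9, mua_baseline = 0.05,
                     blood_volume_fraction = 0, fiber_axis = "z")
  tab <- build_property_table(list(wm), 633)
  expect_equal(tab$mus_z, 15.8)
  expect_equal(tab$mus_x, 35.9)
  expect_equal(tab$mus_y, 35.9)
  expect_equal(tab$mua, 0.05)  # identity configuration: B = 0, lambda = ref

  # isotropic gray matter: all axes equal to mean(long, rad) / (1 - g)
  gm <- tissue_class("gm", 2L, 2.67, 2.90, g = 0.9, mua_baseline = 0.05,
                     blood_volume_fraction = 0, fiber_axis = "isotropic")
  tab2 <- build_property_table(list(gm), 633)
  expect_equal(tab2$mus_x, 2.785 / 0.1)
  expect_equal(tab2$mus_x, tab2$mus_y)
  expect_equal(tab2$mus_x, tab2$mus_z)

  # fibers along x instead
  wmx <- tissue_class("wm", 1L, 1.58, 3.59, g = 0.9, fiber_axis = "x",
                      blood_volume_fraction = 0)
  expect_equal(build_property_table(list(wmx), 633)$mus_x, 15.8)

  expect_error(build_property_table(list(wm, wm), 633), "distinct")
  bad <- tissue_class("wm", 1L, 1.58, 3.59, mua_baseline = 0,
                      blood_volume_fraction = 0)
  expect_error(build_property_table(list(bad), 633), "mua > 0")
})

test_that("packaged presets carry the measured coefficients verbatim", {
  p <- tissue_preset("macaque_fixed")
  expect_equal(p[[1]]$mus_prime_long_ref, 1.58)
  expect_equal(p[[1]]$mus_prime_rad_ref, 3.59)
  expect_equal(p[[2]]$mus_prime_long_ref, 2.67)
  expect_equal(p[[2]]$mus_prime_rad_ref, 2.90)
  expect_identical(p[[2]]$fiber_axis, "isotropic")
  h <- tissue_preset("human_fresh", blood_volume_fraction = 0)
  expect_equal(h[[1]]$mus_prime_long_ref, 1.56)
  expect_equal(h[[1]]$mus_prime_rad_ref, 3.51)
  expect_equal(h[[1]]$blood_volume_fraction, 0)
})

test_that("tissue tables round-trip through JSON", {
  tissues <- tissue_preset("macaque_fixed")
  path <- tempfile(fileext = ".json")
  write_tissue_table(tissues, path)
  back <- read_tissue_table(path)
  expect_equal(back, tissues, ignore_attr = TRUE)
})
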