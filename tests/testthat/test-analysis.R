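# small synthetic fluence_result for unit checks
fake_result <- function(fluence, spec, power = 10) {
  src <- source_spec(c(spec$nx * spec$dx / 2, 0, spec$nz * spec$dz / 2),
                     c(0, 1, 0), power = power)
  structure(list(fluence = fluence, spec = spec, source = src,
                 n_photons = 1L, seed = 1L, wavelength = 473),
            class = "fluence_result")
}

test_that("intensity maps are linear in delivered power", {
  spec <- voxel_spec(5, 5, 5, 0.1)
  f <- array(runif(125), c(5, 5, 5))
  res <- fake_result(f, spec)
  expect_equal(intensity_map(res, 0), f * 0)
  expect_equal(intensity_map(res, 20), 2 * intensity_map(res, 10))
  # F = 0.1 mm^-2 W^-1 at 10 mW is exactly the 1 mW/mm^2 threshold
  res$fluence[1] <- 0.1
  expect_equal(intensity_map(res, 10)[1], 1.0)
})

test_that("activation masks threshold tissue voxels and nest monotonically", {
  spec <- voxel_spec(6, 6, 6, 0.1)
  vol <- homogeneous_block(spec, 1L)
  inten <- array(runif(216, 0, 3), c(6, 6, 6))
  m1 <- activation_mask(inten, vol, 1)
  m2 <- activation_mask(inten, vol, 2)
  expect_true(all(m2 <= m1))                      # subset under larger threshold
  expect_false(any(activation_mask(array(0.5, c(6, 6, 6)), vol, 1)))
  # threshold -> 0+ activates all tissue with nonzero intensity
  m0 <- activation_mask(inten, vol, 1e-12)
  expect_equal(sum(m0), sum(inten > 0))
  # background voxels never activate
  vol0 <- homogeneous_block(spec, 0L)
  expect_false(any(activation_mask(inten, vol0, 1)))
})

test_that("activation depth is measured from the dorsal tissue surface", {
  spec <- voxel_spec(5, 40, 5, 0.05)
  vol <- homogeneous_block(spec, 1L)
  mask <- array(FALSE, c(5, 40, 5))
  mask[3, 1, 3] <- TRUE                  # single voxel at the surface
  expect_equal(activation_depth_dv(mask, vol), 0.05 / 2)

  # half-ball of radius 1.2 mm below the surface
  spec2 <- voxel_spec(60, 30, 60, 0.05)
  vol2 <- homogeneous_block(spec2, 1L)
  cx <- (seq_len(60) - 0.5) * 0.05; cy <- (seq_len(30) - 0.5) * 0.05
  r2 <- outer(outer((cx - 1.5)^2, cy^2, "+"), (cx - 1.5)^2, "+")
  ball <- r2 <= 1.2^2
  expect_equal(activation_depth_dv(ball, vol2), 1.2, tolerance = 0.05)
  expect_equal(activation_depth_dv(array(FALSE, c(60, 30, 60)), vol2), 0)

  # surface offset: tissue starting 0.2 mm down shifts the reference
  slab <- layered_slab(spec2, list(c(0.2, 0), c(1.3, 1)))
  expect_equal(activation_depth_dv(ball, slab),
               activation_depth_dv(ball, vol2) - 0.2, tolerance = 0.05)
})

test_that("longitudinal extent measures |z - z_fiber| of the mask", {
  spec <- voxel_spec(10, 10, 100, 0.05)
  vol <- homogeneous_block(spec, 1L)
  src <- source_spec(c(0.25, 0, 2.5), c(0, 1, 0))
  mask <- array(FALSE, c(10, 10, 100))
  mask[, , 50] <- TRUE                   # single plane at the midline
  expect_lte(activation_extent_long(mask, vol, src), 0.05 / 2)
  zc <- (seq_len(100) - 0.5) * 0.05
  mask2 <- array(rep(abs(zc - 2.5) <= 1.6, each = 100), c(10, 10, 100))
  expect_equal(activation_extent_long(mask2, vol, src), 1.6,
               tolerance = 0.05)
})

test_that("a synthetic inverse-square field activates out to sqrt(10) mm", {
  # I(r) = 10 / r^2 mW/mm^2 around the fiber tip; threshold 1 activates
  # r <= sqrt(10), verified against a brute-force voxel count
  spec <- voxel_spec(80, 40, 80, 0.1)
  vol <- homogeneous_block(spec, 1L)
  cx <- (seq_len(80) - 0.5) * 0.1; cy <- (seq_len(40) - 0.5) * 0.1
  r2 <- outer(outer((cx - 4)^2, cy^2, "+"), (cx - 4)^2, "+")
  inten <- 10 / pmax(r2, 1e-6)
  mask <- activation_mask(inten, vol, 1)
  rad <- sqrt(max(r2[mask]))
  expect_equal(rad, sqrt(10), tolerance = 0.1)
  expect_equal(sum(mask), sum(r2 <= 10))
})

test_that("metrics are invariant under whole-voxel scene translation", {
  spec <- voxel_spec(40, 20, 40, 0.1)
  vol <- homogeneous_block(spec, 1L)
  src <- source_spec(c(1, 0, 1), c(0, 1, 0))
  inten <- array(0, c(40, 20, 40))
  inten[6:14, 1:8, 6:14] <- 5
  m <- activation_mask(inten, vol, 1)
  shift <- 7L
  inten2 <- array(0, c(40, 20, 40))
  inten2[(6:14) + shift, 1:8, (6:14) + shift] <- 5
  src2 <- source_spec(c(1 + 0.7, 0, 1 + 0.7), c(0, 1, 0))
  m2 <- activation_mask(inten2, vol, 1)
  expect_equal(activation_depth_dv(m, vol), activation_depth_dv(m2, vol))
  expect_equal(activation_extent_long(m, vol, src),
               activation_extent_long(m2, vol, src2), tolerance = 0.1)
  expect_equal(extent_ratio(inten, vol, src)$ratio,
               extent_ratio(inten2, vol, src2)$ratio, tolerance = 1e-9)
})

test_that("extent ratio is 1 in isotropic media and inverts on axis swap", {
  spec <- voxel_spec(50, 36, 50, 0.06)
  vol <- homogeneous_block(spec, 1L)
  src <- top_fiber(spec)
  cfg <- run_config(1e5, seed = 17)
  iso <- run_mc(vol, iso_props(2.5, 0.3, g = 0.9), src, cfg)
  er_iso <- extent_ratio(iso$fluence * 10, vol, src, 1)
  expect_equal(er_iso$ratio, 1, tolerance = 0.12)

  aniso <- build_property_table(list(wm_tissue(long = 1.57, rad = 3.52,
                                               mua = 0.3, axis = "z")), 633)
  swapped <- build_property_table(list(wm_tissue(long = 1.57, rad = 3.52,
                                                 mua = 0.3, axis = "x")), 633)
  ra <- extent_ratio(run_mc(vol, aniso, src, cfg)$fluence * 10, vol, src, 1)
  rs <- extent_ratio(run_mc(vol, swapped, src, cfg)$fluence * 10, vol, src, 1)
  expect_gt(ra$ratio, 1)
  expect_lt(rs$ratio, 1)
  expect_equal(ra$ratio, 1 / rs$ratio, tolerance = 0.15)

  expect_error(extent_ratio(iso$fluence * 0, vol, src, 1), "empty")
  src_z <- source_spec(src$tip_position, c(0, 0, 1))
  expect_error(extent_ratio(iso$fluence, vol, src_z, 1), "perpendicular")
})

test_that("activation_metrics assembles a consistent report", {
  spec <- voxel_spec(30, 24, 30, 0.05)
  vol <- homogeneous_block(spec, 1L)
  src <- top_fiber(spec)
  res <- run_mc(vol, iso_props(2.5, 0.4, g = 0.9), src,
                run_config(3e4, seed = 23))
  m <- activation_metrics(res, vol, src, power = 10, threshold = 1)
  mask <- activation_mask(intensity_map(res, 10), vol, 1)
  expect_equal(m$activated_volume, sum(mask) * 0.05^3)
  expect_gt(m$depth_dv, 0)
  expect_true(!is.na(m$extent_ratio))
  path <- tempfile(fileext = ".json")
  write_metrics(m, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$depth_dv_mm, m$depth_dv)
  expect_equal(js$threshold_mw_mm2, 1)
})
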