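test_that("sphere radius round-trips through the volume formula", {
  r <- sphere_radius_mm(26)
  expect_equal(4 / 3 * pi * r^3 / 1000, 26, tolerance = 1e-12)
  expect_equal(r, 18.4, tolerance = 0.01)
})

test_that("truth masks voxelize the nominal volumes closely", {
  ps <- phantom_spec()
  sp <- c(ps$pixel_mm, ps$pixel_mm, ps$slice_mm)
  voxvol <- prod(sp) / 1000
  for (i in seq_along(ps$volumes_ccm)) {
    v <- mask_volume_ccm(truth_mask(ps, i), sp)
    expect_lt(abs(v - ps$volumes_ccm[i]), 13 * voxvol)   # within the surface shell
  }
  # partial-volume rasterization integrates to the analytic volume
  act <- petseg:::rasterize_activity(phantom_spec(background = 0), 0)
  expect_equal(sum(act) * voxvol / 1.2, sum(c(3, 12, 26)), tolerance = 0.005)
})

test_that("the noiseless unfiltered simulation equals the rasterized map", {
  ps <- phantom_spec(fwhm_mm = 0, noise_coef = 0, noise_floor = 0)
  img <- simulate_static(ps)
  expect_identical(img$values, petseg:::rasterize_activity(ps, 0))
})

test_that("Gaussian blurring conserves total activity away from grid edges", {
  ps0 <- phantom_spec(fwhm_mm = 0, noise_coef = 0, noise_floor = 0)
  ps5 <- phantom_spec(fwhm_mm = 5, noise_coef = 0, noise_floor = 0)
  a0 <- simulate_static(ps0)$values
  a5 <- simulate_static(ps5)$values
  expect_equal(sum(a5), sum(a0), tolerance = 1e-3)
  expect_lt(max(a5), max(a0))   # smoothing reduces the peak
})

test_that("simulations are reproducible from spec and seed", {
  ps <- phantom_spec(seed = 13)
  a <- simulate_static(ps)
  b <- simulate_static(ps)
  expect_identical(a$values, b$values)
  c2 <- simulate_static(ps, seed = 14)
  expect_false(identical(a$values, c2$values))
})

test_that("zero amplitude motion reproduces the static acquisition", {
  ps <- phantom_spec(amplitude_mm = 0, seed = 5)
  expect_identical(simulate_motion_blurred(ps)$values, simulate_static(ps)$values)
})

test_that("motion blur stretches the 40% isocontour and never shrinks it", {
  ps <- phantom_spec(noise_coef = 0, noise_floor = 0, seed = 5)
  stat <- simulate_static(ps)
  mov <- simulate_motion_blurred(ps)
  sv <- sphere_center_voxel(ps, 3)
  ms <- threshold_segment(stat, sv)
  mm <- threshold_segment(mov, sv)
  expect_gt(sum(mm), sum(ms))     # smearing enlarges the 40% isocontour
  zs <- range(which(apply(ms, 3, any)))
  zm <- range(which(apply(mm, 3, any)))
  expect_gte(diff(zm), diff(zs))  # apparent z extent never shrinks
})

test_that("motion phase sampling spans the stated sinusoidal excursion", {
  ps <- phantom_spec()
  shifts <- (ps$amplitude_mm / 2) *
    sin(2 * pi * (seq_len(ps$n_phases) - 0.5) / ps$n_phases)
  expect_equal(max(abs(shifts)), ps$amplitude_mm / 2, tolerance = 0.01)
  expect_equal(mean(shifts), 0, tolerance = 1e-12)
  expect_equal(60 / ps$freq_cpm, 5)   # 12 cycles/min -> 5 s period
})

test_that("phantom spec validation rejects impossible geometry", {
  expect_error(phantom_spec(volumes_ccm = c(26, 26),
                            centers_mm = rbind(c(256, 256, 80), c(256, 266, 80))),
               "overlap")
  expect_error(phantom_spec(volumes_ccm = 26,
                            centers_mm = matrix(c(256, 256, 12), 1)),
               "exceeds")
})

test_that("the two-texture phantom provides usable calibration geometry", {
  tx <- simulate_texture_phantom(seed = 2)
  expect_true(all(tx$truth[tx$tumor_cube]))
  expect_false(any(tx$background_box & tx$truth))
  expect_equal(sum(tx$tumor_cube), 27)
  expect_true(tx$truth[tx$center_voxel[1], tx$center_voxel[2], tx$center_voxel[3]])
  # lesion and background intensity ranges are as designed
  expect_gt(mean(tx$image$values[tx$truth]), 1.5)
  expect_lt(mean(tx$image$values[tx$background_box]), 1.0)
})
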