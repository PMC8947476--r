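make_line_image <- function() {
  v <- array(0, c(5, 3, 3))
  v[1:3, 2, 2] <- c(10, 4, 3.9)
  vol_image(v, c(1, 1, 1))
}

test_that("threshold segmentation keeps the seed component at >= 40% of max", {
  img <- make_line_image()
  m <- threshold_segment(img, c(1, 2, 2))
  expect_true(m[1, 2, 2] && m[2, 2, 2])   # 10 and 4 (= 0.40 * 10, inclusive)
  expect_false(m[3, 2, 2])                # 3.9 < 4
  expect_equal(sum(m), 2)

  expect_error(threshold_segment(img, c(5, 1, 1)), "uptake")
})

test_that("threshold segmentation recovers a uniform sphere exactly", {
  ps <- phantom_spec(volumes_ccm = 12, centers_mm = matrix(c(256, 256, 80), 1),
                     fwhm_mm = 0, noise_coef = 0, noise_floor = 0,
                     amplitude_mm = 0)
  img <- simulate_static(ps)
  tm <- truth_mask(ps, 1)
  seg <- threshold_segment(img, sphere_center_voxel(ps, 1))
  # with partial-volume rasterization, voxels with >= 40% inside fraction
  # survive; the voxel-center truth is recovered up to the boundary shell
  expect_true(all(seg[tm & img$values >= 0.4 * max(img$values)]))
  expect_false(any(seg & img$values < 0.4 * max(img$values)))
})

test_that("raising the threshold fraction never increases the volume", {
  ps <- phantom_spec(seed = 3)
  img <- simulate_static(ps)
  sv <- sphere_center_voxel(ps, 3)
  vols <- sapply(c(0.3, 0.4, 0.5, 0.6),
                 function(fr) sum(threshold_segment(img, sv, fr)))
  expect_true(all(diff(vols) <= 0))
})

test_that("threshold segmentation equals the brute-force scan oracle", {
  ps <- phantom_spec(volumes_ccm = 12,
                     centers_mm = matrix(c(40, 40, 40), 1),
                     matrix_size = 20L, n_slices = 16L, seed = 11)
  img <- simulate_static(ps)
  sv <- sphere_center_voxel(ps, 1)
  expect_identical(threshold_segment(img, sv),
                   brute_threshold_segment(img, sv))
})

test_that("directional growth adds one voxel layer, clipped at faces", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  g <- directional_grow(m, "+x")
  expect_equal(sum(g), 2)
  expect_true(g[3, 2, 2])

  edge <- array(FALSE, c(4, 4, 4)); edge[4, 2, 2] <- TRUE
  expect_identical(directional_grow(edge, "+x"), edge)  # clipped

  # L-shaped mask vs per-voxel set-union oracle
  L <- array(FALSE, c(5, 5, 5))
  L[2, 2:4, 2] <- TRUE; L[3:4, 2, 2] <- TRUE
  g2 <- directional_grow(L, "-y")
  oracle <- L
  for (lin in which(L)) {
    co <- arrayInd(lin, dim(L))
    if (co[2] > 1) oracle[co[1], co[2] - 1, co[3]] <- TRUE
  }
  expect_identical(g2, oracle)
  expect_true(all(L[g2 == FALSE] == FALSE))  # never removes voxels
})

test_that("region growing stops immediately when the start cube violates the criterion", {
  img <- rand_image(c(9, 9, 9), seed = 5)
  fs <- feature_spec("local_entropy", threshold = 0.001, accept = "below")
  res <- texture_region_grow(img, c(5, 5, 5), fs)
  expect_true(res$terminated_at_start)
  expect_equal(res$iterations, 0L)
  expect_equal(sum(res$mask), 27)
  expect_equal(res$volume_ccm, 27 * prod(img$spacing) / 1000)
})

test_that("an always-satisfied criterion grows to the whole grid and terminates", {
  img <- rand_image(c(7, 7, 7), seed = 6)
  fs <- feature_spec("local_entropy", threshold = Inf, accept = "below")
  res <- texture_region_grow(img, c(4, 4, 4), fs)
  expect_true(res$converged)
  expect_true(all(res$mask))
})

test_that("growth is monotone, deterministic, and matches the reference scheme", {
  set.seed(21)
  d <- c(32, 32, 32)
  v <- array(rnorm(prod(d), 1, 0.3), d)
  # embed a smoother bright blob so growth has structure to follow
  ax <- ((1:32) - 16.5)^2
  D2 <- outer(outer(ax, ax, `+`), ax, `+`)
  v <- v + 3 * exp(-D2 / 40)
  img <- vol_image(v, c(2, 2, 2))
  fs <- feature_spec("local_entropy", threshold = 7.2, accept = "below",
                     n_levels = 16)
  res <- texture_region_grow(img, c(16, 16, 16), fs)
  ref <- reference_region_grow(img, c(16, 16, 16), fs)

  expect_identical(res$mask, ref$mask)
  expect_equal(res$iterations, ref$iterations)
  expect_equal(nrow(res$trace), nrow(ref$trace))
  expect_equal(res$trace$feature, ref$trace$feature, tolerance = 1e-12)
  expect_identical(res$trace$accepted, ref$trace$accepted)
  expect_identical(res$trace$direction, ref$trace$direction)
  expect_equal(res$trace$volume_ccm, ref$trace$volume_ccm)

  # volume sequence per iteration is non-decreasing
  vols <- tapply(res$trace$volume_ccm, res$trace$iteration, max)
  expect_true(all(diff(c(27 * 0.008, vols)) >= -1e-12))

  # determinism: identical image + seed + spec -> identical mask
  res2 <- texture_region_grow(img, c(16, 16, 16), fs)
  expect_identical(res$mask, res2$mask)
})

test_that("midpoint calibration places the threshold between the example regions", {
  # synthetic feature contrast: two flat blocks with different texture
  set.seed(31)
  v <- array(runif(14 * 7 * 7), c(14, 7, 7))
  v[8:14, , ] <- v[8:14, , ] * 0.01 + 5   # near-constant block
  img <- vol_image(v, c(1, 1, 1))
  a <- array(FALSE, dim(v)); a[2:4, 2:4, 2:4] <- TRUE
  b <- array(FALSE, dim(v)); b[10:12, 2:4, 2:4] <- TRUE
  fs <- feature_spec("local_entropy", n_levels = 16)
  cal <- calibrate_threshold(img, a, b, fs)
  expect_equal(cal$threshold, (cal$feature_tumor + cal$feature_background) / 2)
  expect_equal(cal$accept,
               if (cal$feature_tumor < cal$threshold) "below" else "above")
  expect_equal(cal$spec$threshold, cal$threshold)

  # symmetric synthetic values via direct fabrication of degenerate case
  expect_error(calibrate_threshold(img, a, a, fs), "disjoint")
  tiny <- array(FALSE, dim(v)); tiny[1, 1, 1] <- TRUE
  expect_error(calibrate_threshold(img, tiny, b, fs), "27")
})

test_that("boundary calibration separates inside from spilled regions", {
  tx <- simulate_texture_phantom(seed = 4)
  fs <- feature_spec("long_zone_emphasis", n_levels = 32)
  cal <- calibrate_boundary(tx$image, tx$truth, fs)
  expect_true(cal$threshold > min(cal$feature_tumor, cal$feature_background))
  expect_true(cal$threshold < max(cal$feature_tumor, cal$feature_background))
  expect_equal(cal$threshold, sqrt(cal$feature_tumor * cal$feature_background))
})
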