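test_that("discretization maps intensities to 1..G uniform bins", {
  img <- vol_image(array(7, c(3, 3, 3)), c(1, 1, 1))
  m <- array(TRUE, c(3, 3, 3))
  reg <- discretize(img, m, 16)
  expect_true(all(reg$levels[m] == 1L))  # constant region -> level 1

  v <- array(0, c(4, 1, 1)); v[, 1, 1] <- c(0, 1, 2, 3)
  img2 <- vol_image(v, c(1, 1, 1))
  m2 <- array(TRUE, c(4, 1, 1))
  reg2 <- discretize(img2, m2, 4, edges = 0:4)
  expect_equal(as.integer(reg2$levels[m2]), 1:4)

  # random region vs an independent edge-search binning oracle
  img3 <- rand_image(c(5, 5, 5), seed = 42)
  m3 <- rand_mask(c(5, 5, 5), seed = 43)
  reg3 <- discretize(img3, m3, 64)
  x <- img3$values[m3]
  oracle <- pmin(pmax(findInterval(x, reg3$edges, rightmost.closed = TRUE), 1), 64)
  expect_equal(as.integer(reg3$levels[m3]), as.integer(oracle))
})

test_that("co-occurrence matrix matches trivial cases and is a probability matrix", {
  v <- array(0, c(2, 1, 1)); v[, 1, 1] <- c(0.2, 0.2)
  img <- vol_image(v, c(1, 1, 1))
  m <- array(TRUE, c(2, 1, 1))
  m1 <- cooccurrence(discretize(img, m, 4))
  expect_equal(m1[1, 1], 1.0)  # one pair, both at level 1

  img2 <- vol_image(array(5, c(3, 3, 3)), c(1, 1, 1))
  m2 <- cooccurrence(discretize(img2, array(TRUE, c(3, 3, 3)), 8))
  expect_equal(m2[1, 1], 1.0)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_error(cooccurrence(discretize(img2, single, 8)), "pairs")
})

test_that("co-occurrence and size-zone matrices match brute-force enumeration", {
  for (s in 1:8) {
    img <- rand_image(c(4, 4, 4), seed = 200 + s)
    m <- rand_mask(c(4, 4, 4), seed = 300 + s, p = 0.8)
    reg <- discretize(img, m, 6)
    m1 <- cooccurrence(reg)
    expect_lt(max(abs(m1 - brute_glcm(reg$levels, 6))), 1e-9)
    expect_equal(sum(m1), 1, tolerance = 1e-9)
    expect_equal(unclass(m1), t(unclass(m1)), ignore_attr = TRUE)  # symmetric

    m4 <- size_zone(reg)
    expect_identical(m4$counts, brute_szm(reg$levels, 6))
    # mass conservation: sum_ij M4_ij * j = member count
    expect_equal(sum(sweep(m4$counts, 2, seq_len(ncol(m4$counts)), `*`)), sum(m))
  }
})

test_that("checkerboard co-occurrence equals the exhaustive oracle", {
  v <- array(0, c(3, 3, 3))
  idx <- which(array(TRUE, c(3, 3, 3)), arr.ind = TRUE)
  v[] <- (rowSums(idx) %% 2)
  img <- vol_image(v, c(1, 1, 1))
  m <- array(TRUE, c(3, 3, 3))
  reg <- discretize(img, m, 2)
  expect_lt(max(abs(cooccurrence(reg) - brute_glcm(reg$levels, 2))), 1e-9)
})

test_that("size zones: uniform cube is one zone, distinct levels are singletons", {
  img <- vol_image(array(1, c(3, 3, 3)), c(1, 1, 1))
  m4 <- size_zone(discretize(img, array(TRUE, c(3, 3, 3)), 8))
  expect_equal(m4$counts[1, 27], 1L)
  expect_equal(sum(m4$counts), 1L)

  v <- array(seq_len(8), c(2, 2, 2))  # all-distinct levels after binning
  reg <- discretize(vol_image(v, c(1, 1, 1)), array(TRUE, c(2, 2, 2)), 8,
                    edges = seq(0.5, 8.5, by = 1))
  m4b <- size_zone(reg)
  expect_equal(sum(m4b$counts[, 1]), 8L)  # every zone size 1

  # striped block vs flood-fill oracle
  v2 <- array(rep(c(0, 1), length.out = 32), c(4, 4, 2))
  reg2 <- discretize(vol_image(v2, c(1, 1, 1)), array(TRUE, c(4, 4, 2)), 2)
  expect_identical(size_zone(reg2)$counts, brute_szm(reg2$levels, 2))
})

test_that("kurtosis anchors, errors and invariances", {
  expect_equal(region_kurtosis(c(rep(-1, 8), rep(1, 8))), 1.0)
  expect_error(region_kurtosis(rep(3, 10)), "degenerate")
  expect_error(region_kurtosis(2), "at least 2")

  x <- c(1, 2, 2, 3, 3, 3, 4, 4, 4, 4)
  expect_equal(region_kurtosis(x), brute_kurtosis(x), tolerance = 1e-12)

  set.seed(9)
  y <- rnorm(200)
  expect_gte(region_kurtosis(y), 1)          # Pearson bound
  expect_equal(region_kurtosis(y + 5), region_kurtosis(y))   # shift invariant
  expect_equal(region_kurtosis(3 * y), region_kurtosis(y))   # scale invariant
})

test_that("local entropy anchors and bounds", {
  m1 <- matrix(0, 4, 4); m1[2, 3] <- 0.5; m1[3, 2] <- 0.5
  expect_equal(local_entropy(matrix(c(1, 0, 0, 0), 2, 2)), 0)
  expect_equal(local_entropy(matrix(1 / 16, 4, 4)), 4)

  for (s in 1:5) {
    img <- rand_image(c(4, 4, 4), seed = 400 + s)
    reg <- discretize(img, array(TRUE, c(4, 4, 4)), 8)
    p <- cooccurrence(reg)
    le <- local_entropy(p)
    expect_equal(le, brute_entropy(p), tolerance = 1e-9)
    expect_gte(le, 0)
    expect_lte(le, 2 * log2(8))
  }
})

test_that("long-zone emphasis anchors and lower bound", {
  one_zone <- structure(list(counts = {
    m <- matrix(0L, 4, 27); m[1, 27] <- 1L; m
  }, n_levels = 4L), class = "size_zone_matrix")
  expect_equal(long_zone_emphasis(one_zone), 729)

  all_single <- structure(list(counts = matrix(c(3L, 2L, 0L, 1L), 4, 1),
                               n_levels = 4L), class = "size_zone_matrix")
  expect_equal(long_zone_emphasis(all_single), 1.0)

  mixed <- structure(list(counts = {
    m <- matrix(0L, 2, 4); m[1, 1] <- 2L; m[2, 4] <- 1L; m
  }, n_levels = 2L), class = "size_zone_matrix")
  expect_equal(long_zone_emphasis(mixed), (1 + 1 + 16) / 3)
  expect_equal(long_zone_emphasis(mixed), brute_lze(mixed$counts))
})

test_that("compute_feature dispatches and is shift invariant", {
  v <- array(rep(c(-1, 1), length.out = 16), c(4, 2, 2))
  img <- vol_image(v, c(1, 1, 1))
  m <- array(TRUE, c(4, 2, 2))
  expect_equal(compute_feature(img, m, feature_spec("kurtosis")), 1.0)

  img2 <- vol_image(array(1, c(3, 3, 3)), c(1, 1, 1))
  m2 <- array(TRUE, c(3, 3, 3))
  expect_equal(compute_feature(img2, m2, feature_spec("long_zone_emphasis")), 729)

  # adding a constant leaves all three features unchanged (per-region bins)
  img3 <- rand_image(c(5, 5, 5), seed = 77)
  img4 <- vol_image(img3$values + 10, img3$spacing)
  m3 <- rand_mask(c(5, 5, 5), seed = 78)
  for (fn in c("kurtosis", "local_entropy", "long_zone_emphasis")) {
    fs <- feature_spec(fn, n_levels = 16, binning = "per-region")
    expect_equal(compute_feature(img3, m3, fs), compute_feature(img4, m3, fs),
                 tolerance = 1e-9)
  }
})
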