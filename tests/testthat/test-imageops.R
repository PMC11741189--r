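test_that("subtract_constant clamps at zero and preserves metadata", {
  img <- image_plane(matrix(c(0, 30, 70, 200), 2, 2), pixel_size = 0.5,
                     bit_depth = 16L)
  out <- subtract_constant(img, 50)
  expect_equal(as.vector(out$pixels), c(0, 0, 20, 150))
  expect_equal(out$pixel_size, 0.5)
  expect_equal(out$bit_depth, 16L)
  expect_equal(subtract_constant(img, 0)$pixels, img$pixels)
  expect_equal(subtract_constant(const_plane(50), 50)$pixels,
               matrix(0, 64, 64))
  expect_error(subtract_constant(img, -1), "non-negative")
})

test_that("rolling-ball background subtraction matches a brute-force min/max oracle", {
  # flat image: background equals image, residual is zero
  expect_equal(subtract_rolling_ball(const_plane(123), 50)$pixels,
               matrix(0, 64, 64))
  # isolated narrow spot survives untouched
  m <- matrix(0, 64, 64); m[30:32, 40:42] <- 100
  out <- subtract_rolling_ball(image_plane(m, bit_depth = 32L), 50)
  expect_equal(max(out$pixels), 100)
  expect_equal(sum(out$pixels > 0), 9)
  # ramp + spot: residual agrees with the oracle everywhere, and is
  # spot-only away from borders
  ramp <- outer(seq_len(64), seq_len(64), function(i, j) i + 0.5 * j)
  m2 <- ramp; m2[20:22, 50:52] <- m2[20:22, 50:52] + 80
  img2 <- image_plane(m2, bit_depth = 32L)
  got <- subtract_rolling_ball(img2, 8)$pixels
  want <- pmax(m2 - oracle_opening(m2, 8), 0)
  expect_equal(got, want, tolerance = 1e-12)
  inner <- 10:54
  spot_only <- matrix(0, 64, 64); spot_only[20:22, 50:52] <- 80
  expect_lt(max(abs(got[inner, inner] - spot_only[inner, inner])), 1)
  # output bounded by [0, img]
  expect_true(all(got >= 0 & got <= m2 + 1e-9))
  expect_error(subtract_rolling_ball(img2, 0.5), ">= 1")
})

test_that("gaussian blur conserves mass and matches the impulse closed form", {
  expect_equal(gaussian_blur(const_plane(42), 4)$pixels, matrix(42, 64, 64),
               tolerance = 1e-10)
  imp <- matrix(0, 129, 129); imp[65, 65] <- 1
  b <- gaussian_blur(image_plane(imp, bit_depth = 32L), 4)$pixels
  expect_equal(b[65, 65], 1 / (2 * pi * 16), tolerance = 0.02)
  expect_equal(sum(b), 1, tolerance = 1e-6)
  expect_error(gaussian_blur(const_plane(1), 0), "> 0")
})

test_that("image subtraction keeps sign and returns 32-float planes", {
  a <- image_plane(matrix(c(10, 5), 1, 2), bit_depth = 16L)
  b <- image_plane(matrix(c(3, 8), 1, 2), bit_depth = 16L)
  d <- subtract_images(a, b)
  expect_equal(as.vector(d$pixels), c(7, -3))
  expect_equal(d$bit_depth, 32L)
  expect_equal(subtract_images(a, a)$pixels, matrix(0, 1, 2))
  expect_error(subtract_images(a, const_plane(1)), "shape mismatch")
  # difference of an impulse and its blur has the DoG centre value
  imp <- matrix(0, 129, 129); imp[65, 65] <- 1
  imp <- image_plane(imp, bit_depth = 32L)
  d2 <- subtract_images(imp, gaussian_blur(imp, 4))
  expect_equal(max(d2$pixels), 1 - 1 / (2 * pi * 16), tolerance = 0.001)
})

test_that("thresholding uses the >= convention and is monotone", {
  img <- image_plane(matrix(c(0, 2.9, 3.0, 7), 2, 2), bit_depth = 32L)
  expect_equal(as.vector(apply_threshold(img, 3)$pixels),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(apply_threshold(img, -Inf)$pixels))
  set.seed(11)
  for (i in 1:20) {
    m <- image_plane(matrix(rnorm(400), 20, 20), bit_depth = 32L)
    t1 <- runif(1, -1, 0.5); t2 <- t1 + runif(1, 0, 1)
    m1 <- apply_threshold(m, t1)$pixels
    m2 <- apply_threshold(m, t2)$pixels
    expect_true(all(m1[m2]))  # mask(t2) subset of mask(t1)
  }
})

test_that("particle analysis agrees with the flood-fill oracle and EBImage", {
  empty <- connected_particles(binary_mask(matrix(FALSE, 8, 8)))
  expect_equal(nrow(empty), 0L)
  # diagonal pair: one particle under 8-connectivity, two under 4
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(connected_particles(binary_mask(m), 8L)), 1L)
  expect_equal(nrow(connected_particles(binary_mask(m), 4L)), 2L)
  set.seed(7)
  for (i in 1:40) {
    mk <- matrix(runif(32 * 32) < runif(1, 0.1, 0.55), 32, 32)
    bm <- binary_mask(mk)
    for (conn in c(4L, 8L)) {
      got <- connected_particles(bm, conn)
      want <- oracle_components(mk, conn)
      expect_equal(nrow(got), want$n)
      expect_equal(sort(got$area_px), want$areas)
    }
    # EBImage's labeller as a second, independent 4-connectivity check
    expect_equal(nrow(connected_particles(bm, 4L)),
                 max(EBImage::bwlabel(mk)))
    expect_lte(sum(got$area_px), 32 * 32)
  }
})

test_that("circularity separates discs from lines and areas are calibrated", {
  disc <- connected_particles(binary_mask(disk_mask(32, 8), pixel_size = 0.5))
  expect_equal(nrow(disc), 1L)
  expect_gte(disc$circularity, 0.85)
  expect_lte(disc$circularity, 1.0)
  expect_equal(disc$area_um2, disc$area_px * 0.25)
  expect_equal(disc$equiv_diam_um, 2 * sqrt(disc$area_um2 / pi))
  # centroid of a centred disc is the centre
  expect_equal(c(disc$row, disc$col), c(16.5, 16.5), tolerance = 0.01)
  line <- matrix(FALSE, 30, 30); line[15, 5:24] <- TRUE
  lp <- connected_particles(binary_mask(line))
  expect_lt(lp$circularity, 0.3)
})

test_that("min_area_px filters particles and relabels contiguously", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE                 # area 1
  m[5:6, 5:6] <- TRUE             # area 4
  pt <- connected_particles(binary_mask(m), min_area_px = 2L)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$label, 1L)
  expect_equal(pt$area_px, 4L)
})
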