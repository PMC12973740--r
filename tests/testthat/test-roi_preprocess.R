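test_that("crop_roi extracts exact sub-grids and rejects out-of-bounds ROIs", {
  img <- grey_patch(matrix(0:99 %% 256, 100, 100))
  tl <- crop_roi(img, roi_spec("anterior", "right", c(0, 0), 64))
  expect_equal(dim(tl), c(64, 64))
  expect_equal(bare(tl), unclass(img)[1:64, 1:64])
  br <- crop_roi(img, roi_spec("molar", "right", c(36, 36), 64))
  expect_equal(bare(br), unclass(img)[37:100, 37:100])
  expect_error(crop_roi(img, roi_spec("molar", "right", c(50, 50), 64)),
               "out of bounds.*\\(50, 50\\)")
})

test_that("gaussian background preserves constants and conserves mass", {
  const <- grey_patch(matrix(100, 64, 64))
  expect_equal(gaussian_background(const, 35),
               matrix(100, 64, 64), tolerance = 1e-9)
  imp <- matrix(0, 64, 64); imp[32, 32] <- 200
  bl <- gaussian_background(grey_patch(imp), 5)
  expect_equal(sum(bl), 200, tolerance = 1e-9) # reflective boundary
  expect_error(gaussian_background(const, 0), "sigma")
  # smoothing contracts extremes on a noise patch
  set.seed(1)
  noisy <- grey_patch(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  bln <- gaussian_background(noisy, 35)
  expect_lt(diff(range(bln)), diff(range(noisy)))
})

test_that("subtract_offset does clamped half-away rounding arithmetic", {
  const <- grey_patch(matrix(77, 64, 64))
  out <- subtract_offset(const, gaussian_background(const, 35), 128)
  expect_true(all(out == 128)) # flat background lands on the offset
  px <- grey_patch(matrix(200, 2, 2))
  expect_true(all(subtract_offset(px, matrix(150, 2, 2)) == 178))
  lo <- grey_patch(matrix(0, 2, 2))
  expect_true(all(subtract_offset(lo, matrix(200, 2, 2)) == 0)) # clamp
  hi <- grey_patch(matrix(255, 2, 2))
  expect_true(all(subtract_offset(hi, matrix(0, 2, 2)) == 255)) # clamp
  expect_error(subtract_offset(px, matrix(0, 3, 3)), "dimension")
})

test_that("binarize maps below-threshold black, above white, ties white", {
  g <- grey_patch(matrix(c(127, 128, 129, 0), 2, 2))
  b <- binarize(g, 128)
  expect_identical(as.vector(b), c(FALSE, TRUE, TRUE, FALSE))
  allt <- binarize(grey_patch(matrix(128, 4, 4)), 128)
  expect_true(all(allt))
  expect_equal(attr(allt, "stage"), "thresholded")
})

test_that("morphological opening removes speckle and keeps solid blocks", {
  white <- binary_patch(matrix(TRUE, 16, 16), "thresholded")
  expect_true(all(morpho_clean(white))) # all-white stable under padding
  speck <- matrix(FALSE, 16, 16); speck[8, 8] <- TRUE
  expect_false(any(morpho_clean(binary_patch(speck, "thresholded"))))
  block <- matrix(FALSE, 20, 20); block[6:15, 6:15] <- TRUE
  cleaned <- morpho_clean(binary_patch(block, "thresholded"))
  expect_equal(bare(cleaned), block) # 10x10 solid block preserved
  expect_error(morpho_clean(binary_patch(block, "cleaned")),
               "pipeline-order")
})

test_that("invert complements the cleaned phase and is an involution", {
  m <- matrix(c(TRUE, FALSE), 8, 8)
  inv <- invert(binary_patch(m, "cleaned"))
  expect_equal(sum(inv), 64 - sum(m))
  expect_equal(!bare(inv), m)
  expect_error(invert(binary_patch(m, "thresholded")), "pipeline-order")
})

test_that("skeletonization thins to one pixel, never adds, and is idempotent", {
  bar <- matrix(FALSE, 20, 40); bar[9:11, 5:36] <- TRUE
  sk <- skeletonize(binary_patch(bar, "inverted"))
  expect_true(all(!sk | bar)) # subset of input
  expect_false(has_2x2_block(unclass(sk)))
  # thins to a single 1-px line of the same length, give or take endpoints
  expect_lte(abs(sum(sk) - 32), 4)
  expect_equal(sum(rowSums(unclass(sk)) > 0), 1)
  empty <- binary_patch(matrix(FALSE, 16, 16), "inverted")
  expect_equal(sum(skeletonize(empty)), 0)
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(runif(32 * 32) < 0.5, 32, 32)
    s1 <- skeletonize(binary_patch(m, "inverted"))
    expect_true(all(!s1 | m))
    expect_false(has_2x2_block(unclass(s1)))
    s2 <- skeletonize(binary_patch(unclass(s1), "inverted"))
    expect_identical(unclass(s2), unclass(s1))
  }
})

test_that("full chain flags degenerate constant patches", {
  res <- preprocess(grey_patch(matrix(100, 64, 64)))
  expect_true(attr(res, "degenerate"))
  expect_named(attr(res, "trace"),
               c("thresholded", "cleaned", "inverted", "skeletonized"))
})

test_that("chain output on a degraded phantom matches the clean-pattern chain", {
  # oracle: the same morphology/inversion/thinning applied directly to the
  # known binary pattern, bypassing grey rendering and background removal
  clean <- carpet_patch_64()
  thr_clean <- binary_patch(!unclass(clean), "thresholded")
  sk_clean <- skeletonize(invert(morpho_clean(thr_clean)))
  fd_clean <- fractal_dimension(box_count(sk_clean))$fd
  for (amp in c(0, 60)) {
    g <- make_grey_patch(synth_params(seed = 7,
                                      texture_model = "ifs_fractal",
                                      illumination_amplitude = amp))
    sk <- preprocess(g)
    expect_false(attr(sk, "degenerate"))
    fd <- fractal_dimension(box_count(sk))$fd
    expect_lt(abs(fd - fd_clean), 0.15)
  }
})

test_that("estimated FD is invariant to linear illumination ramps up to 60 grey", {
  for (tm in c("ifs_fractal", "spectral_surface", "strut_lattice")) {
    flat <- analyze_patch(make_grey_patch(synth_params(
      seed = 13, texture_model = tm, illumination_amplitude = 0)))
    ramp <- analyze_patch(make_grey_patch(synth_params(
      seed = 13, texture_model = tm, illumination_amplitude = 60)))
    expect_false(flat$degenerate)
    expect_lt(abs(flat$fd - ramp$fd), 0.15)
  }
})
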