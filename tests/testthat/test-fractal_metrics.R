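test_that("occupied counts match closed forms and the brute-force oracle", {
  full <- matrix(TRUE, 64, 64)
  s <- box_count(full, c(2, 3), n_offsets = 1)
  expect_equal(s$occupied[s$box_size == 2], 1024) # (64/2)^2
  expect_equal(s$occupied[s$box_size == 3], 484)  # ceil(64/3)^2 = 22^2
  single <- matrix(FALSE, 64, 64); single[10, 53] <- TRUE
  s1 <- box_count(single, c(2, 3, 8, 32), n_offsets = 1)
  expect_true(all(s1$occupied == 1))
  # exhaustive oracle on random 16x16 patterns, all sizes and offsets
  set.seed(21)
  for (rep in 1:3) {
    x <- matrix(runif(256) < 0.3, 16, 16)
    if (!any(x)) next
    s <- box_count(x, c(2, 3, 5, 8, 16), n_offsets = 4)
    for (i in seq_len(nrow(s))) {
      oracle <- brute_box_count(x, s$box_size[i],
                                c(s$off_row[i], s$off_col[i]))
      expect_equal(s$occupied[i], oracle$occupied)
      expect_equal(s$mass_mean[i], mean(oracle$masses))
      expect_equal(s$mass_sd[i],
                   sqrt(mean((oracle$masses - mean(oracle$masses))^2)))
    }
  }
})

test_that("per-grid masses always sum to the foreground pixel count", {
  set.seed(5)
  x <- matrix(runif(64 * 64) < 0.4, 64, 64)
  s <- box_count(x, default_box_sizes(), n_offsets = 4)
  expect_equal(s$mass_mean * s$n_boxes, rep(sum(x), nrow(s)))
})

test_that("nested dyadic grids give monotone coverage", {
  set.seed(6)
  x <- matrix(runif(64 * 64) < 0.1, 64, 64)
  s <- box_count(x, c(2, 4, 8, 16, 32), n_offsets = 1)
  expect_true(all(diff(s$occupied[order(s$box_size)]) <= 0))
})

test_that("exact dimensions: filled square 2.0 and straight line 1.0", {
  dyadic <- c(2, 4, 8, 16, 32, 64)
  expect_equal(fd_single_origin(matrix(TRUE, 64, 64), dyadic), 2.0)
  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  expect_equal(fd_single_origin(line, dyadic), 1.0)
})

test_that("Sierpinski carpet dimension is recovered within 0.05", {
  p81 <- make_ifs_fractal(synth_params(texture_model = "ifs_fractal",
                                       size = 81))
  fd <- fd_single_origin(p81, c(3, 9, 27, 81))
  expect_lt(abs(fd - log(8) / log(3)), 0.05)
})

test_that("degenerate and undersized inputs raise the declared signals", {
  expect_error(box_count(matrix(FALSE, 16, 16), c(2, 4)),
               class = "degenerate_input")
  s <- box_count(matrix(TRUE, 16, 16), c(2, 4), n_offsets = 1)
  expect_error(fractal_dimension(s), "insufficient scales")
  expect_error(box_count(matrix(TRUE, 16, 16), c(2, 4, 128)), "box sizes")
})

test_that("lacunarity reproduces hand-enumerated closed forms", {
  dyadic <- c(2, 4, 8, 16, 32, 64)
  full <- box_count(matrix(TRUE, 64, 64), dyadic, n_offsets = 1)
  lf <- lacunarity(full)
  expect_equal(lf$lacunarity, 0) # sigma = 0 at every size
  expect_true(all(lf$lacunarity_by_size$lacunarity == 0))
  single <- matrix(FALSE, 64, 64); single[5, 9] <- TRUE
  ls <- lacunarity(box_count(single, 32, n_offsets = 1))
  expect_equal(ls$lacunarity, 3) # masses {1,0,0,0}: (sd/mu)^2 = 3
  cb <- ((row(matrix(0, 64, 64)) - 1) %/% 2 +
         (col(matrix(0, 64, 64)) - 1) %/% 2) %% 2 == 0
  lc <- lacunarity(box_count(cb, 2, n_offsets = 1))
  expect_equal(lc$lacunarity, 1) # masses alternate 4/0: mu=2, var=4
})

test_that("lacunarity is phase-sensitive", {
  p <- unclass(carpet_patch_64())
  lam <- lacunarity(box_count(p, c(4, 8, 16), n_offsets = 1))$lacunarity
  lam_c <- lacunarity(box_count(!p, c(4, 8, 16), n_offsets = 1))$lacunarity
  expect_false(isTRUE(all.equal(lam, lam_c)))
})

test_that("offset averaging reduces FD variance across translations", {
  set.seed(31)
  base <- matrix(FALSE, 80, 80)
  base[21:60, 21:60] <- unclass(make_ifs_fractal(
    synth_params(texture_model = "ifs_fractal", size = 40)))
  sizes <- c(2, 3, 4, 6, 8, 12, 16)
  fd_at <- function(n_off) {
    vapply(1:50, function(i) {
      dr <- sample(-10:10, 1); dc <- sample(-10:10, 1)
      shifted <- matrix(FALSE, 80, 80)
      shifted[(21 + dr):(60 + dr), (21 + dc):(60 + dc)] <-
        base[21:60, 21:60]
      fractal_dimension(box_count(shifted, sizes, n_offsets = n_off))$fd
    }, numeric(1))
  }
  v1 <- stats::var(fd_at(1))
  set.seed(31)
  v4 <- stats::var(fd_at(4))
  expect_lt(v4, v1)
})

test_that("analyze_patch flags degenerate input and bounds its estimates", {
  expect_true(analyze_patch(grey_patch(matrix(50, 64, 64)))$degenerate)
  for (seed in 1:4) {
    r <- analyze_patch(make_grey_patch(synth_params(
      seed = seed, texture_model = "ifs_fractal", noise_sd = 8)))
    expect_false(r$degenerate)
    expect_gte(r$fd, 0); expect_lte(r$fd, 2)
    expect_gte(r$lacunarity, 0)
    expect_gt(r$fit_r2, 0.9)
  }
})
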