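# Synthetic phantoms and cohorts with known ground truth. These stand in
# for patient radiographs: the estimator can only be validated at desk
# scale against patterns whose box-counting dimension is known in closed
# form and cohorts whose group structure is chosen by construction.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters for synthetic texture generation
#'
#' @param seed integer RNG seed; identical parameters (including seed)
#'   produce bit-identical outputs.
#' @param texture_model one of `"ifs_fractal"` (Sierpinski carpet),
#'   `"spectral_surface"` (thresholded 1/f^beta surface),
#'   `"strut_lattice"`, `"uniform"`, `"single_line"`, `"single_point"`.
#' @param size pixels per side (default 64, the ROI size).
#' @param illumination_amplitude grey levels (0--127) of the additive
#'   low-frequency linear gradient, peak-to-peak.
#' @param noise_sd grey levels of additive Gaussian pixel noise.
#' @param model_params texture-specific parameters: `depth` (IFS recursion
#'   depth, default 4), `beta` (spectral exponent, default 3),
#'   `spacing` and `width` (strut lattice period and strut width in px,
#'   defaults 8/3), `fg`/`bg` (grey levels rendered for the pattern and
#'   background phases, defaults 90/160: the pattern is drawn dark so
#'   that the chain's inversion step makes it the analysed foreground).
#' @return A `synth_params` list.
#' @export
synth_params <- function(seed = 1L,
                         texture_model = c("ifs_fractal", "spectral_surface",
                                           "strut_lattice", "uniform",
                                           "single_line", "single_point"),
                         size = 64L,
                         illumination_amplitude = 0,
                         noise_sd = 0,
                         model_params = list()) {
  texture_model <- match.arg(texture_model)
  if (size < 8) stop("invalid parameter: size must be >= 8")
  if (illumination_amplitude < 0 || illumination_amplitude > 127) {
    stop("invalid parameter: illumination_amplitude must be in [0, 127]")
  }
  if (noise_sd < 0) stop("invalid parameter: noise_sd must be >= 0")
  defaults <- list(depth = 4L, beta = 3, spacing = 8L, width = 3L,
                   fg = 90L, bg = 160L)
  mp <- utils::modifyList(defaults, model_params)
  structure(list(seed = as.integer(seed), texture_model = texture_model,
                 size = as.integer(size),
                 illumination_amplitude = illumination_amplitude,
                 noise_sd = noise_sd, model_params = mp),
            class = "synth_params")
}

# Sierpinski carpet membership on a 3^depth grid: a cell is removed iff
# some base-3 digit pair of its (row, col) index is (1, 1).
carpet_mask <- function(depth) {
  n <- 3L^depth
  idx <- 0:(n - 1L)
  in_carpet_1d <- matrix(TRUE, n, depth)
  r <- idx
  for (d in seq_len(depth)) {
    in_carpet_1d[, d] <- (r %% 3L) == 1L
    r <- r %/% 3L
  }
  # mask[i, j] = TRUE unless digit d of both i and j equals 1 for some d
  mask <- matrix(TRUE, n, n)
  for (d in seq_len(depth)) {
    mid <- in_carpet_1d[, d]
    mask <- mask & !outer(mid, mid, "&")
  }
  mask
}

# Nearest-neighbour rasterization of a square mask onto `size` pixels
nn_rescale <- function(mask, size) {
  n <- nrow(mask)
  if (n == size) return(mask)
  src <- pmin(n, floor((seq_len(size) - 0.5) / size * n) + 1L)
  mask[src, src]
}

spectral_surface <- function(size, beta, seed) {
  with_seed(seed, {
    f_r <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    fr <- matrix(f_r, size, size)
    fc <- t(fr)
    rad <- sqrt(fr^2 + fc^2)
    amp <- ifelse(rad == 0, 0, rad^(-beta / 2))
    phase <- matrix(stats::runif(size^2, 0, 2 * pi), size, size)
    spec <- amp * exp(1i * phase)
    surf <- Re(stats::fft(spec, inverse = TRUE)) / size^2
    (surf - min(surf)) / (max(surf) - min(surf))
  })
}

#' Generate a binary texture phantom
#'
#' Produces a binary pattern whose theoretical box-counting dimension is
#' known (or trivially computable), used as ground truth for the fractal
#' estimator. The depth-`d` Sierpinski carpet has dimension
#' log 8 / log 3 = 1.8928 and exactly `8^d` foreground cells on its
#' natural `3^d` grid; other models give dimension 2 (`uniform`),
#' 1 (`single_line`), 0 (`single_point`), or lattice/spectral textures
#' resembling trabecular struts.
#'
#' @param params a [synth_params()] object.
#' @return A [binary_patch()] at stage `"skeletonized"`-independent raw
#'   stage `"thresholded"` (it has not passed through the chain), with
#'   attribute `theoretical_fd` where a closed form exists.
#' @export
make_ifs_fractal <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$size
  mp <- params$model_params
  out <- switch(params$texture_model,
    ifs_fractal = {
      m <- carpet_mask(mp$depth)
      structure(nn_rescale(m, n), theoretical_fd = log(8) / log(3))
    },
    uniform = structure(matrix(TRUE, n, n), theoretical_fd = 2),
    single_line = {
      m <- matrix(FALSE, n, n)
      m[n %/% 2, ] <- TRUE
      structure(m, theoretical_fd = 1)
    },
    single_point = {
      m <- matrix(FALSE, n, n)
      m[n %/% 2, n %/% 2] <- TRUE
      structure(m, theoretical_fd = 0)
    },
    strut_lattice = {
      i <- seq_len(n) - 1L
      on <- (i %% mp$spacing) < mp$width
      structure(outer(on, on, "|"), theoretical_fd = NA_real_)
    },
    spectral_surface = {
      s <- spectral_surface(n, mp$beta, params$seed)
      structure(s >= stats::median(s), theoretical_fd = NA_real_)
    }
  )
  fd <- attr(out, "theoretical_fd")
  p <- binary_patch(matrix(as.logical(out), n, n), stage = "thresholded")
  attr(p, "theoretical_fd") <- fd
  p
}

#' Generate a radiograph-like greyscale patch
#'
#' Maps a binary texture to two grey levels (the pattern phase dark by
#' default, so that after thresholding and inversion the chain analyses
#' the generated pattern itself), adds a low-frequency linear
#' illumination gradient of the stated peak-to-peak amplitude (the
#' soft-tissue brightness bias the sigma = 35 background-removal step is
#' designed to undo) and additive Gaussian noise, then rounds and clamps
#' to \[0, 255\].
#'
#' @param params a [synth_params()] object.
#' @return A [grey_patch()] carrying the underlying clean binary pattern
#'   in attribute `clean_pattern` for oracle comparisons.
#' @export
make_grey_patch <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$size
  mp <- params$model_params
  clean <- make_ifs_fractal(params)
  g <- matrix(as.numeric(mp$bg), n, n)
  g[as_logical_pixels(clean)] <- as.numeric(mp$fg)
  a <- params$illumination_amplitude
  if (a > 0) {
    u <- (row(g) - 1) / (n - 1) + (col(g) - 1) / (n - 1) # in [0, 2]
    g <- g + a * (u / 2 - 0.5)
  }
  if (params$noise_sd > 0) {
    g <- g + with_seed(params$seed + 1L,
                       matrix(stats::rnorm(n^2, 0, params$noise_sd), n, n))
  }
  g[] <- pmin(255, pmax(0, round(g)))
  out <- grey_patch(g, provenance = list(source = "synthetic",
                                         model = params$texture_model))
  attr(out, "clean_pattern") <- clean
  out
}

#' Parameters for synthetic cohort generation
#'
#' Defaults reproduce the structure of the hypercholesterolaemia study
#' population: three total-cholesterol groups (`normal` < 5.2 mmol/L,
#' `borderline` 5.2--6.2 mmol/L, `high` > 6.2 mmol/L) of sizes 35/33/24,
#' with group medians of regional fractal dimension (FD), lacunarity,
#' mandibular cortical width (MCW) and panoramic mandibular index (PMI)
#' set to the published cohort medians.
#'
#' @param n_per_group integer vector of three group sizes.
#' @param fd_medians 3 x 3 matrix of FD location parameters,
#'   rows = regions (anterior, premolar, molar), cols = groups
#'   (normal, borderline, high).
#' @param lac_medians 3 x 3 matrix of lacunarity locations (same layout).
#' @param mcw_medians 2 x 3 matrix, rows = sides (right, left), in pixels.
#' @param pmi_medians 2 x 3 matrix, rows = sides (right, left).
#' @param fd_spread,lac_spread,mcw_spread,pmi_spread within-group standard
#'   deviations of the logistic variation model.
#' @param age_mean,age_sd length-3 vectors per group (years).
#' @param male_prop length-3 vector of male proportions per group.
#' @param seed integer RNG seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_per_group = c(35L, 33L, 24L),
                          fd_medians = rbind(
                            anterior = c(1.4192, 1.4273, 1.4771),
                            premolar = c(1.5100, 1.5060, 1.5045),
                            molar    = c(1.5180, 1.5062, 1.5305)),
                          lac_medians = rbind(
                            anterior = c(0.2036, 0.1906, 0.1866),
                            premolar = c(0.1805, 0.1630, 0.1702),
                            molar    = c(0.1774, 0.1815, 0.1650)),
                          mcw_medians = rbind(
                            right = c(47.50, 47.70, 45.25),
                            left  = c(49.00, 46.70, 43.65)),
                          pmi_medians = rbind(
                            right = c(0.3670, 0.3609, 0.3687),
                            left  = c(0.3585, 0.3497, 0.3568)),
                          fd_spread = 0.10, lac_spread = 0.05,
                          mcw_spread = 9, pmi_spread = 0.08,
                          age_mean = c(60.4, 62.7, 68.88),
                          age_sd = c(19.0, 14.4, 8.2),
                          male_prop = c(0.457, 0.455, 0.125),
                          seed = 1L) {
  if (length(n_per_group) != 3L || any(n_per_group < 2)) {
    stop("n_per_group must be three integers, all >= 2")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 fd_medians = fd_medians, lac_medians = lac_medians,
                 mcw_medians = mcw_medians, pmi_medians = pmi_medians,
                 fd_spread = fd_spread, lac_spread = lac_spread,
                 mcw_spread = mcw_spread, pmi_spread = pmi_spread,
                 age_mean = age_mean, age_sd = age_sd,
                 male_prop = male_prop, seed = as.integer(seed)),
            class = "cohort_params")
}

cohort_groups <- c("normal", "borderline", "high")
cohort_regions <- c("anterior", "premolar", "molar")
cohort_sides <- c("right", "left")

# logistic with given SD: scale = sd * sqrt(3) / pi
rlogis_sd <- function(n, location, sd) {
  stats::rlogis(n, location = location, scale = sd * sqrt(3) / pi)
}

#' Anterior-FD group shift realizing a target Cohen's f
#'
#' For a three-group location-shift pattern `pattern` (default -1, 0, +1)
#' with within-group SD `spread` and group sizes `n_per_group`, returns the
#' scale `delta` such that group locations `delta * pattern` have
#' population effect size Cohen's f equal to `f`
#' (f^2 = sum w_i (mu_i - mu_bar)^2 / sigma^2 with w_i = n_i / N).
#'
#' @param f target Cohen's f (>= 0).
#' @param n_per_group three group sizes.
#' @param spread within-group SD.
#' @param pattern length-3 shift pattern.
#' @return The scalar `delta`.
#' @export
shift_for_cohens_f <- function(f, n_per_group = c(35L, 33L, 24L),
                               spread = 0.10, pattern = c(-1, 0, 1)) {
  if (f < 0) stop("invalid parameter: f must be >= 0")
  w <- n_per_group / sum(n_per_group)
  pbar <- sum(w * pattern)
  f * spread / sqrt(sum(w * (pattern - pbar)^2))
}

#' Simulate a per-patient cohort table
#'
#' Draws per-patient regional FD/lacunarity and per-side MCW/PMI values
#' from a logistic location-shift model around the configured group
#' medians, with age and sex structure per group, in the long layout
#' `patient_id, group, age, sex, region, fd, lacunarity, mcw, pmi`
#' (regions carry FD/lacunarity; sides carry MCW/PMI). Deterministic
#' under the seed in `params`.
#'
#' @param params a [cohort_params()] object.
#' @return A data.frame of class `cohort` with one row per patient x
#'   region/side.
#' @export
make_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_per_group
  N <- sum(n)
  g <- rep(1:3, n)
  with_seed(params$seed, {
    age <- round(pmin(100, pmax(18,
      stats::rnorm(N, params$age_mean[g], params$age_sd[g]))))
    sex <- ifelse(stats::runif(N) < params$male_prop[g], "male", "female")
    chol_lo <- c(3.2, 5.2, 6.21)[g]
    chol_hi <- c(5.19, 6.2, 9.5)[g]
    cholesterol <- round(stats::runif(N, chol_lo, chol_hi), 2)
    id <- sprintf("P%03d", seq_len(N))

    region_rows <- do.call(rbind, lapply(seq_along(cohort_regions), function(r) {
      data.frame(patient_id = id, group = cohort_groups[g], age = age,
                 sex = sex, cholesterol = cholesterol,
                 region = cohort_regions[r],
                 fd = rlogis_sd(N, params$fd_medians[r, g], params$fd_spread),
                 lacunarity = pmax(0, rlogis_sd(N, params$lac_medians[r, g],
                                                params$lac_spread)),
                 mcw = NA_real_, pmi = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    side_rows <- do.call(rbind, lapply(seq_along(cohort_sides), function(s) {
      data.frame(patient_id = id, group = cohort_groups[g], age = age,
                 sex = sex, cholesterol = cholesterol,
                 region = cohort_sides[s],
                 fd = NA_real_, lacunarity = NA_real_,
                 mcw = pmax(0, rlogis_sd(N, params$mcw_medians[s, g],
                                         params$mcw_spread)),
                 pmi = pmax(0, rlogis_sd(N, params$pmi_medians[s, g],
                                         params$pmi_spread)),
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(region_rows, side_rows)
    out <- out[order(out$patient_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Construct a landmark fixture with known morphometry
#'
#' Builds synthetic mandibular landmarks — inferior border polyline,
#' lower edge of the mental foramen, endosteal (inner cortical) margin —
#' from chosen cortical width `a` and foramen-to-border distance `b`, so
#' the morphometry operations can be checked against construction values.
#' The whole construction is rotated by `angle` and translated, which must
#' leave MCW/PMI unchanged (isometry invariance).
#'
#' @param seed integer; randomizes rotation/translation unless overridden.
#' @param a cortical width in pixels (MCW ground truth).
#' @param b foramen-to-border distance in pixels.
#' @param angle rotation in radians (default drawn from seed).
#' @param side `"right"` or `"left"`.
#' @return A list with elements `landmarks` (a `landmark_set`), `mcw`,
#'   `b` and `pmi` (the construction values).
#' @export
make_landmark_fixture <- function(seed = 1L, a = 12, b = 40, angle = NULL,
                                  side = "right") {
  if (is.null(angle)) {
    angle <- with_seed(seed, stats::runif(1, -pi / 6, pi / 6))
  }
  shift <- with_seed(seed + 1L, stats::runif(2, 100, 300))
  cols <- seq(-60, 60, by = 2)
  # image coordinates: row grows downward; border below, foramen above
  border <- cbind(row = rep(0, length(cols)), col = cols)
  inner <- cbind(row = rep(-a, length(cols)), col = cols)
  foramen <- c(row = -b, col = 3) # slightly off-centre of the polyline
  rot <- function(p) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    sweep(p %*% R, 2, -shift)
  }
  lm <- landmark_set(
    inferior_border = rot(border),
    foramen_lower_edge = drop(rot(matrix(foramen, 1, 2))),
    cortical_inner_margin = rot(inner),
    side = side
  )
  list(landmarks = lm, mcw = a, b = b,
       pmi = if (b > 0) a / b else 0)
}
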