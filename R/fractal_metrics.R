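# Box-counting fractal dimension and gliding-box lacunarity of a binary
# trabecular pattern. The dimension is the slope of log N(eps) against
# log(1/eps); lacunarity at each scale is the squared coefficient of
# variation of per-box foreground mass, empty boxes included.

#' Default box sizes
#'
#' The nine box side lengths used for the ROI analysis:
#' 2, 3, 4, 6, 8, 12, 16, 32, 64 pixels.
#' @return Integer vector of box sizes.
#' @export
default_box_sizes <- function() c(2L, 3L, 4L, 6L, 8L, 12L, 16L, 32L, 64L)

degenerate_input <- function(msg) {
  stop(structure(class = c("degenerate_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# deterministic grid origins for a box size: (0,0), (h,0), (0,h), (h,h)
# with h = floor(eps/2)
grid_offsets <- function(eps, n_offsets) {
  h <- eps %/% 2L
  offs <- unique(list(c(0L, 0L), c(h, 0L), c(0L, h), c(h, h)))
  offs[seq_len(min(n_offsets, length(offs)))]
}

#' Count occupied boxes and per-box masses across scales
#'
#' Covers the patch with grids of boxes of side `eps` for each configured
#' size and grid origin; edge boxes may be partial and are included. For
#' each grid the occupied count N(eps) (boxes containing at least one
#' foreground pixel) and the mean and population SD of per-box foreground
#' mass over all boxes covering the patch (empty boxes included) are
#' recorded. Grid origins are the deterministic set (0,0), (h,0), (0,h),
#' (h,h) with h = floor(eps/2); `n_offsets = 1` reproduces the classic
#' single-origin count.
#'
#' @param patch a [binary_patch()] (any stage) or logical matrix.
#' @param box_sizes integer box sides, each in \[1, patch side\].
#' @param n_offsets number of grid origins per size (1--4, default 4).
#' @return A `box_count_series` data.frame with columns `box_size`,
#'   `off_row`, `off_col`, `n_boxes`, `occupied`, `mass_mean`, `mass_sd`,
#'   and attribute `foreground` (total foreground pixel count).
#' @export
box_count <- function(patch, box_sizes = default_box_sizes(),
                      n_offsets = 4L) {
  x <- as_logical_pixels(patch)
  h <- nrow(x); w <- ncol(x)
  fg <- which(x, arr.ind = TRUE)
  if (nrow(fg) == 0L) degenerate_input("empty foreground: no boxes to count")
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1L) || any(box_sizes > max(h, w))) {
    stop("box sizes must be >= 1 and <= the patch side")
  }
  rows <- list()
  for (eps in box_sizes) {
    for (off in grid_offsets(eps, n_offsets)) {
      nbr <- (h - 1L + off[1]) %/% eps + 1L
      nbc <- (w - 1L + off[2]) %/% eps + 1L
      bi <- (fg[, 1] - 1L + off[1]) %/% eps
      bj <- (fg[, 2] - 1L + off[2]) %/% eps
      mass <- tabulate(bi * nbc + bj + 1L, nbins = nbr * nbc)
      mu <- mean(mass)
      sd_pop <- sqrt(mean((mass - mu)^2))
      rows[[length(rows) + 1L]] <- data.frame(
        box_size = eps, off_row = off[1], off_col = off[2],
        n_boxes = nbr * nbc, occupied = sum(mass > 0L),
        mass_mean = mu, mass_sd = sd_pop)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "foreground") <- nrow(fg)
  attr(out, "patch_dim") <- c(h, w)
  class(out) <- c("box_count_series", "data.frame")
  out
}

new_fractal_result <- function(fd = NA_real_, fit_r2 = NA_real_,
                               lacunarity = NA_real_,
                               lacunarity_by_size = NULL,
                               box_sizes = integer(), degenerate = FALSE) {
  structure(list(fd = fd, fit_r2 = fit_r2, lacunarity = lacunarity,
                 lacunarity_by_size = lacunarity_by_size,
                 box_sizes = box_sizes, degenerate = degenerate),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<fractal_result: degenerate input>\n")
  } else {
    cat(sprintf("<fractal_result fd=%.4f (R2=%.4f), lacunarity=%.4f>\n",
                x$fd, x$fit_r2, x$lacunarity))
  }
  invisible(x)
}

#' Box-counting fractal dimension from a count series
#'
#' Ordinary least squares of log N(eps) on log(1/eps), with occupied
#' counts first averaged over grid origins within each box size. The
#' slope is the dimension estimate; R-squared reports fit quality.
#' Estimates outside \[0, 2\] (possible with partial-box noise) are
#' clamped with a warning.
#'
#' @param series a `box_count_series` from [box_count()].
#' @return A `fractal_result` with `fd` and `fit_r2` populated.
#' @export
fractal_dimension <- function(series) {
  stopifnot(inherits(series, "box_count_series"))
  nbar <- tapply(series$occupied, series$box_size, mean)
  eps <- as.numeric(names(nbar))
  if (length(eps) < 3L) {
    stop("insufficient scales: need >= 3 distinct box sizes")
  }
  fit <- stats::lm.fit(cbind(1, log(1 / eps)), log(as.numeric(nbar)))
  slope <- fit$coefficients[2]
  y <- log(as.numeric(nbar))
  r2 <- if (all(y == y[1])) 1 else 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  fd <- unname(slope)
  if (fd < -1e-8 || fd > 2 + 1e-8) {
    warning(sprintf("fd estimate %.4f outside [0, 2]; clamped", fd))
  }
  fd <- min(2, max(0, fd))
  new_fractal_result(fd = fd, fit_r2 = unname(r2),
                     box_sizes = as.integer(eps))
}

#' Gliding-box lacunarity from a count series
#'
#' Per grid, lambda = (sigma/mu)^2 over per-box foreground masses (all
#' boxes covering the patch, empty boxes included); Lambda(eps) averages
#' lambda over grid origins, and the summary lacunarity averages
#' Lambda(eps) over box sizes. Zero for a translation-uniform full
#' pattern; large when mass concentrates in few boxes.
#'
#' @param series a `box_count_series` from [box_count()].
#' @return A `fractal_result` with `lacunarity` and `lacunarity_by_size`
#'   populated.
#' @export
lacunarity <- function(series) {
  stopifnot(inherits(series, "box_count_series"))
  if (any(series$mass_mean == 0)) {
    degenerate_input("empty foreground: lacunarity undefined")
  }
  lam <- (series$mass_sd / series$mass_mean)^2
  by_size <- tapply(lam, series$box_size, mean)
  new_fractal_result(
    lacunarity = mean(by_size),
    lacunarity_by_size = data.frame(box_size = as.integer(names(by_size)),
                                    lacunarity = as.numeric(by_size)),
    box_sizes = as.integer(names(by_size)))
}

#' Full texture analysis of a greyscale ROI
#'
#' Runs the preprocessing chain ([preprocess()]) and then box counting,
#' fractal dimension and lacunarity on the skeletonized pattern, using
#' the nine standard box sizes by default. A patch with no texture (e.g.
#' constant grey) yields a result flagged `degenerate = TRUE` with
#' `fd`/`lacunarity` unset, never a silent estimate.
#'
#' @param patch a [grey_patch()].
#' @param box_sizes box sides (default [default_box_sizes()]).
#' @param n_offsets grid origins per size (default 4).
#' @param sigma,offset,threshold preprocessing parameters (defaults 35,
#'   128, 128).
#' @return A `fractal_result` with `fd`, `fit_r2`, `lacunarity`,
#'   `lacunarity_by_size` and `degenerate` populated.
#' @export
analyze_patch <- function(patch, box_sizes = default_box_sizes(),
                          n_offsets = 4L, sigma = 35, offset = 128,
                          threshold = 128) {
  skel <- preprocess(patch, sigma = sigma, offset = offset,
                     threshold = threshold)
  if (isTRUE(attr(skel, "degenerate"))) {
    return(new_fractal_result(degenerate = TRUE,
                              box_sizes = as.integer(box_sizes)))
  }
  series <- box_count(skel, box_sizes = box_sizes, n_offsets = n_offsets)
  fdres <- fractal_dimension(series)
  lacres <- lacunarity(series)
  out <- new_fractal_result(fd = fdres$fd, fit_r2 = fdres$fit_r2,
                            lacunarity = lacres$lacunarity,
                            lacunarity_by_size = lacres$lacunarity_by_size,
                            box_sizes = as.integer(box_sizes))
  attr(out, "trace") <- attr(skel, "trace")
  out
}
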