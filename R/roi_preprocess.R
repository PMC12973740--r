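# Rudolph-White trabecular preprocessing chain: Gaussian background
# estimation (sigma = 35), subtraction with a +128 offset, threshold at
# 128, 3x3 morphological opening, inversion, and thinning to a
# one-pixel-wide skeleton. The stage tag on binary_patch enforces the
# order deterministically.

#' Crop a region of interest from a full image
#'
#' Extracts the exact sub-grid named by `roi`; no resampling is performed.
#'
#' @param image a [grey_patch()] (or any grey matrix) covering the full
#'   radiograph.
#' @param roi a [roi_spec()].
#' @return A [grey_patch()] of side `roi$size` with provenance recording
#'   the ROI offset.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  h <- nrow(image); w <- ncol(image)
  r0 <- roi$origin[1]; c0 <- roi$origin[2]; s <- roi$size
  if (r0 < 0 || c0 < 0 || r0 + s > h || c0 + s > w) {
    stop(sprintf(
      "ROI out of bounds: origin (%d, %d) + size %d exceeds image %d x %d",
      r0, c0, s, h, w))
  }
  sub <- unclass(image)[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), drop = FALSE]
  grey_patch(sub, provenance = list(region = roi$region, side = roi$side,
                                    origin = roi$origin))
}

#' ROI specification
#'
#' @param region one of `"anterior"`, `"premolar"`, `"molar"`.
#' @param side `"right"` or `"left"`; the right side is used unless
#'   inflammation precluded it.
#' @param origin `(row, col)` 0-based top-left corner in the source image.
#' @param size pixels per side (default 64).
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(region = c("anterior", "premolar", "molar"),
                     side = c("right", "left"),
                     origin = c(0L, 0L), size = 64L) {
  region <- match.arg(region)
  side <- match.arg(side)
  structure(list(region = region, side = side,
                 origin = as.integer(origin), size = as.integer(size)),
            class = "roi_spec")
}

# Row/column blur operator for a separable Gaussian with symmetric
# (reflect) padding: an n x n doubly-stochastic matrix applied on both
# sides. Symmetric padding matters here: sigma = 35 exceeds the 64-px
# patch, so zero padding would darken every border.
gaussian_operator <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # symmetric (half-sample) reflection of out-of-range indices
  reflect <- function(i) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- reflect(i + (-r):r)
    w <- rowsum(k, src)
    M[i, as.integer(rownames(w))] <- w
  }
  M
}

#' Estimate the slowly-varying background of a patch
#'
#' Gaussian blur with the stated sigma; with sigma = 35 on a 64 x 64 ROI
#' this captures the X-ray brightness variation due to soft tissue and
#' bone thickness while averaging out the trabecular texture. Boundary
#' handling is symmetric reflection, so a constant patch blurs to itself.
#'
#' @param patch a [grey_patch()].
#' @param sigma Gaussian standard deviation in pixels (> 0), default 35.
#' @return A real-valued matrix of the same dimensions.
#' @export
gaussian_background <- function(patch, sigma = 35) {
  if (sigma <= 0) stop("invalid parameter: sigma must be > 0")
  x <- unclass(patch)
  storage.mode(x) <- "double"
  Mr <- gaussian_operator(nrow(x), sigma)
  Mc <- if (ncol(x) == nrow(x)) Mr else gaussian_operator(ncol(x), sigma)
  Mr %*% x %*% t(Mc)
}

# round half away from zero, as in integer 8-bit pipelines
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Subtract the background and re-centre at a grey offset
#'
#' Per pixel: original - blurred + offset, rounded half-away-from-zero to
#' integer grey and clamped to \[0, 255\]. With offset 128, flat background
#' lands exactly on the subsequent threshold.
#'
#' @param original the [grey_patch()] before blurring.
#' @param blurred the matrix returned by [gaussian_background()].
#' @param offset grey levels added after subtraction (default 128).
#' @return A [grey_patch()].
#' @export
subtract_offset <- function(original, blurred, offset = 128) {
  if (!all(dim(original) == dim(blurred))) {
    stop(sprintf("dimension mismatch: original %d x %d vs blurred %d x %d",
                 nrow(original), ncol(original), nrow(blurred), ncol(blurred)))
  }
  v <- round_half_away(unclass(original) - blurred + offset)
  v[] <- pmin(255, pmax(0, v))
  grey_patch(v, provenance = attr(original, "provenance"))
}

#' Binarize a grey patch at a fixed threshold
#'
#' Pixels with grey value below the threshold become black (background),
#' above it white (foreground). A pixel exactly at the threshold is
#' assigned white: after background subtraction flat regions sit exactly
#' at 128, and the tie rule must be fixed for the chain to be
#' deterministic.
#'
#' @param patch a [grey_patch()].
#' @param threshold grey level (default 128).
#' @return A [binary_patch()] at stage `"thresholded"` (`TRUE` = white).
#' @export
binarize <- function(patch, threshold = 128) {
  binary_patch(unclass(patch) >= threshold, stage = "thresholded")
}

shift_pad <- function(x, dr, dc, pad) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(pad, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

morph3 <- function(x, op = c("erode", "dilate")) {
  op <- match.arg(op)
  pad <- op == "erode" # outside the patch does not veto erosion / feed dilation
  acc <- x
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shift_pad(x, dr, dc, pad)
    acc <- if (op == "erode") acc & s else acc | s
  }
  acc
}

#' Morphological opening to suppress radiological noise
#'
#' One binary erosion then one binary dilation of the white phase with a
#' 3 x 3 square structuring element, removing speckle smaller than the
#' element. Pixels outside the patch are treated as white for erosion and
#' black for dilation, so an all-white patch is stable.
#'
#' @param patch a [binary_patch()] at stage `"thresholded"`.
#' @return A [binary_patch()] at stage `"cleaned"`.
#' @export
morpho_clean <- function(patch) {
  require_stage(patch, "thresholded", "morpho_clean")
  x <- as_logical_pixels(patch)
  binary_patch(morph3(morph3(x, "erode"), "dilate"), stage = "cleaned")
}

#' Invert a cleaned binary patch
#'
#' Logical complement: after inversion the analysed foreground is the
#' originally-dark phase (marrow spaces between trabeculae), which the
#' subsequent thinning reduces to the trabecular pattern.
#'
#' @param patch a [binary_patch()] at stage `"cleaned"`.
#' @return A [binary_patch()] at stage `"inverted"`.
#' @export
invert <- function(patch) {
  require_stage(patch, "cleaned", "invert")
  binary_patch(!as_logical_pixels(patch), stage = "inverted")
}

# one Zhang-Suen sub-iteration; returns the updated matrix
zs_subiter <- function(x, step) {
  # neighbours P2..P9 clockwise from north
  P2 <- shift_pad(x,  1,  0, FALSE); P3 <- shift_pad(x,  1, -1, FALSE)
  P4 <- shift_pad(x,  0, -1, FALSE); P5 <- shift_pad(x, -1, -1, FALSE)
  P6 <- shift_pad(x, -1,  0, FALSE); P7 <- shift_pad(x, -1,  1, FALSE)
  P8 <- shift_pad(x,  0,  1, FALSE); P9 <- shift_pad(x,  1,  1, FALSE)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
       (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  cond <- x & B >= 2 & B <= 6 & A == 1
  if (step == 1L) {
    cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
  } else {
    cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
  }
  x & !cond
}

zs_thin <- function(x) {
  repeat {
    before <- x
    repeat {
      x1 <- zs_subiter(x, 1L)
      x2 <- zs_subiter(x1, 2L)
      if (identical(x2, x)) break
      x <- x2
    }
    # deterministic cleanup: break any residual 2x2 all-foreground block
    # by removing its top-left pixel (raster order), then re-thin
    repeat {
      b <- x[-nrow(x), -ncol(x)] & x[-1, -ncol(x)] &
           x[-nrow(x), -1] & x[-1, -1]
      if (!any(b)) break
      idx <- which(b, arr.ind = TRUE)[1, , drop = TRUE]
      x[idx[1], idx[2]] <- FALSE
    }
    if (identical(x, before)) break
  }
  x
}

#' Thin the inverted pattern to a one-pixel-wide skeleton
#'
#' Zhang-Suen-type 8-connected thinning of the `TRUE` phase; the result
#' contains no 2 x 2 all-foreground block and is a subset of the input
#' foreground.
#'
#' @param patch a [binary_patch()] at stage `"inverted"`.
#' @return A [binary_patch()] at stage `"skeletonized"`.
#' @export
skeletonize <- function(patch) {
  require_stage(patch, "inverted", "skeletonize")
  binary_patch(zs_thin(as_logical_pixels(patch)), stage = "skeletonized")
}

#' Run the full trabecular preprocessing chain
#'
#' Composition gaussian_background -> subtract_offset -> binarize ->
#' morpho_clean -> invert -> skeletonize. The result carries a `trace`
#' attribute with the foreground fraction after each binary stage (for
#' auditing which phase is being analysed) and a `degenerate` flag set
#' when the patch has no texture (thresholded stage all-white or
#' all-black, or an empty skeleton).
#'
#' @param patch a [grey_patch()].
#' @param sigma Gaussian sigma in pixels (default 35).
#' @param offset grey offset added after subtraction (default 128).
#' @param threshold binarization threshold (default 128).
#' @return A [binary_patch()] at stage `"skeletonized"` with attributes
#'   `degenerate` and `trace`.
#' @export
preprocess <- function(patch, sigma = 35, offset = 128, threshold = 128) {
  bg <- gaussian_background(patch, sigma)
  centred <- subtract_offset(patch, bg, offset)
  thr <- binarize(centred, threshold)
  cleaned <- morpho_clean(thr)
  inv <- invert(cleaned)
  skel <- skeletonize(inv)
  frac <- c(thresholded = mean(thr), cleaned = mean(cleaned),
            inverted = mean(inv), skeletonized = mean(skel))
  degenerate <- frac[["thresholded"]] %in% c(0, 1) ||
    frac[["cleaned"]] %in% c(0, 1) ||
    frac[["skeletonized"]] == 0
  attr(skel, "trace") <- frac
  attr(skel, "degenerate") <- degenerate
  skel
}
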