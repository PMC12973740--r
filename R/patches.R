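#' Grey-level patch
#'
#' Construct an 8-bit greyscale patch, the unit of texture analysis. Values
#' are integers in \[0, 255\]; a typical region of interest (ROI) is a
#' 64 x 64 pixel square of trabecular bone.
#'
#' @param pixels numeric matrix of grey values in \[0, 255\].
#' @param provenance optional list recording source image id and ROI offset.
#' @return A `grey_patch`: an integer matrix with class and provenance
#'   attributes.
#' @export
grey_patch <- function(pixels, provenance = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels)) stop("grey patch contains NA pixels")
  if (any(pixels < 0 | pixels > 255)) {
    stop("grey values must lie in [0, 255]")
  }
  x <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(x, class = "grey_patch", provenance = provenance)
}

#' @export
print.grey_patch <- function(x, ...) {
  cat(sprintf("<grey_patch %d x %d, grey range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Binary patch with a pipeline stage tag
#'
#' Boolean pixel grid produced by thresholding, morphology or thinning.
#' The stage tag enforces the order of the preprocessing chain:
#' `thresholded` -> `cleaned` -> `inverted` -> `skeletonized`.
#'
#' @param pixels logical matrix (`TRUE` = foreground).
#' @param stage one of `"thresholded"`, `"cleaned"`, `"inverted"`,
#'   `"skeletonized"`.
#' @return A `binary_patch`: a logical matrix with a `stage` attribute.
#' @export
binary_patch <- function(pixels,
                         stage = c("thresholded", "cleaned", "inverted",
                                   "skeletonized")) {
  stage <- match.arg(stage)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("binary patch contains NA pixels")
  structure(pixels, class = "binary_patch", stage = stage)
}

#' @export
print.binary_patch <- function(x, ...) {
  cat(sprintf("<binary_patch %d x %d, stage=%s, foreground %.1f%%>\n",
              nrow(x), ncol(x), attr(x, "stage"), 100 * mean(x)))
  invisible(x)
}

patch_stage <- function(x) attr(x, "stage")

require_stage <- function(x, expected, op) {
  if (!inherits(x, "binary_patch")) {
    stop(sprintf("%s() expects a binary_patch", op))
  }
  if (!identical(patch_stage(x), expected)) {
    stop(sprintf(
      "pipeline-order error: %s() expects stage '%s' but got '%s'",
      op, expected, patch_stage(x)
    ))
  }
  invisible(x)
}

as_logical_pixels <- function(patch) {
  if (inherits(patch, "binary_patch") || is.logical(patch)) {
    x <- patch
    storage.mode(x) <- "logical"
    attributes(x) <- list(dim = dim(patch))
    return(x)
  }
  stop("expected a binary_patch or logical matrix")
}

#' Read an 8-bit greyscale image
#'
#' Reads a TIFF or PNG file (chosen by extension) and returns a
#' `grey_patch` on the 0--255 integer scale. Colour images are converted
#' to luminance by channel averaging.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return A [grey_patch()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: .", ext)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  grey_patch(round(arr * 255), provenance = list(source = path))
}

#' Write a patch to an 8-bit greyscale image file
#'
#' @param patch a [grey_patch()] or [binary_patch()] (binary is written as
#'   0/255).
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(patch, path) {
  x <- if (inherits(patch, "binary_patch")) {
    matrix(as.numeric(patch), nrow(patch), ncol(patch))
  } else {
    unclass(patch) / 255
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported image extension: .", ext)
  )
  invisible(path)
}
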