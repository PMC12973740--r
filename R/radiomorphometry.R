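# Mandibular cortical width (MCW) and panoramic mandibular index (PMI)
# from operator-supplied landmark coordinates: the cortical thickness is
# measured on a line perpendicular to the inferior mandibular border
# passing through the lower edge of the mental foramen, and PMI divides
# it by the foramen-to-border distance along the same axis, making the
# ratio independent of panoramic magnification.

#' Landmark coordinates for one hemimandible
#'
#' @param inferior_border numeric matrix of `(row, col)` points (>= 2)
#'   tracing the lower mandibular border near the mental foramen.
#' @param foramen_lower_edge `(row, col)` point at the lower edge of the
#'   mental foramen.
#' @param cortical_inner_margin numeric matrix of `(row, col)` points
#'   tracing the endosteal cortical boundary.
#' @param side `"right"` or `"left"`.
#' @return A `landmark_set` list. Coordinates are in pixels.
#' @export
landmark_set <- function(inferior_border, foramen_lower_edge,
                         cortical_inner_margin, side = c("right", "left")) {
  side <- match.arg(side)
  inferior_border <- as.matrix(inferior_border)
  cortical_inner_margin <- as.matrix(cortical_inner_margin)
  if (nrow(inferior_border) < 2L) {
    stop("inferior_border needs at least 2 points")
  }
  foramen_lower_edge <- as.numeric(foramen_lower_edge)
  stopifnot(length(foramen_lower_edge) == 2L,
            ncol(inferior_border) == 2L,
            ncol(cortical_inner_margin) == 2L)
  structure(list(inferior_border = unname(inferior_border),
                 foramen_lower_edge = unname(foramen_lower_edge),
                 cortical_inner_margin = unname(cortical_inner_margin),
                 side = side),
            class = "landmark_set")
}

# closest point on a polyline to p; returns list(point, seg_index)
project_on_polyline <- function(poly, p) {
  best <- NULL; bestd <- Inf
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < bestd) {
      bestd <- d
      best <- list(point = q, seg = i)
    }
  }
  best
}

#' Perpendicular measurement axis through the mental foramen
#'
#' Projects the foramen point onto the inferior-border polyline, fits the
#' local tangent by a total-least-squares line over the `k` border
#' vertices nearest the foot point (rotation-invariant, robust to
#' polyline jitter), and returns the foot point together with the unit
#' normal oriented toward the foramen.
#'
#' @param border numeric matrix of border `(row, col)` points (>= 2).
#' @param through the `(row, col)` point the axis must pass through
#'   (lower edge of the mental foramen).
#' @param k number of border vertices used for the tangent fit
#'   (default 7).
#' @return A list with `foot` (point on the border), `normal` (unit
#'   vector toward `through`) and `tangent` (unit vector).
#' @export
perpendicular_axis <- function(border, through, k = 7L) {
  border <- as.matrix(border)
  if (nrow(border) < 2L) stop("border needs at least 2 points")
  through <- as.numeric(through)
  proj <- project_on_polyline(border, through)
  foot <- proj$point
  d2 <- rowSums(sweep(border, 2, foot)^2)
  nn <- border[order(d2)[seq_len(min(k, nrow(border)))], , drop = FALSE]
  ctr <- sweep(nn, 2, colMeans(nn))
  cv <- crossprod(ctr) / nrow(nn)
  if (sum(cv^2) < .Machine$double.eps) {
    stop("geometry error: degenerate tangent (repeated border points)")
  }
  ev <- eigen(cv, symmetric = TRUE)
  tangent <- ev$vectors[, 1]
  tangent <- tangent / sqrt(sum(tangent^2))
  normal <- c(-tangent[2], tangent[1])
  s <- sum((through - foot) * normal)
  if (s < 0) normal <- -normal
  list(foot = foot, normal = normal, tangent = tangent)
}

# the shared measurement axis: perpendicular through the foramen, with
# the normal oriented toward the cortical inner margin (so a foramen on
# the wrong side of the border shows up as b < 0, not a flipped axis)
measurement_axis <- function(landmarks, k) {
  ax <- perpendicular_axis(landmarks$inferior_border,
                           landmarks$foramen_lower_edge, k = k)
  ctr <- colMeans(landmarks$cortical_inner_margin)
  if (sum((ctr - ax$foot) * ax$normal) < 0) ax$normal <- -ax$normal
  ax
}

# intersection parameter t of ray foot + t*dir with polyline segments;
# smallest positive t within [0, tmax]
ray_polyline_t <- function(foot, dir, poly, tmax = Inf) {
  best <- NA_real_
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    # solve foot + t*dir = a + u*(b - a)
    M <- cbind(dir, a - b)
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(det) < 1e-12) next
    rhs <- a - foot
    t <- (rhs[1] * M[2, 2] - rhs[2] * M[1, 2]) / det
    u <- (M[1, 1] * rhs[2] - M[2, 1] * rhs[1]) / det
    if (u >= -1e-9 && u <= 1 + 1e-9 && t >= -1e-9 && t <= tmax) {
      if (is.na(best) || t < best) best <- t
    }
  }
  best
}

#' Mandibular cortical width
#'
#' Euclidean distance along the perpendicular axis between its foot on
#' the inferior border and its intersection with the endosteal
#' (inner cortical) margin, in pixels.
#'
#' @param landmarks a [landmark_set()].
#' @param k tangent-fit neighbourhood size (see [perpendicular_axis()]).
#' @return MCW in pixels.
#' @export
mcw <- function(landmarks, k = 7L) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ax <- measurement_axis(landmarks, k)
  t <- ray_polyline_t(ax$foot, ax$normal, landmarks$cortical_inner_margin)
  if (is.na(t)) {
    stop("measurement failure: perpendicular axis does not intersect ",
         "the cortical inner margin")
  }
  max(0, t)
}

#' Panoramic mandibular index
#'
#' PMI = MCW / b where b is the distance from the lower edge of the
#' mental foramen to the inferior border, measured along the same
#' perpendicular axis. Because both lengths share the panoramic
#' magnification factor, the ratio is scale-invariant.
#'
#' @param landmarks a [landmark_set()].
#' @param k tangent-fit neighbourhood size.
#' @return A `morphometric_result` list with `mcw`,
#'   `foramen_border_distance`, `pmi` and `side`.
#' @export
pmi <- function(landmarks, k = 7L) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ax <- measurement_axis(landmarks, k)
  b <- sum((landmarks$foramen_lower_edge - ax$foot) * ax$normal)
  if (b <= 0) {
    stop("degenerate geometry: foramen lies on or below the inferior ",
         "border (b <= 0)")
  }
  a <- mcw(landmarks, k = k)
  structure(list(mcw = a, foramen_border_distance = b, pmi = a / b,
                 side = landmarks$side),
            class = "morphometric_result")
}

#' @export
print.morphometric_result <- function(x, ...) {
  cat(sprintf("<morphometry %s: MCW=%.2f px, b=%.2f px, PMI=%.4f>\n",
              x$side, x$mcw, x$foramen_border_distance, x$pmi))
  invisible(x)
}

#' Read a landmark table
#'
#' Parses a CSV with columns `image, side, role, point_index, row, col`
#' (role one of `inferior_border`, `foramen_lower_edge`,
#' `cortical_inner_margin`) into one [landmark_set()] per image and side.
#'
#' @param path CSV path.
#' @return A named list of `landmark_set`s, names `"<image>/<side>"`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "side", "role", "point_index", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !df$role %in% c("inferior_border", "foramen_lower_edge",
                         "cortical_inner_margin")
  if (any(bad)) {
    stop(sprintf("unknown landmark role '%s' at line %d",
                 df$role[which(bad)[1]], which(bad)[1] + 1L))
  }
  keys <- unique(df[, c("image", "side")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$image == keys$image[i] & df$side == keys$side[i], ]
    sub <- sub[order(sub$role, sub$point_index), ]
    pts <- function(role) {
      s <- sub[sub$role == role, ]
      as.matrix(s[order(s$point_index), c("row", "col")])
    }
    for_pt <- pts("foramen_lower_edge")
    out[[paste(keys$image[i], keys$side[i], sep = "/")]] <- landmark_set(
      inferior_border = pts("inferior_border"),
      foramen_lower_edge = for_pt[1, ],
      cortical_inner_margin = pts("cortical_inner_margin"),
      side = keys$side[i])
  }
  out
}
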