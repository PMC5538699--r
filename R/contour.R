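#' Closed planar contours
#'
#' A contour is an ordered set of 2D vertices (in mm) describing a simple,
#' implicitly closed polygon with counter-clockwise orientation. Contours
#' describe the thoracic body surface and the lung and heart boundaries at the
#' electrode-belt plane.
#'
#' Coordinate convention used throughout the package: `x` increases towards the
#' animal's left, `y` increases from anterior (ventral) to posterior (dorsal).
#' Image row 1 is therefore the most anterior row and column 1 the animal's
#' right side.
#'
#' @param vertices two-column numeric matrix (or data frame) of x/y vertex
#'   coordinates in mm, in order, without a repeated closing vertex.
#' @param label free-text label (e.g. "thorax", "lung_left").
#' @return An object of class `eit_contour`: the vertex matrix with attributes
#'   `label`.
#' @export
contour <- function(vertices, label = "contour") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("contour vertices must have two columns (x, y)", call. = FALSE)
  storage.mode(v) <- "double"
  if (nrow(v) >= 2L && isTRUE(all.equal(v[1L, ], v[nrow(v), ], tolerance = 1e-12))) {
    v <- v[-nrow(v), , drop = FALSE]  # drop repeated closing vertex
  }
  if (nrow(v) < 8L) stop("a contour needs at least 8 vertices", call. = FALSE)
  if (anyNA(v)) stop("contour vertices contain NA", call. = FALSE)
  a <- signed_area(v)
  if (abs(a) <= 0) stop("invalid geometry: contour encloses no area", call. = FALSE)
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # enforce CCW
  if (!is_simple_polygon(v)) {
    stop("invalid geometry: contour is self-intersecting", call. = FALSE)
  }
  colnames(v) <- c("x", "y")
  structure(v, label = label, class = c("eit_contour", "matrix", "array"))
}

#' @export
print.eit_contour <- function(x, ...) {
  cat(sprintf("<eit_contour> '%s': %d vertices, area %.3f mm^2\n",
              attr(x, "label"), nrow(x), contour_area(x)))
  invisible(x)
}

is_contour <- function(x) inherits(x, "eit_contour")

# Shoelace signed area; positive for counter-clockwise vertex order.
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Enclosed area of a contour (mm^2)
#' @param c an `eit_contour`
#' @export
contour_area <- function(c) abs(signed_area(unclass(c)))

#' Area centroid ("gravitational center") of a contour
#' @param c an `eit_contour`
#' @return length-2 numeric (x, y) in mm
#' @export
contour_centroid <- function(c) {
  v <- unclass(c)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Perimeter of a contour (mm)
#' @param c an `eit_contour`
#' @export
contour_perimeter <- function(c) {
  v <- unclass(c)
  vn <- v[c(2:nrow(v), 1L), , drop = FALSE]
  sum(sqrt(rowSums((vn - v)^2)))
}

# Segment-intersection based simplicity test. O(n^2) on vertex count, which is
# fine for the contour sizes used here (tens to a few hundred vertices).
is_simple_polygon <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip segments adjacent to segment i (shared endpoints)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(p1[i, ], p2[i, ], p1[js, , drop = FALSE], p2[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# vectorized proper-crossing test of segment (a,b) against segments (c[k,], d[k,])
segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r1, r2) {
    (q[1L] - p[1L]) * (r2 - p[2L]) - (q[2L] - p[2L]) * (r1 - p[1L])
  }
  d1 <- o(a, b, c[, 1L], c[, 2L])
  d2 <- o(a, b, d[, 1L], d[, 2L])
  d3 <- (d[, 1L] - c[, 1L]) * (a[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (a[1L] - c[, 1L])
  d4 <- (d[, 1L] - c[, 1L]) * (b[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (b[1L] - c[, 1L])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Center and area-normalize a contour
#'
#' Aligns the contour on its area centroid and rescales it uniformly so the
#' enclosed area equals pi, the common normalization applied before computing
#' the shape-mismatch metric [symmetric_difference()]. Only translation and
#' uniform scaling are applied, so the shape is similar to the input.
#'
#' @param c an `eit_contour`
#' @return the normalized `eit_contour`
#' @export
normalize_contour <- function(c) {
  stopifnot(is_contour(c))
  a <- contour_area(c)
  if (a <= 0) stop("invalid geometry: degenerate contour", call. = FALSE)
  ctr <- contour_centroid(c)
  v <- sweep(unclass(c), 2L, ctr) * sqrt(pi / a)
  contour(v, label = attr(c, "label"))
}

#' Shape mismatch between two contours (Delta-S, %)
#'
#' Both contours are first centroid-aligned and normalized to area pi
#' ([normalize_contour()]); Delta-S is the area of the set-symmetric difference
#' of the two enclosed regions, as a percentage of pi. Identical shapes give 0;
#' disjoint shapes give 200.
#'
#' @param a,b `eit_contour` objects
#' @param method `"polygon"` computes exact polygon clipping; `"raster"` uses a
#'   fine rasterization (`resolution^2` cells over the joint bounding box).
#' @param resolution raster resolution per axis for `method = "raster"`.
#' @return Delta-S in percent.
#' @export
symmetric_difference <- function(a, b, method = c("polygon", "raster"),
                                 resolution = 4096L) {
  method <- match.arg(method)
  an <- normalize_contour(a)
  bn <- normalize_contour(b)
  if (method == "polygon") {
    inter <- polyclip::polyclip(
      list(x = an[, 1L], y = an[, 2L]),
      list(x = bn[, 1L], y = bn[, 2L]),
      op = "intersection")
    area_i <- if (length(inter)) {
      sum(vapply(inter, function(p) abs(signed_area(cbind(p$x, p$y))), 0.0))
    } else 0
  } else {
    area_i <- raster_intersection_area(an, bn, resolution)
  }
  # area(a) = area(b) = pi after normalization
  100 * (2 * pi - 2 * area_i) / pi
}

# Brute-force area of intersection by cell-center rasterization.
raster_intersection_area <- function(an, bn, resolution) {
  xr <- range(an[, 1L], bn[, 1L]); yr <- range(an[, 2L], bn[, 2L])
  dx <- diff(xr) / resolution; dy <- diff(yr) / resolution
  xs <- xr[1L] + (seq_len(resolution) - 0.5) * dx
  ys <- yr[1L] + (seq_len(resolution) - 0.5) * dy
  # row-wise to keep memory bounded at high resolution
  n_in <- 0
  for (y in ys) {
    ina <- points_in_contour(xs, rep(y, resolution), an)
    if (!any(ina)) next
    inb <- points_in_contour(xs[ina], rep(y, sum(ina)), bn)
    n_in <- n_in + sum(inb)
  }
  n_in * dx * dy
}

# point-in-polygon wrapper; boundary points count as inside
points_in_contour <- function(x, y, c) {
  v <- unclass(c)
  sp::point.in.polygon(x, y, v[, 1L], v[, 2L]) > 0
}

#' Place an electrode belt on a contour
#'
#' Positions `n` electrodes equally spaced by arc length along the contour.
#' Electrode 1 sits at the anterior midline: the intersection of the contour
#' with the ray from its centroid in the anterior (-y) direction. Numbering
#' proceeds clockwise when viewed from cranial, which in the package's
#' coordinate frame means towards the animal's left first; `direction =
#' "right-first"` reverses it.
#'
#' @param c thorax `eit_contour`
#' @param n number of electrodes (default 32)
#' @param width_frac electrode width as a fraction of the inter-electrode arc
#'   spacing (belt-geometry choice; the width only shapes the boundary patches
#'   of the finite-element model).
#' @param direction `"left-first"` (clockwise from cranial) or `"right-first"`.
#' @return An `electrode_layout`: list with `positions` (n x 2 matrix),
#'   `arc` (arc-length coordinate of each electrode along the resampled belt),
#'   `width` (arc width in mm), `perimeter`, and the generating contour.
#' @export
place_electrodes <- function(c, n = 32L, width_frac = 0.35,
                             direction = c("left-first", "right-first")) {
  stopifnot(is_contour(c))
  direction <- match.arg(direction)
  if (n < 4L) stop("invalid argument: need at least 4 electrodes", call. = FALSE)
  v <- unclass(c)
  ctr <- contour_centroid(c)
  s0 <- anterior_arc_position(v, ctr)
  per <- contour_perimeter(c)
  arc <- (s0 + (seq_len(n) - 1L) / n * per) %% per
  if (direction == "right-first") {
    arc <- (s0 - (seq_len(n) - 1L) / n * per) %% per
  }
  pos <- t(vapply(arc, function(s) point_at_arc(v, s), numeric(2L)))
  structure(list(
    positions = pos, arc = arc, n = n,
    width = width_frac * per / n, perimeter = per,
    contour = c, direction = direction
  ), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes, width %.1f mm on perimeter %.1f mm\n",
              x$n, x$width, x$perimeter))
  invisible(x)
}

# cumulative arc length at each vertex (starting at vertex 1 with 0)
vertex_arcs <- function(v) {
  seg <- sqrt(rowSums((v[c(2:nrow(v), 1L), , drop = FALSE] - v)^2))
  c(0, cumsum(seg))  # length nrow+1; last = perimeter
}

# point on the closed polyline at arc-length s from vertex 1
point_at_arc <- function(v, s) {
  cs <- vertex_arcs(v)
  per <- cs[length(cs)]
  s <- s %% per
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, nrow(v))
  f <- (s - cs[i]) / (cs[i + 1L] - cs[i])
  j <- if (i == nrow(v)) 1L else i + 1L
  v[i, ] + f * (v[j, ] - v[i, ])
}

# arc-length coordinate where the ray centroid -> anterior (-y) crosses the
# boundary; found on the piecewise-linear contour exactly
anterior_arc_position <- function(v, ctr) {
  n <- nrow(v)
  cs <- vertex_arcs(v)
  p1 <- v; p2 <- v[c(2:n, 1L), , drop = FALSE]
  # intersect each edge with the vertical half-line x = ctr_x, y < ctr_y
  dx <- p2[, 1L] - p1[, 1L]
  tpar <- (ctr[1L] - p1[, 1L]) / ifelse(abs(dx) < 1e-300, NA_real_, dx)
  ok <- !is.na(tpar) & tpar >= 0 & tpar < 1
  yint <- p1[, 2L] + tpar * (p2[, 2L] - p1[, 2L])
  ok <- ok & yint < ctr[2L]
  if (!any(ok)) stop("invalid geometry: no anterior midline intersection", call. = FALSE)
  # most anterior crossing (smallest y)
  i <- which(ok)[which.min(yint[ok])]
  seg_len <- sqrt(sum((p2[i, ] - p1[i, ])^2))
  cs[i] + tpar[i] * seg_len
}
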