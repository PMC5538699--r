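#' Thorax geometry: body, lung and heart contours
#'
#' Bundles the anatomical prior used to build a reconstruction model: the
#' thoracic body contour, zero to two lung contours and an optional heart
#' contour, together with the kind of prior it represents — `"circular"` (no
#' anatomical information), `"averaged"` (population-average contours) or
#' `"individual"` (subject-specific contours).
#'
#' @param thorax `eit_contour` of the body surface
#' @param lungs list of 0-2 `eit_contour`s
#' @param heart `eit_contour` or NULL
#' @param kind one of `"circular"`, `"averaged"`, `"individual"`
#' @return a `thorax_geometry` object
#' @export
thorax_geometry <- function(thorax, lungs = list(), heart = NULL,
                            kind = c("circular", "averaged", "individual")) {
  kind <- match.arg(kind)
  stopifnot(is_contour(thorax))
  if (is_contour(lungs)) lungs <- list(lungs)
  stopifnot(length(lungs) <= 2L, all(vapply(lungs, is_contour, TRUE)))
  if (!is.null(heart)) stopifnot(is_contour(heart))
  organs <- c(lungs, if (!is.null(heart)) list(heart))
  for (o in organs) {
    if (!all(points_in_contour(o[, 1L], o[, 2L], thorax)))
      stop("invalid geometry: organ contour '", attr(o, "label"),
           "' is not inside the thorax", call. = FALSE)
  }
  if (length(organs) > 1L) {
    for (i in seq_len(length(organs) - 1L)) for (j in (i + 1L):length(organs)) {
      ov <- polyclip::polyclip(
        list(x = organs[[i]][, 1L], y = organs[[i]][, 2L]),
        list(x = organs[[j]][, 1L], y = organs[[j]][, 2L]), op = "intersection")
      if (length(ov) &&
          sum(vapply(ov, function(p) abs(signed_area(cbind(p$x, p$y))), 0)) >
            1e-9 * contour_area(thorax))
        stop("invalid geometry: organ contours '", attr(organs[[i]], "label"),
             "' and '", attr(organs[[j]], "label"), "' overlap", call. = FALSE)
    }
  }
  structure(list(thorax = thorax, lungs = lungs, heart = heart, kind = kind),
            class = "thorax_geometry")
}

#' @export
print.thorax_geometry <- function(x, ...) {
  cat(sprintf("<thorax_geometry> kind '%s': %d lung(s), %s heart; thorax area %.0f mm^2\n",
              x$kind, length(x$lungs), if (is.null(x$heart)) "no" else "1",
              contour_area(x$thorax)))
  invisible(x)
}

#' Effective thorax radius (mm): radius of the equal-area circle
#' @param g a `thorax_geometry` (or an `eit_contour`)
#' @export
effective_radius <- function(g) {
  c <- if (inherits(g, "thorax_geometry")) g$thorax else g
  sqrt(contour_area(c) / pi)
}

#' Rasterize a thorax geometry onto the EIT pixel grid
#'
#' Builds the `n x n` pixel grid spanning the tight axis-aligned bounding box
#' of the thorax contour, with one boolean mask per region. A pixel belongs to
#' a region iff its center lies inside the region's contour. Row 1 is the most
#' anterior row; column 1 is the animal's right side.
#'
#' @param g a `thorax_geometry`
#' @param n grid resolution per axis (32 for EIT images, 128 for
#'   reference-resolution aeration images)
#' @return a `pixel_grid`: list with `n`, `bbox` (xmin, xmax, ymin, ymax),
#'   `body_mask`, `lung_mask`, `heart_mask` (n x n logical matrices, rows =
#'   anterior to posterior), and pixel pitch `dx`, `dy` in mm.
#' @export
rasterize <- function(g, n = 32L) {
  stopifnot(inherits(g, "thorax_geometry"))
  v <- unclass(g$thorax)
  bbox <- c(xmin = min(v[, 1L]), xmax = max(v[, 1L]),
            ymin = min(v[, 2L]), ymax = max(v[, 2L]))
  dx <- (bbox[["xmax"]] - bbox[["xmin"]]) / n
  dy <- (bbox[["ymax"]] - bbox[["ymin"]]) / n
  xc <- bbox[["xmin"]] + (seq_len(n) - 0.5) * dx
  yc <- bbox[["ymin"]] + (seq_len(n) - 0.5) * dy
  # [row, col]: row follows y (anterior -> posterior), col follows x
  grid_x <- matrix(rep(xc, times = n), nrow = n, byrow = TRUE)
  grid_y <- matrix(rep(yc, times = n), nrow = n, byrow = FALSE)
  mask_of <- function(cnt) {
    if (is.null(cnt)) return(matrix(FALSE, n, n))
    m <- points_in_contour(as.vector(grid_x), as.vector(grid_y), cnt)
    matrix(m, n, n)
  }
  lung <- matrix(FALSE, n, n)
  for (l in g$lungs) lung <- lung | mask_of(l)
  structure(list(
    n = n, bbox = bbox, dx = dx, dy = dy,
    centers_x = xc, centers_y = yc,
    body_mask = mask_of(g$thorax),
    lung_mask = lung,
    heart_mask = mask_of(g$heart)
  ), class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %dx%d, body %d px, lung %d px, heart %d px\n",
              x$n, x$n, sum(x$body_mask), sum(x$lung_mask), sum(x$heart_mask)))
  invisible(x)
}

#' Map contours into another geometry's frame by centroid/area alignment
#'
#' Applies to `contours` the similarity transform (translation + uniform
#' scaling) that maps the thorax of `from` onto the thorax of `to`, i.e. aligns
#' centroids and equalizes thorax areas. Used to carry subject lung contours
#' into the averaged-model frame when masking averaged-model images.
#'
#' @param contours list of `eit_contour`s (or a single one)
#' @param from,to `thorax_geometry` objects
#' @return list of transformed contours (single contour if one was given)
#' @export
align_contours <- function(contours, from, to) {
  single <- is_contour(contours)
  if (single) contours <- list(contours)
  cf <- contour_centroid(from$thorax); ct <- contour_centroid(to$thorax)
  s <- sqrt(contour_area(to$thorax) / contour_area(from$thorax))
  out <- lapply(contours, function(cn) {
    v <- sweep(unclass(cn), 2L, cf)
    contour(sweep(v * s, 2L, ct, "+"), label = attr(cn, "label"))
  })
  if (single) out[[1L]] else out
}
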