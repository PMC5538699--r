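test_that("contour validation rejects degenerate input", {
  expect_error(contour(cbind(1:7, 1:7 * 0 + 1)), "8 vertices")
  # collinear points enclose no area
  expect_error(contour(cbind(1:8, 2 * (1:8))), "area")
  # bow-tie self-intersection
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2),
               c(-0.5, 1.5), c(-1, 1.2), c(-1, 0.8), c(-0.5, 0.2))
  expect_error(contour(bow), "self-intersecting")
})

test_that("normalize_contour recenters and rescales to area pi", {
  circ <- fix_circle(R = 1)
  nc <- normalize_contour(circ)
  # unit circle sampled by a polygon: similar shape, area scaled onto pi
  expect_equal(contour_area(nc), pi, tolerance = 1e-9)
  expect_lt(sqrt(sum(contour_centroid(nc)^2)), 1e-9)

  # square of side 2 at (5, -3), 8 vertices including edge midpoints
  sq <- contour(rbind(c(4, -4), c(5, -4), c(6, -4), c(6, -3),
                      c(6, -2), c(5, -2), c(4, -2), c(4, -3)))
  nsq <- normalize_contour(sq)
  expect_equal(contour_area(nsq), pi, tolerance = 1e-12)
  expect_equal(max(abs(unclass(nsq))) * 2, sqrt(pi), tolerance = 1e-12)
  expect_lt(sqrt(sum(contour_centroid(nsq)^2)), 1e-9)

  # random simple 12-gon against the shoelace oracle
  set.seed(7)
  for (k in 1:5) {
    r <- stats::runif(12, 0.5, 2)
    th <- sort(stats::runif(12, 0, 2 * pi))
    poly <- contour(cbind(r * cos(th) + 3, r * sin(th) - 2))
    np <- normalize_contour(poly)
    expect_equal(oracle_area(unclass(np)), pi, tolerance = 1e-9)
    expect_lt(sqrt(sum(oracle_centroid(unclass(np))^2)), 1e-9)
    # similarity: vertex-count and angular structure preserved
    expect_equal(nrow(np), nrow(poly))
  }
})

test_that("symmetric difference is zero for identical and translated shapes", {
  poly <- fix_circle()
  # exact clipping works on scaled integer coordinates; identical shapes
  # agree to the coordinate quantum
  expect_lt(symmetric_difference(poly, poly), 1e-5)
  shifted <- contour(sweep(unclass(poly), 2L, c(37.5, -12.25), "+"))
  expect_lt(symmetric_difference(poly, shifted), 1e-5)
})

test_that("symmetric difference of circle and equal-area square matches the scanline oracle", {
  circ <- fix_circle(n = 256L)
  s <- sqrt(pi) / 2
  sq <- contour(rbind(c(-s, -s), c(0, -s), c(s, -s), c(s, 0),
                      c(s, s), c(0, s), c(-s, s), c(-s, 0)))
  ds <- symmetric_difference(circ, sq)
  a <- unclass(normalize_contour(circ)); b <- unclass(normalize_contour(sq))
  ds_oracle <- 100 * oracle_symmdiff_area(a, b, nrows = 4096L) / pi
  expect_equal(ds, ds_oracle, tolerance = 0.1)
  # raster fallback agrees with the polygon-clipping path
  expect_equal(symmetric_difference(circ, sq, method = "raster", resolution = 1024L),
               ds, tolerance = 0.1)
})

test_that("symmetric difference is symmetric and similarity-invariant", {
  set.seed(3)
  r <- stats::runif(16, 0.7, 1.4)
  th <- sort(stats::runif(16, 0, 2 * pi))
  a <- contour(cbind(r * cos(th), r * sin(th)))
  b <- fix_circle(R = 1, n = 32L)
  ds <- symmetric_difference(a, b)
  expect_equal(symmetric_difference(b, a), ds, tolerance = 1e-9)
  # uniform scaling of either input is removed by normalization
  expect_equal(symmetric_difference(contour(unclass(a) * 3.7), b), ds,
               tolerance = 1e-9)
  # common rotation of both inputs
  ang <- 0.83
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  ar <- contour(unclass(a) %*% rot); br <- contour(unclass(b) %*% rot)
  expect_equal(symmetric_difference(ar, br), ds, tolerance = 0.05)
})

test_that("electrodes are equally spaced by arc length", {
  lay <- place_electrodes(fix_circle(), n = 32L)
  # on a circle, equal arc spacing = equal central angles of 2*pi/32
  ang <- atan2(lay$positions[, 2L], lay$positions[, 1L])
  gaps <- diff(sort(ang))
  expect_equal(gaps, rep(2 * pi / 32, 31L), tolerance = 1e-6)

  # general contour: arc gaps equal under the projection oracle
  set.seed(5)
  r <- 100 * (1 + 0.15 * cos(2 * seq(0, 2 * pi, length.out = 49L)[-49L]))
  th <- seq(0, 2 * pi, length.out = 49L)[-49L]
  blob <- contour(cbind(r * cos(th), r * sin(th)))
  lay2 <- place_electrodes(blob, n = 16L)
  s <- sort(oracle_arc_positions(lay2$positions, unclass(blob)))
  per <- sum(oracle_arc_gaps_len(unclass(blob)))
  gaps2 <- diff(c(s, s[1L] + per))
  expect_equal(gaps2, rep(per / 16, 16L), tolerance = 1e-6 * per)
})

test_that("equal-arc electrode placement on an ellipse is not angle-uniform", {
  th <- seq(0, 2 * pi, length.out = 513L)[-513L]
  ell <- contour(cbind(100 * cos(th), 50 * sin(th)))
  # with 4 electrodes from the minor axis, symmetry puts all on the axes;
  # with 8, the intermediate positions are arc-equal but NOT at parameter
  # angles of pi/4 multiples (arc length is not proportional to angle)
  lay <- place_electrodes(ell, n = 8L)
  tpar <- atan2(lay$positions[, 2L] / 50, lay$positions[, 1L] / 100) %% (2 * pi)
  frac <- (tpar / (pi / 4)) %% 1
  off <- pmin(frac, 1 - frac)
  expect_gt(max(off), 0.05)
  expect_error(place_electrodes(ell, n = 3L), "at least 4")
})

test_that("rasterize produces consistent masks", {
  g <- fix_circle_geometry()
  grid <- rasterize(g)
  expect_false(any(grid$lung_mask))
  # circle inscribed in its bounding box: cover fraction approx pi/4
  expect_equal(sum(grid$body_mask), (pi / 4) * 32^2, tolerance = 0.03 * 32^2 / ((pi / 4) * 32^2))

  ga <- make_phantom("averaged")
  grida <- rasterize(ga)
  expect_true(all(grida$body_mask[grida$lung_mask]))
  expect_true(all(grida$body_mask[grida$heart_mask]))

  # mask-count area vs polygon area for a convex contour spanning the grid
  area_px <- sum(grida$body_mask) * grida$dx * grida$dy
  expect_equal(area_px, contour_area(ga$thorax),
               tolerance = 0.05 * contour_area(ga$thorax))
})

test_that("anterior-posterior orientation of the grid follows y", {
  g <- make_phantom("averaged")
  grid <- rasterize(g, 64L)
  lung_rows <- which(rowSums(grid$lung_mask) > 0)
  heart_rows <- which(rowSums(grid$heart_mask) > 0)
  # the heart sits anterior (lower row indices) of the lung centroid rows
  expect_lt(mean(heart_rows), mean(lung_rows))
})
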