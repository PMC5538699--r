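# Shared fixtures (built once per test run) and independent oracles.

.fix <- new.env()

fix_circle <- function(R = 110, n = 64L) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  contour(R * cbind(cos(phi), sin(phi)), "thorax")
}

fix_circle_geometry <- function() {
  if (is.null(.fix$circle_geom))
    .fix$circle_geom <- thorax_geometry(fix_circle(), kind = "circular")
  .fix$circle_geom
}

# small circular mesh + scheme, reused across forward/inverse tests
fix_small_mesh <- function() {
  if (is.null(.fix$small_mesh))
    .fix$small_mesh <- build_mesh(fix_circle_geometry(), target_elements = 3000)
  .fix$small_mesh
}

fix_scheme <- function() skip4_scheme()

# small averaged-phantom mesh with organs
fix_organ_mesh <- function() {
  if (is.null(.fix$organ_mesh))
    .fix$organ_mesh <- build_mesh(make_phantom("averaged"), target_elements = 4000)
  .fix$organ_mesh
}

# calibrated small GREIT model on the averaged phantom (slow; built once)
fix_organ_model <- function(nf = 0.3) {
  key <- paste0("organ_model_", nf)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- train_model(make_phantom("averaged"),
                               greit_config(nf = nf),
                               mesh = fix_organ_mesh())
  }
  .fix[[key]]
}

# short noiseless simulated recording on the averaged phantom
fix_recording <- function(delta_sigma = 0.2) {
  key <- paste0("rec_", delta_sigma)
  if (is.null(.fix[[key]])) {
    b <- breathing_config(fs = 12, duration = 20, delta_sigma = delta_sigma,
                          noise_snr = 300, seed = 11L)
    .fix[[key]] <- simulate_recording(make_phantom("averaged"), b,
                                      recon_elements = 4000)
  }
  .fix[[key]]
}

# training-target set on the small circle mesh (uniform background)
fix_circle_targets <- function() {
  if (is.null(.fix$circle_targets)) {
    m <- fix_small_mesh()
    g <- fix_circle_geometry()
    J2 <- jacobian_2d(eit_jacobian(m, weighted_background(m, "uniform"),
                                   fix_scheme()), m)
    .fix$circle_targets <- make_training_targets(
      m, J2, rasterize(g), greit_config(background = "uniform"))
    .fix$circle_J2 <- J2
  }
  .fix$circle_targets
}

fix_circle_J2 <- function() {
  fix_circle_targets()
  .fix$circle_J2
}

# ---- independent oracles -----------------------------------------------------

# shoelace area/centroid, written independently of the package internals
oracle_area <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1L] * v[j, 2L] - v[j, 1L] * v[i, 2L]
  }
  unname(abs(s) / 2)
}

# closed-polyline segment lengths
oracle_arc_gaps_len <- function(v) {
  n <- nrow(v)
  sqrt(rowSums((v[c(2:n, 1L), , drop = FALSE] - v)^2))
}

oracle_centroid <- function(v) {
  n <- nrow(v)
  sx <- sy <- sa <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- v[i, 1L] * v[j, 2L] - v[j, 1L] * v[i, 2L]
    sa <- sa + cr
    sx <- sx + (v[i, 1L] + v[j, 1L]) * cr
    sy <- sy + (v[i, 2L] + v[j, 2L]) * cr
  }
  unname(c(sx, sy) / (3 * sa))
}

# even-odd point-in-polygon by ray casting (independent of sp)
oracle_in_poly <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# scanline symmetric-difference area of two normalized contours: per raster
# row, the in-A and in-B intervals are found from exact edge crossings and
# combined by interval arithmetic (different algorithm than polygon clipping).
oracle_symmdiff_area <- function(a, b, nrows = 4096L) {
  crossings <- function(v, y) {
    n <- nrow(v)
    x <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- v[j, 2L]; y2 <- v[i, 2L]
      if ((y1 > y) != (y2 > y)) {
        t <- (y - y1) / (y2 - y1)
        x <- c(x, v[j, 1L] + t * (v[i, 1L] - v[j, 1L]))
      }
      j <- i
    }
    sort(x)
  }
  measure <- function(x) if (length(x)) sum(x[seq(2, length(x), by = 2)] -
                                            x[seq(1, length(x), by = 2)]) else 0
  inter_measure <- function(xa, xb) {
    if (!length(xa) || !length(xb)) return(0)
    # clip each A interval against B intervals
    tot <- 0
    for (i in seq(1, length(xa), by = 2)) {
      for (j in seq(1, length(xb), by = 2)) {
        lo <- max(xa[i], xb[j]); hi <- min(xa[i + 1L], xb[j + 1L])
        if (hi > lo) tot <- tot + (hi - lo)
      }
    }
    tot
  }
  yr <- range(a[, 2L], b[, 2L])
  dy <- diff(yr) / nrows
  ys <- yr[1L] + (seq_len(nrows) - 0.5) * dy
  s <- 0
  for (y in ys) {
    xa <- crossings(a, y); xb <- crossings(b, y)
    s <- s + measure(xa) + measure(xb) - 2 * inter_measure(xa, xb)
  }
  s * dy
}

# arc-length coordinate of points lying on a closed polyline, by projecting
# each point onto its nearest contour segment
oracle_arc_positions <- function(pts, v) {
  n <- nrow(v)
  seg_from <- v
  seg_to <- v[c(2:n, 1L), , drop = FALSE]
  seg_len <- sqrt(rowSums((seg_to - seg_from)^2))
  cum <- c(0, cumsum(seg_len))
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    d <- seg_to - seg_from
    t <- ((p[1L] - seg_from[, 1L]) * d[, 1L] + (p[2L] - seg_from[, 2L]) * d[, 2L]) /
      (seg_len^2)
    t <- pmin(pmax(t, 0), 1)
    proj <- seg_from + d * t
    dist <- (proj[, 1L] - p[1L])^2 + (proj[, 2L] - p[2L])^2
    i <- which.min(dist)
    cum[i] + t[i] * seg_len[i]
  }, 0.0)
}
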