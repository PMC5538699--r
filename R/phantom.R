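#' Synthetic thorax phantoms
#'
#' Generates the three kinds of reconstruction geometry studied by the
#' package: `"circular"` (a circle, no organs — the no-prior model),
#' `"averaged"` (a fixed smooth pig-like thorax with two lungs and a heart,
#' defined by low-order Fourier descriptors) and `"individual"` (the averaged
#' geometry deformed by a seeded smooth radial perturbation of bounded
#' amplitude, organs deformed consistently so containment is preserved).
#'
#' The default perturbation amplitude produces shape mismatches (Delta-S)
#' between individual and averaged contours of roughly 3-8%, the scale of
#' inter-animal variation the geometry-mismatch metric is meant to resolve.
#'
#' @param kind phantom kind
#' @param seed integer seed for the individual perturbation
#' @param perturbation_amplitude radial perturbation amplitude as a fraction
#'   of the local radius (individual kind only)
#' @param scale thorax scale in mm (effective radius of the circular phantom;
#'   the averaged contour is defined at the same scale)
#' @param n_vertices vertices per generated contour
#' @return a [thorax_geometry()]
#' @export
make_phantom <- function(kind = c("circular", "averaged", "individual"),
                         seed = 1L, perturbation_amplitude = 0.04,
                         scale = 110, n_vertices = 64L) {
  kind <- match.arg(kind)
  phi <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  if (kind == "circular") {
    th <- contour(scale * cbind(cos(phi), sin(phi)), "thorax")
    return(thorax_geometry(th, kind = "circular"))
  }
  base <- averaged_phantom(scale, n_vertices)
  if (kind == "averaged") return(base)

  for (attempt in 0:9) {
    coef <- perturbation_field(seed + attempt * 7919L)
    g <- try(deform_geometry(base, coef, perturbation_amplitude), silent = TRUE)
    if (!inherits(g, "try-error")) {
      g$kind <- "individual"
      return(g)
    }
  }
  stop("phantom error: perturbation kept violating organ containment",
       call. = FALSE)
}

# Fixed averaged thorax: low-order Fourier radius about the origin, two
# elliptical lungs and a heart. Coordinates: x towards the animal's left,
# y anterior -> posterior.
averaged_phantom <- function(scale = 110, n_vertices = 64L) {
  phi <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- scale * (1 + 0.12 * cos(2 * phi) - 0.05 * sin(phi) + 0.02 * cos(3 * phi + 0.4))
  th <- contour(cbind(r * cos(phi), r * sin(phi)), "thorax")
  s <- scale / 110
  lung <- function(cx, cy, ax, ay, rot, lab) {
    t <- 2 * pi * (seq_len(48L) - 1L) / 48L
    x <- ax * cos(t); y <- ay * sin(t)
    contour(cbind(cx + x * cos(rot) - y * sin(rot),
                  cy + x * sin(rot) + y * cos(rot)) * 1, lab)
  }
  lungs <- list(
    lung(48 * s, 18 * s, 32 * s, 44 * s, -0.18, "lung_left"),
    lung(-48 * s, 18 * s, 32 * s, 44 * s, 0.18, "lung_right"))
  heart <- lung(8 * s, -38 * s, 24 * s, 20 * s, 0.1, "heart")
  thorax_geometry(th, lungs = lungs, heart = heart, kind = "averaged")
}

# Smooth random radial field: modes 2..5, coefficients ~ N(0, 1/k^2),
# normalized to unit standard deviation over the circle.
perturbation_field <- function(seed) {
  set.seed(seed)
  ks <- 2:5
  a <- stats::rnorm(length(ks), sd = 1 / ks)
  b <- stats::rnorm(length(ks), sd = 1 / ks)
  tg <- seq(0, 2 * pi, length.out = 721L)[-721L]
  h <- function(theta) {
    out <- 0
    for (i in seq_along(ks)) out <- out + a[i] * cos(ks[i] * theta) + b[i] * sin(ks[i] * theta)
    out
  }
  s <- stats::sd(h(tg))
  list(eval = function(theta) h(theta) / s)
}

# Radial map p -> c + (p - c) * (1 + eps*h(theta_p)) applied to every contour;
# preserves containment because points on a common ray scale together.
deform_geometry <- function(g, coef, eps) {
  ctr <- contour_centroid(g$thorax)
  warp <- function(cn) {
    v <- sweep(unclass(cn), 2L, ctr)
    theta <- atan2(v[, 2L], v[, 1L])
    f <- 1 + eps * coef$eval(theta)
    contour(sweep(v * f, 2L, ctr, "+"), label = attr(cn, "label"))
  }
  thorax_geometry(warp(g$thorax), lungs = lapply(g$lungs, warp),
                  heart = if (!is.null(g$heart)) warp(g$heart),
                  kind = g$kind)
}

#' Breathing and acquisition configuration for simulated recordings
#'
#' @param f_resp respiratory rate (breaths per minute)
#' @param fs EIT sampling rate (Hz)
#' @param duration recording length (s)
#' @param delta_sigma peak relative conductivity decrease in the lungs at
#'   end-inspiration (0.2 = 20% swing, small enough for approximate
#'   linearity of the difference signal)
#' @param ap_gradient anteroposterior ventilation asymmetry: the local
#'   aeration swing varies linearly from `1 - g/2` (anterior lung edge) to
#'   `1 + g/2` (posterior lung edge) before normalization, mimicking the
#'   gravity-dependent distribution in supine animals
#' @param noise_snr additive white Gaussian channel-noise level, as signal-
#'   to-noise ratio in dB relative to the RMS breathing-induced voltage swing
#' @param sim_mesh_refinement element-count factor of the simulation mesh
#'   relative to the default reconstruction mesh (inverse-crime guard)
#' @param seed noise seed
#' @return a `breathing_config`
#' @export
breathing_config <- function(f_resp = 6, fs = 48, duration = 30,
                             delta_sigma = 0.2, ap_gradient = 0.3,
                             noise_snr = 50, sim_mesh_refinement = 2,
                             seed = 1L) {
  if (fs <= 2 * f_resp / 60) stop("invalid argument: fs must exceed twice the breathing frequency", call. = FALSE)
  if (duration < 1.5 * 60 / f_resp) stop("invalid argument: need at least 1.5 breaths", call. = FALSE)
  if (sim_mesh_refinement < 2) stop("invalid argument: sim_mesh_refinement must be >= 2", call. = FALSE)
  structure(list(f_resp = f_resp, fs = fs, duration = duration,
                 delta_sigma = delta_sigma, ap_gradient = ap_gradient,
                 noise_snr = noise_snr, sim_mesh_refinement = sim_mesh_refinement,
                 seed = as.integer(seed)),
            class = "breathing_config")
}

#' Simulate a breathing-driven EIT recording with ground truth
#'
#' Lung conductivity is modulated as
#' `sigma(t) = sigma_lung0 * (1 - a(y) * delta_sigma * g(t))` with breath
#' amplitude `g(t) = (1 - cos(2 pi f t)) / 2` and a linear anteroposterior
#' weighting `a(y)` (volume-weighted mean 1 over the lung). The forward
#' problem is solved on a refined mesh (distinct node lattice from any
#' reconstruction mesh) at 9 amplitude knots and channel voltages are
#' spline-interpolated over the amplitude for every frame; white Gaussian
#' noise is added at the configured SNR.
#'
#' The ground truth is the 128x128 tidal aeration image: the per-pixel
#' conductivity swing between end-expiration and end-inspiration (positive,
#' arbitrary units, supported on the lung mask), together with its
#' anteroposterior profile.
#'
#' @param g a [thorax_geometry()] with lungs
#' @param b a [breathing_config()]
#' @param scheme stimulation scheme
#' @param recon_elements element count of the reference reconstruction mesh
#'   that `sim_mesh_refinement` multiplies
#' @return list with `series` (a [voltage_series()]), `truth` (list:
#'   `tidal`, `grid`, `vd_truth`, `a_weight`), and `mesh` (the simulation
#'   mesh)
#' @export
simulate_recording <- function(g, b = breathing_config(),
                               scheme = skip4_scheme(),
                               recon_elements = 20000L) {
  stopifnot(inherits(g, "thorax_geometry"))
  if (!length(g$lungs)) stop("geometry has no lungs to ventilate", call. = FALSE)
  stopifnot(inherits(b, "breathing_config"))

  m <- build_mesh(g, target_elements = round(b$sim_mesh_refinement * recon_elements),
                  lattice_offset = c(0.37, 0.19))
  sigma0 <- weighted_background(m, "weighted")
  lung <- m$elem_region == "lung"
  ec_y <- (m$nodes[m$elems[, 1L], 2L] + m$nodes[m$elems[, 2L], 2L] +
           m$nodes[m$elems[, 3L], 2L] + m$nodes[m$elems[, 4L], 2L]) / 4
  aw <- ap_weight(ec_y[lung], g, b$ap_gradient, weights = m$volumes[lung])

  knots <- seq(0, 1, length.out = 9L)
  cache <- cem_cache(m)
  V <- vapply(knots, function(gk) {
    s <- sigma0
    s[lung] <- sigma0[lung] * (1 - aw * b$delta_sigma * gk)
    as.numeric(solve_forward(m, s, scheme, cache = cache))
  }, numeric(length(scheme$valid)))

  nt <- round(b$duration * b$fs)
  t <- (seq_len(nt) - 1L) / b$fs
  gt <- (1 - cos(2 * pi * b$f_resp / 60 * t)) / 2
  valid <- scheme$valid
  Vt <- matrix(NA_real_, nt, length(valid))
  for (c_ in which(valid)) {
    Vt[, c_] <- stats::spline(knots, V[c_, ], xout = gt, method = "natural")$y
  }
  # additive channel noise at the configured SNR on the breathing swing
  swing <- sqrt(mean(apply(Vt[, valid, drop = FALSE], 2L, stats::var)))
  sd_n <- swing / 10^(b$noise_snr / 20)
  set.seed(b$seed)
  Vt[, valid] <- Vt[, valid] + stats::rnorm(nt * sum(valid), sd = sd_n)

  truth <- ground_truth_tidal(g, b)
  list(series = voltage_series(Vt, fs = b$fs, valid = valid),
       truth = truth, mesh = m, config = b)
}

# Linear anteroposterior weighting over the lung extent, normalized to
# (weighted) mean 1.
ap_weight <- function(y, g, gradient, weights = NULL, y_range = NULL) {
  if (is.null(y_range)) {
    ys <- unlist(lapply(g$lungs, function(l) unclass(l)[, 2L]))
    y_range <- range(ys)
  }
  yt <- (y - y_range[1L]) / diff(y_range)
  raw <- pmax(1 + gradient * (yt - 0.5), 0.05)
  if (is.null(weights)) weights <- rep(1, length(y))
  raw / stats::weighted.mean(raw, weights)
}

# 128x128 ground-truth tidal aeration image and its profile
ground_truth_tidal <- function(g, b, n = 128L) {
  grid <- rasterize(g, n)
  img <- matrix(0, n, n)
  if (any(grid$lung_mask)) {
    yy <- matrix(rep(grid$centers_y, times = n), n, n)  # row = y index
    aw <- ap_weight(yy[grid$lung_mask], g, b$ap_gradient)
    img[grid$lung_mask] <- aw * b$delta_sigma * 0.2  # sigma_lung0 = 0.2
  }
  list(tidal = img, grid = grid,
       vd_truth = if (any(img > 0)) ap_profile(img, grid$lung_mask),
       ap_gradient = b$ap_gradient)
}

#' Simulate a cohort of subjects
#'
#' Builds `n` individual phantoms (one per subject) plus the shared averaged
#' and circular geometries, and simulates one breathing recording with ground
#' truth per subject on its individual geometry.
#'
#' @param n number of subjects
#' @param seed master seed; per-subject phantom and noise seeds are derived
#'   from it
#' @param breathing a [breathing_config()] template (per-subject noise seeds
#'   override its `seed`)
#' @param recon_elements reference reconstruction mesh size the simulation
#'   refinement multiplies (see [simulate_recording()])
#' @param ... passed to [make_phantom()] for the individual phantoms
#' @return a `cohort` list: `subjects` (each with `geometry`, `recording`,
#'   `truth`, `seed`), `averaged`, `circular`
#' @export
cohort <- function(n = 8L, seed = 1L, breathing = breathing_config(),
                   recon_elements = 20000L, ...) {
  stopifnot(n >= 1L)
  averaged <- make_phantom("averaged")
  circular <- make_phantom("circular")
  subjects <- lapply(seq_len(n), function(i) {
    s_i <- seed * 1000L + i
    geom <- make_phantom("individual", seed = s_i, ...)
    bc <- breathing
    bc$seed <- s_i + 500L
    rec <- simulate_recording(geom, bc, recon_elements = recon_elements)
    list(geometry = geom, recording = rec$series, truth = rec$truth,
         sim_mesh = rec$mesh, seed = s_i)
  })
  structure(list(subjects = subjects, averaged = averaged, circular = circular,
                 seed = seed), class = "eit_cohort")
}

#' @export
print.eit_cohort <- function(x, ...) {
  cat(sprintf("<eit_cohort> %d subjects (seed %d)\n", length(x$subjects), x$seed))
  invisible(x)
}
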