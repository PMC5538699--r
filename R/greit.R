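#' GREIT reconstruction configuration
#'
#' @param nf noise figure the regularization is calibrated to (> 0)
#' @param ts training target radius as a fraction of the effective thorax
#'   radius
#' @param rw desired-image (weighting) radius as a fraction of the effective
#'   thorax radius
#' @param background `"uniform"` or `"weighted"` conductivity background for
#'   the training forward model
#' @param reference voltage referencing the matrix is trained for: `"TD"`
#'   (time difference) or `"NTD"` (normalized time difference)
#' @return a `greit_config`
#' @export
greit_config <- function(nf = 0.15, ts = 0.06, rw = 0.15,
                         background = c("weighted", "uniform"),
                         reference = c("TD", "NTD")) {
  stopifnot(nf > 0, ts > 0, ts < 1, rw > 0, rw < 1)
  structure(list(algorithm = "GREIT", nf = nf, ts = ts, rw = rw,
                 background = match.arg(background),
                 reference = match.arg(reference)),
            class = c("greit_config", "recon_config"))
}

#' Gauss-Newton reconstruction configuration
#'
#' @inheritParams greit_config
#' @param prior regularization prior: `"Laplace"` (adjacency-graph Laplacian),
#'   `"Tikhonov"` (identity) or `"NOSER"` (diagonal of J'J)
#' @return a `gn_config`
#' @export
gn_config <- function(nf = 0.15, prior = c("Laplace", "Tikhonov", "NOSER"),
                      background = c("weighted", "uniform"),
                      reference = c("TD", "NTD")) {
  stopifnot(nf > 0)
  structure(list(algorithm = "GN", nf = nf, prior = match.arg(prior),
                 background = match.arg(background),
                 reference = match.arg(reference)),
            class = c("gn_config", "recon_config"))
}

#' @export
print.recon_config <- function(x, ...) {
  cat("<", x$algorithm, "> ", paste(names(x)[-1L],
      vapply(x[-1L], format, ""), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Training target set for GREIT
#'
#' Places one small conductivity target at every pixel center inside the body
#' mask (optionally thinned by `spacing`), simulates its voltage signature
#' through the linearized forward map, and builds the desired disc image of
#' radius `rw` around each target.
#'
#' Targets are conductivity decreases (contrast -1, mimicking inflation) so
#' that ventilation appears positive in reconstructed tidal images.
#'
#' @param m an `eit_mesh`
#' @param J2 Jacobian on the 2D element basis ([jacobian_2d()]), computed at
#'   the configuration's background conductivity
#' @param grid pixel grid of the mesh geometry
#' @param cfg a [greit_config()]
#' @param spacing pixel stride between target centers (1 = every pixel)
#' @return a `training_targets` list: `centers`, `Y` (signatures, channels x
#'   targets), `X` (desired images, pixels x targets), `y_ref` (signature of a
#'   central target, the noise-figure reference signal), `R_eff`.
#' @export
make_training_targets <- function(m, J2, grid, cfg, spacing = 1L) {
  stopifnot(inherits(cfg, "greit_config"))
  n <- grid$n
  R_eff <- effective_radius(m$geometry)
  r_t <- cfg$ts * R_eff
  r_w <- cfg$rw * R_eff

  rows <- seq(1L, n, by = spacing)
  sel <- as.matrix(expand.grid(row = rows, col = rows))
  inside <- grid$body_mask[sel]
  sel <- sel[inside, , drop = FALSE]
  if (!nrow(sel)) stop("invalid argument: no training targets in body", call. = FALSE)
  cx <- grid$centers_x[sel[, "col"]]
  cy <- grid$centers_y[sel[, "row"]]

  ec <- tri_centroids(m)
  ea <- tri_areas(m)
  Y <- signature_matrix(J2, ec, cx, cy, r_t, ea)

  # desired images: hard discs of radius rw, clipped to the body
  # row-major pixel order: index = (row-1)*n + col -> col varies fastest
  px <- rep(grid$centers_x, times = n)
  py <- rep(grid$centers_y, each = n)
  body <- as.vector(t(grid$body_mask))
  X <- vapply(seq_len(nrow(sel)), function(k) {
    as.numeric(((px - cx[k])^2 + (py - cy[k])^2 <= r_w^2) & body)
  }, numeric(n * n))

  ctr <- contour_centroid(m$geometry$thorax)
  y_ref <- signature_matrix(J2, ec, ctr[1L], ctr[2L], r_t, ea)[, 1L]

  structure(list(centers = cbind(x = cx, y = cy), Y = Y, X = X,
                 y_ref = y_ref, R_eff = R_eff, grid = grid, cfg = cfg),
            class = "training_targets")
}

tri_centroids <- function(m) {
  p <- m$nodes2d; t <- m$tris2d
  cbind((p[t[, 1L], 1L] + p[t[, 2L], 1L] + p[t[, 3L], 1L]) / 3,
        (p[t[, 1L], 2L] + p[t[, 2L], 2L] + p[t[, 3L], 2L]) / 3)
}

# Voltage signatures of disc targets with contrast -1: Y[,k] = J2 %*% x_k,
# where x_k holds (minus) the fraction of element e covered by the target
# disc. The fraction is approximated by the lens overlap of the target disc
# with the equal-area disc of the element around its centroid — smooth in the
# target radius and exact in the contained limits, so signatures stay well
# defined when the target radius is below the element size (small ts on
# desk-scale meshes).
signature_matrix <- function(J2, ec, cx, cy, r_t, areas) {
  K <- length(cx)
  re <- sqrt(areas / pi)
  ind <- vapply(seq_len(K), function(k) {
    d <- sqrt((ec[, 1L] - cx[k])^2 + (ec[, 2L] - cy[k])^2)
    -circle_overlap(r_t, re, d) / areas
  }, numeric(nrow(ec)))
  as.matrix(J2 %*% ind)
}

# vectorized area of intersection of circles with radii r1, r2 at distance d
circle_overlap <- function(r1, r2, d) {
  out <- numeric(length(d))
  lo <- d <= abs(r1 - r2)
  out[lo] <- pi * pmin(r1, r2[lo])^2
  mid <- !lo & d < r1 + r2
  if (any(mid)) {
    dd <- d[mid]; rr2 <- r2[mid]
    a1 <- r1^2 * acos(pmin(pmax((dd^2 + r1^2 - rr2^2) / (2 * dd * r1), -1), 1))
    a2 <- rr2^2 * acos(pmin(pmax((dd^2 + rr2^2 - r1^2) / (2 * dd * rr2), -1), 1))
    s <- pmax((r1 + rr2 - dd) * (dd + r1 - rr2) * (dd - r1 + rr2) * (dd + r1 + rr2), 0)
    out[mid] <- a1 + a2 - sqrt(s) / 2
  }
  out
}

#' Train a GREIT reconstruction matrix
#'
#' Solves the regularized linear regression `R = X Y' (Y Y' + lambda Sigma)^-1`
#' mapping simulated target signatures `Y` to desired disc images `X`, with
#' `Sigma` the channel noise covariance (identity by default).
#'
#' @param targets a [make_training_targets()] set
#' @param lambda regularization weight (>= 0)
#' @param noise_cov per-channel noise variances (diagonal covariance), default
#'   identity
#' @return a `recon_matrix` (see [reconstruction_matrix()])
#' @export
greit_train <- function(targets, lambda, noise_cov = NULL) {
  tr <- greit_trainer(targets, noise_cov)
  tr$matrix_at(lambda)
}

# Shared precomputation for fast retraining across lambda (eigendecomposition
# of Y Y'). Returns closures used by the calibration loop.
greit_trainer <- function(targets, noise_cov = NULL) {
  Y <- targets$Y
  X <- targets$X
  nch <- nrow(Y)
  sn <- if (is.null(noise_cov)) rep(1, nch) else noise_cov
  stopifnot(length(sn) == nch, all(sn > 0))
  # transform so the penalty becomes lambda * I
  s <- sqrt(sn)
  Yt <- Y / s
  eg <- eigen(tcrossprod(Yt), symmetric = TRUE)
  U <- eg$vectors
  dvals <- pmax(eg$values, 0)
  B <- X %*% crossprod(Yt, U)      # pixels x channels
  y_ref <- targets$y_ref
  body <- as.vector(t(targets$grid$body_mask))

  # lambda = 0 falls back to the pseudo-inverse (null directions dropped)
  coefs <- function(lambda) {
    if (lambda == 0) {
      ifelse(dvals > 1e-12 * max(dvals), 1 / dvals, 0)
    } else 1 / (dvals + lambda)
  }
  unit_noise <- all(s == 1)
  # closed-form noise figure at lambda (see noise_figure() for the formula)
  nf_at <- function(lambda) {
    w <- coefs(lambda)
    Bw <- sweep(B, 2L, w, "*")
    if (unit_noise) {
      rown <- sqrt(rowSums(Bw^2))                # row norms of R in U-basis
      img <- Bw %*% crossprod(U, y_ref / s)
    } else {
      R <- sweep(Bw %*% t(U), 2L, s, "/")
      rown <- sqrt(rowSums(R^2))
      img <- R %*% y_ref
    }
    mean(rown[body]) * mean(abs(y_ref)) / mean(abs(img[body]))
  }
  matrix_at <- function(lambda, achieved_nf = NULL) {
    w <- coefs(lambda)
    R <- sweep(B, 2L, w, "*") %*% t(U)
    R <- sweep(R, 2L, s, "/")      # undo channel scaling: acts on raw voltages
    reconstruction_matrix(R, targets$grid, targets$cfg, lambda = lambda,
                          nf = if (is.null(achieved_nf)) NULL else achieved_nf,
                          y_ref = y_ref)
  }
  list(nf_at = nf_at, matrix_at = matrix_at)
}

#' Reconstruction matrix container
#'
#' Linear map from valid measurement channels to the 1024-pixel image, with
#' zero rows outside the body mask.
#'
#' @param R matrix (n_pixels x n_valid_channels)
#' @param grid pixel grid
#' @param cfg the generating `recon_config`
#' @param lambda regularization weight used
#' @param nf achieved noise figure (if calibrated)
#' @param y_ref noise-figure reference signal
#' @export
reconstruction_matrix <- function(R, grid, cfg, lambda = NA_real_, nf = NULL,
                                  y_ref = NULL) {
  structure(list(R = R, grid = grid, config = cfg, lambda = lambda,
                 nf = nf, y_ref = y_ref),
            class = "recon_matrix")
}

#' @export
print.recon_matrix <- function(x, ...) {
  cat(sprintf("<recon_matrix> %s: %d px x %d ch, lambda=%.3g%s\n",
              x$config$algorithm, nrow(x$R), ncol(x$R), x$lambda,
              if (!is.null(x$nf)) sprintf(", nf=%.4f", x$nf) else ""))
  invisible(x)
}

#' Noise figure of a reconstruction matrix
#'
#' Ratio of the noise amplification to the signal amplification of the map:
#' `nf = [mean|R n| / mean|n|] / [mean|R y_c| / mean|y_c|]`, in expectation
#' over i.i.d. unit-variance Gaussian channel noise `n`, with `y_c` the
#' signature of a small central target. The expectation is evaluated in closed
#' form from the row norms of `R` (`E|R n|_i = sqrt(2/pi) ||R_i||`, and the
#' same factor for `E|n|`, so the factors cancel); image means are taken over
#' in-body pixels only. Absolute values depend on this convention.
#'
#' @param rm a `recon_matrix`
#' @param ref_signal reference signal (defaults to the stored `y_ref`)
#' @return the noise figure (dimensionless, scale-invariant in `R`)
#' @export
noise_figure <- function(rm, ref_signal = NULL) {
  y <- if (is.null(ref_signal)) rm$y_ref else ref_signal
  if (is.null(y) || all(y == 0))
    stop("invalid argument: zero reference signal", call. = FALSE)
  body <- as.vector(t(rm$grid$body_mask))
  rown <- sqrt(rowSums(rm$R^2))
  img <- as.vector(rm$R %*% y)
  mean(rown[body]) * mean(abs(y)) / mean(abs(img[body]))
}

#' Calibrate the regularization weight to a target noise figure
#'
#' Locates the regularization weight whose noise figure matches the target:
#' the noise figure is evaluated on a log-spaced lambda grid over the
#' bracket, the sub-interval containing the smallest-lambda crossing of the
#' target (the least-regularized matching solution) is selected, and
#' bisection on log(lambda) refines it until the achieved noise figure is
#' within `tol` relative of the target. The noise figure decreases with
#' lambda over the operating branch; the initial grid guards against the
#' shallow non-monotonic tail at very strong regularization.
#'
#' @param nf_fun function lambda -> noise figure
#' @param target_nf requested noise figure
#' @param bracket lambda search interval
#' @param tol relative tolerance on the achieved noise figure
#' @param max_iter bisection iteration cap
#' @param n_scan size of the initial log-spaced lambda grid
#' @return list(lambda, nf, iterations)
#' @export
calibrate_nf <- function(nf_fun, target_nf, bracket = c(1e-8, 1e4),
                         tol = 0.01, max_iter = 60L, n_scan = 25L) {
  lg <- seq(log(bracket[1L]), log(bracket[2L]), length.out = n_scan)
  fg <- vapply(lg, function(l) nf_fun(exp(l)), 0.0)
  hit <- which.min(abs(fg - target_nf))
  if (abs(fg[hit] - target_nf) / target_nf < tol)
    return(list(lambda = exp(lg[hit]), nf = fg[hit], iterations = 0L))
  cross <- which(diff(sign(fg - target_nf)) != 0)
  if (!length(cross))
    stop(sprintf(
      "calibration error: target nf %.4g outside achievable range [%.4g, %.4g]",
      target_nf, min(fg), max(fg)), call. = FALSE)
  i <- cross[1L]
  lo <- lg[i]; hi <- lg[i + 1L]
  decreasing <- fg[i] > fg[i + 1L]
  it <- 0L
  repeat {
    mid <- (lo + hi) / 2
    f <- nf_fun(exp(mid))
    it <- it + 1L
    if (abs(f - target_nf) / target_nf < tol || it >= max_iter) break
    above <- f > target_nf
    if (above == decreasing) lo <- mid else hi <- mid
  }
  if (abs(f - target_nf) / target_nf >= tol)
    stop("calibration error: bisection did not reach target nf", call. = FALSE)
  list(lambda = exp(mid), nf = f, iterations = it)
}

#' Build a calibrated GREIT reconstruction matrix for a geometry
#'
#' Full training stack: electrode layout, mesh, background conductivity,
#' Jacobian, training targets, and noise-figure calibration of the
#' regularization weight.
#'
#' @param g a [thorax_geometry()]
#' @param cfg a [greit_config()] or [gn_config()]
#' @param target_elements mesh size for the reconstruction model
#' @param scheme stimulation scheme (skip-4 by default)
#' @param mesh optional prebuilt mesh (overrides `target_elements`)
#' @param J2 optional precomputed 2D Jacobian for `mesh` at the config's
#'   background (with `v0` attribute)
#' @return a calibrated `recon_matrix`; its `mesh` field holds the model mesh
#' @export
train_model <- function(g, cfg = greit_config(), target_elements = 20000L,
                        scheme = skip4_scheme(), mesh = NULL, J2 = NULL) {
  m <- if (is.null(mesh)) build_mesh(g, target_elements = target_elements) else mesh
  grid <- rasterize(g)
  if (is.null(J2)) {
    sigma <- weighted_background(m, cfg$background)
    J <- eit_jacobian(m, sigma, scheme)
    J2 <- jacobian_2d(J, m)
  }
  if (cfg$reference == "NTD") {
    v0 <- attr(J2, "v0")[attr(J2, "valid")]
    J2r <- J2 / v0
    attr(J2r, "valid") <- attr(J2, "valid"); attr(J2r, "v0") <- attr(J2, "v0")
    J2 <- J2r
  }
  rm <- if (inherits(cfg, "greit_config")) {
    tg <- make_training_targets(m, J2, grid, cfg)
    tr <- greit_trainer(tg)
    cal <- calibrate_nf(tr$nf_at, cfg$nf)
    tr$matrix_at(cal$lambda, achieved_nf = cal$nf)
  } else {
    tr <- gn_trainer(m, J2, grid, cfg)
    cal <- calibrate_nf(tr$nf_at, cfg$nf)
    tr$matrix_at(cal$lambda, achieved_nf = cal$nf)
  }
  rm$mesh <- m
  rm$valid <- attr(J2, "valid")
  rm
}
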