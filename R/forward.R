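#' Skip-4 stimulation and measurement scheme
#'
#' Pairwise current injection and voltage measurement with four electrodes
#' skipped between the members of each pair: drive `k` injects between
#' electrodes `k` and `k+5` (mod n), and measurement `j` of each drive is taken
#' between electrodes `j` and `j+5` (mod n). A measurement channel is invalid
#' iff its pair shares an electrode with the driving pair, which for n = 32
#' leaves 29 valid measurements per drive (928 of the 1024 channels).
#'
#' @param n_electrodes electrode count (32 for the supported belt; other
#'   counts are allowed for testing)
#' @param amplitude injected current in mA
#' @param skip number of skipped electrodes (4 for the supported pattern)
#' @return a `stim_scheme`: list with `drives` (n x 2, 1-based electrode
#'   indices), `meas` (n x 2), `valid` (length n^2 logical in channel order
#'   drive-major), `n_electrodes`, `amplitude`.
#' @export
skip4_scheme <- function(n_electrodes = 32L, amplitude = 3, skip = 4L) {
  if (amplitude <= 0) stop("invalid argument: amplitude must be > 0", call. = FALSE)
  n <- as.integer(n_electrodes)
  step <- as.integer(skip) + 1L
  pairs <- cbind(seq_len(n), (seq_len(n) - 1L + step) %% n + 1L)
  valid <- logical(n * n)
  for (k in seq_len(n)) {
    dk <- pairs[k, ]
    share <- pairs[, 1L] %in% dk | pairs[, 2L] %in% dk
    valid[(k - 1L) * n + seq_len(n)] <- !share
  }
  structure(list(drives = pairs, meas = pairs, valid = valid,
                 n_electrodes = n, skip = as.integer(skip),
                 amplitude = amplitude),
            class = "stim_scheme")
}

#' @export
print.stim_scheme <- function(x, ...) {
  cat(sprintf("<stim_scheme> %d electrodes, skip %d, %.1f mA; %d/%d valid channels\n",
              x$n_electrodes, x$skip, x$amplitude, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Tissue-weighted background conductivity
#'
#' Relative (dimensionless) per-element conductivity: `uniform` sets every
#' element to 1; `weighted` sets lung elements to 0.2 and heart elements to
#' 1.5 to account for their different conductivities.
#'
#' @param m an `eit_mesh`
#' @param mode `"uniform"` or `"weighted"`
#' @export
weighted_background <- function(m, mode = c("uniform", "weighted")) {
  mode <- match.arg(mode)
  sigma <- rep(1, nrow(m$elems))
  if (mode == "weighted") {
    if (!any(m$elem_region != "background"))
      stop("invalid argument: weighted background needs organ labels", call. = FALSE)
    sigma[m$elem_region == "lung"] <- 0.2
    sigma[m$elem_region == "heart"] <- 1.5
  }
  sigma
}

# ---- complete-electrode-model assembly --------------------------------------

# Per-element shape-function gradients and volumes for linear tetrahedra.
# Returns list(grads: n_elem x 4 x 3 array, vol: n_elem).
tet_gradients <- function(m) {
  e <- m$elems
  p1 <- m$nodes[e[, 1L], , drop = FALSE]
  p2 <- m$nodes[e[, 2L], , drop = FALSE]
  p3 <- m$nodes[e[, 3L], , drop = FALSE]
  p4 <- m$nodes[e[, 4L], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c_ <- p4 - p1
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
         a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
         a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  # rows of inverse Jacobian give gradients of barycentric coords 2..4
  cross <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  g2 <- cross(b, c_) / det
  g3 <- cross(c_, a) / det
  g4 <- cross(a, b) / det
  g1 <- -(g2 + g3 + g4)
  grads <- array(0, dim = c(nrow(e), 4L, 3L))
  grads[, 1L, ] <- g1; grads[, 2L, ] <- g2; grads[, 3L, ] <- g3; grads[, 4L, ] <- g4
  list(grads = grads, vol = abs(det) / 6)
}

# Assemble the CEM system for per-element conductivity sigma.
# Unknowns: node potentials (N), electrode potentials (E), one Lagrange
# multiplier enforcing sum of electrode potentials = 0 (grounding).
assemble_cem <- function(m, sigma, z_contact = 1e4, cache = NULL) {
  n_nodes <- nrow(m$nodes)
  n_el <- length(m$elec_faces)
  if (length(sigma) != nrow(m$elems))
    stop("sigma length must equal element count", call. = FALSE)
  if (any(sigma <= 0)) stop("solver error: non-positive conductivity", call. = FALSE)

  if (is.null(cache)) cache <- cem_cache(m)
  gv <- cache$gv
  vol <- gv$vol
  dim_tot <- n_nodes + n_el + 1L
  # volume stiffness: K[i,j] += sigma*vol * grad_i . grad_j
  K <- Matrix::sparseMatrix(i = cache$ii, j = cache$jj,
                            x = rep(sigma, 16L) * cache$gfac,
                            dims = c(dim_tot, dim_tot))
  K <- K + cache$bc$M / z_contact
  # grounding: sum of electrode potentials = 0 via Lagrange multiplier
  gi <- n_nodes + seq_len(n_el)
  lam <- dim_tot
  K <- K + Matrix::sparseMatrix(i = c(rep(lam, n_el), gi),
                                j = c(gi, rep(lam, n_el)),
                                x = rep(1, 2L * n_el),
                                dims = c(dim_tot, dim_tot))
  list(K = K, n_nodes = n_nodes, n_el = n_el, gv = gv, bc = cache$bc)
}

# conductivity-independent assembly precomputation (shape gradients,
# stiffness triplet pattern, electrode boundary matrix)
cem_cache <- function(m) {
  gv <- tet_gradients(m)
  n_nodes <- nrow(m$nodes)
  n_el <- length(m$elec_faces)
  ii <- jj <- gg <- vector("list", 16L)
  idx <- 1L
  for (i in 1:4) for (j in 1:4) {
    ii[[idx]] <- m$elems[, i]
    jj[[idx]] <- m$elems[, j]
    gg[[idx]] <- gv$vol * rowSums(gv$grads[, i, ] * gv$grads[, j, ])
    idx <- idx + 1L
  }
  list(gv = gv, ii = unlist(ii), jj = unlist(jj), gfac = unlist(gg),
       bc = cem_boundary(m, n_nodes, n_el))
}

# Conductivity-independent electrode boundary matrix (unit contact impedance):
# 1/z * [ \int phi_i phi_j, -\int phi_i, |E_l| ] terms on each electrode.
cem_boundary <- function(m, n_nodes, n_el) {
  ii <- jj <- xx <- list()
  k <- 1L
  for (l in seq_len(n_el)) {
    f <- m$elec_faces[[l]]
    p1 <- m$nodes[f[, 1L], , drop = FALSE]
    p2 <- m$nodes[f[, 2L], , drop = FALSE]
    p3 <- m$nodes[f[, 3L], , drop = FALSE]
    u <- p2 - p1; v <- p3 - p1
    cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    area <- sqrt(rowSums(cr^2)) / 2
    el_col <- n_nodes + l
    for (i in 1:3) for (j in 1:3) {
      ii[[k]] <- f[, i]; jj[[k]] <- f[, j]
      xx[[k]] <- area / ifelse(i == j, 6, 12)
      k <- k + 1L
    }
    for (i in 1:3) {
      ii[[k]] <- f[, i]; jj[[k]] <- rep(el_col, nrow(f)); xx[[k]] <- -area / 3; k <- k + 1L
      ii[[k]] <- rep(el_col, nrow(f)); jj[[k]] <- f[, i]; xx[[k]] <- -area / 3; k <- k + 1L
    }
    ii[[k]] <- el_col; jj[[k]] <- el_col; xx[[k]] <- sum(area); k <- k + 1L
  }
  dim_tot <- n_nodes + n_el + 1L
  list(M = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                dims = c(dim_tot, dim_tot)))
}

#' Solve the complete-electrode-model forward problem
#'
#' Computes electrode potentials for every drive of the stimulation scheme and
#' assembles the measured channel voltages. The model includes per-electrode
#' contact impedance and is grounded by constraining the electrode potentials
#' to zero sum.
#'
#' @param m an `eit_mesh`
#' @param sigma per-element relative conductivity (all > 0)
#' @param scheme a [skip4_scheme()]
#' @param z_contact contact impedance (Ohm mm^2), default 1e4 (= 100 Ohm cm^2)
#' @param full also return node potentials per drive (needed for sensitivity
#'   computations)
#' @param cache precomputed conductivity-independent assembly data (internal;
#'   reused across repeated solves on the same mesh)
#' @return a `voltage_frame`: numeric vector of length `n^2` in drive-major
#'   channel order with `NA` in invalid slots, with attributes `valid` and
#'   (if `full`) the potential fields.
#' @export
solve_forward <- function(m, sigma, scheme, z_contact = 1e4, full = FALSE,
                          cache = NULL) {
  sys <- assemble_cem(m, sigma, z_contact, cache = cache)
  n <- scheme$n_electrodes
  if (length(m$elec_faces) != n)
    stop("scheme/mesh electrode count mismatch", call. = FALSE)
  B <- matrix(0, nrow(sys$K), n)
  amp <- scheme$amplitude
  for (k in seq_len(n)) {
    B[sys$n_nodes + scheme$drives[k, 1L], k] <- amp
    B[sys$n_nodes + scheme$drives[k, 2L], k] <- -amp
  }
  U <- tryCatch(as.matrix(Matrix::solve(sys$K, B)),
                error = function(e) stop("solver error: ", conditionMessage(e),
                                         call. = FALSE))
  Uel <- U[sys$n_nodes + seq_len(n), , drop = FALSE]  # electrodes x drives
  V <- Uel[scheme$meas[, 1L], ] - Uel[scheme$meas[, 2L], ]  # meas x drive
  frame <- as.vector(V[cbind(rep(seq_len(n), times = n),
                             rep(seq_len(n), each = n))])  # drive-major
  frame[!scheme$valid] <- NA_real_
  structure(frame, valid = scheme$valid, class = "voltage_frame",
            potentials = if (full) U[seq_len(sys$n_nodes), , drop = FALSE] else NULL)
}

#' @export
print.voltage_frame <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<voltage_frame> %d channels (%d valid), range [%.3g, %.3g]\n",
              length(v), sum(attr(x, "valid")), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

#' Conductivity sensitivity matrix (Jacobian) by the adjoint-field method
#'
#' Row `c` column `e` holds the derivative of valid channel `c`'s voltage with
#' respect to the conductivity of element `e`, evaluated at `sigma`:
#' `J[c,e] = -int_e grad(u_drive) . grad(u_meas) dV`, with the measurement
#' field driven by unit current through the measurement pair.
#'
#' @inheritParams solve_forward
#' @return matrix with one row per valid channel (channel order as in the
#'   scheme, invalid slots dropped) and one column per element. Attributes:
#'   `valid` (channel mask), `v0` (the forward frame at `sigma`).
#' @export
eit_jacobian <- function(m, sigma, scheme, z_contact = 1e4) {
  sys <- assemble_cem(m, sigma, z_contact)
  n <- scheme$n_electrodes
  dim_tot <- nrow(sys$K)
  B <- matrix(0, dim_tot, 2L * n)
  for (k in seq_len(n)) {
    B[sys$n_nodes + scheme$drives[k, 1L], k] <- scheme$amplitude
    B[sys$n_nodes + scheme$drives[k, 2L], k] <- -scheme$amplitude
    # unit-current measurement fields
    B[sys$n_nodes + scheme$meas[k, 1L], n + k] <- 1
    B[sys$n_nodes + scheme$meas[k, 2L], n + k] <- -1
  }
  U <- as.matrix(Matrix::solve(sys$K, B))
  Un <- U[seq_len(sys$n_nodes), , drop = FALSE]
  Uel <- U[sys$n_nodes + seq_len(n), seq_len(n), drop = FALSE]

  gv <- sys$gv
  # per-element gradient of each field: n_elem x 3 per field
  grad_field <- function(uvec) {
    u1 <- uvec[m$elems[, 1L]]; u2 <- uvec[m$elems[, 2L]]
    u3 <- uvec[m$elems[, 3L]]; u4 <- uvec[m$elems[, 4L]]
    gv$grads[, 1L, ] * u1 + gv$grads[, 2L, ] * u2 +
      gv$grads[, 3L, ] * u3 + gv$grads[, 4L, ] * u4
  }
  gd <- lapply(seq_len(n), function(k) grad_field(Un[, k]))
  gm <- lapply(seq_len(n), function(k) grad_field(Un[, n + k]))

  valid <- scheme$valid
  J <- matrix(0, sum(valid), nrow(m$elems))
  r <- 1L
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (!valid[(k - 1L) * n + j]) next
    J[r, ] <- -gv$vol * rowSums(gd[[k]] * gm[[j]])
    r <- r + 1L
  }
  v0 <- Uel[scheme$meas[, 1L], ] - Uel[scheme$meas[, 2L], ]
  frame <- as.vector(v0[cbind(rep(seq_len(n), times = n), rep(seq_len(n), each = n))])
  frame[!valid] <- NA_real_
  structure(J, valid = valid, v0 = frame)
}

#' Aggregate a tetrahedral Jacobian to the 2D (2.5D) element basis
#'
#' In the 2.5D setting conductivity is constant along the extrusion, so the
#' inverse problem is parameterized on the 2D triangles; the sensitivity to a
#' 2D element is the sum over the tetrahedra extruded from it.
#'
#' @param J matrix from [eit_jacobian()]
#' @param m the `eit_mesh` the Jacobian was computed on
#' @export
jacobian_2d <- function(J, m) {
  agg <- Matrix::sparseMatrix(i = seq_len(ncol(J)), j = m$tri2d, x = 1,
                              dims = c(ncol(J), nrow(m$tris2d)))
  out <- as.matrix(J %*% agg)
  attr(out, "valid") <- attr(J, "valid")
  attr(out, "v0") <- attr(J, "v0")
  out
}
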