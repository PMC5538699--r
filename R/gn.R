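#' One-step Gauss-Newton solution map in element space
#'
#' Returns the linear map `(J'J + lambda^2 P)^-1 J'` from channel differences
#' to element conductivity changes, for the chosen regularization prior.
#' Computed through the prior Cholesky factor and the dual (channel-space)
#' normal equations, so the cost is governed by the channel count.
#'
#' @param J sensitivity matrix (channels x elements)
#' @param prior `"Tikhonov"` (P = I), `"NOSER"` (P = diag(J'J)) or
#'   `"Laplace"` (P = L'L for the element-adjacency graph Laplacian L; a small
#'   diagonal shift makes it invertible)
#' @param lambda regularization weight
#' @param adjacency for the Laplace prior: two-column matrix of neighboring
#'   element index pairs
#' @return elements x channels matrix
#' @export
gn_map <- function(J, prior = c("Tikhonov", "NOSER", "Laplace"), lambda,
                   adjacency = NULL) {
  prior <- match.arg(prior)
  parts <- gn_dual_parts(J, prior, adjacency)
  with(parts, Cinv_Jt_U %*% (t(U) * gn_coefs(dvals, lambda)))
}

# dual-space filter factors 1/(d + lambda^2); directions in the numerical
# null space of J P^-1 J' are dropped (their loadings are round-off)
gn_coefs <- function(dvals, lambda) {
  ifelse(dvals > 1e-12 * max(dvals), 1 / (dvals + lambda^2), 0)
}

# Shared precomputation: prior factor, dual eigendecomposition.
gn_dual_parts <- function(J, prior, adjacency = NULL) {
  ne <- ncol(J)
  if (prior == "Laplace") {
    if (is.null(adjacency)) stop("Laplace prior needs element adjacency", call. = FALSE)
    L <- element_laplacian(ne, adjacency)
    P <- L %*% L
    P <- P + Matrix::Diagonal(ne, 1e-8 * mean(Matrix::diag(P)))
    C <- Matrix::chol(P)
    Jt_white <- as.matrix(Matrix::solve(Matrix::t(C), t(J)))  # t(J C^-1)
    Cinv <- function(x) as.matrix(Matrix::solve(C, x))
  } else {
    dP <- if (prior == "Tikhonov") rep(1, ne) else colSums(J^2)  # NOSER
    if (any(dP <= 0)) dP <- pmax(dP, 1e-12 * max(dP))
    s <- sqrt(dP)
    Jt_white <- t(J) / s
    Cinv <- function(x) x / s
  }
  M <- crossprod(Jt_white)  # J P^-1 J' (channels x channels)
  eg <- eigen(M, symmetric = TRUE)
  list(U = eg$vectors, dvals = pmax(eg$values, 0),
       Cinv_Jt_U = Cinv(Jt_white %*% eg$vectors))
}

# graph Laplacian of the element adjacency (symmetric, PSD)
element_laplacian <- function(ne, adjacency) {
  i <- c(adjacency[, 1L], adjacency[, 2L])
  j <- c(adjacency[, 2L], adjacency[, 1L])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(ne, ne))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# edge-sharing neighbor pairs of the 2D triangles
tri_adjacency <- function(m) {
  tr <- m$tris2d
  edges <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  tri_id <- rep(seq_len(nrow(tr)), 3L)
  sp <- split(tri_id, key)
  sp <- sp[lengths(sp) == 2L]
  do.call(rbind, sp)
}

#' Gauss-Newton trainer with noise-figure calibration support
#'
#' Builds the pixel-space one-step Gauss-Newton reconstruction map
#' `-T (J'J + lambda^2 P)^-1 J'` (T the element-to-pixel interpolation; the
#' sign makes a lung conductivity decrease appear positive) in a form where
#' retraining across lambda is cheap, for use with [calibrate_nf()].
#'
#' @param m an `eit_mesh`
#' @param J2 2D-element Jacobian at the config's background (reference-scaled
#'   for NTD)
#' @param grid pixel grid
#' @param cfg a [gn_config()]
#' @keywords internal
gn_trainer <- function(m, J2, grid, cfg) {
  parts <- gn_dual_parts(as.matrix(J2), cfg$prior,
                         adjacency = if (cfg$prior == "Laplace") tri_adjacency(m))
  Tm <- pixel_interp_matrix(m, grid)
  B <- as.matrix(Tm %*% parts$Cinv_Jt_U)   # pixels x channels
  body <- as.vector(t(grid$body_mask))
  R_eff <- effective_radius(m$geometry)
  ctr <- contour_centroid(m$geometry$thorax)
  y_ref <- signature_matrix(J2, tri_centroids(m), ctr[1L], ctr[2L],
                            0.06 * R_eff, tri_areas(m))[, 1L]
  U <- parts$U; dvals <- parts$dvals

  nf_at <- function(lambda) {
    Bw <- sweep(B, 2L, gn_coefs(dvals, lambda), "*")
    rown <- sqrt(rowSums(Bw^2))
    img <- Bw %*% crossprod(U, y_ref)
    mean(rown[body]) * mean(abs(y_ref)) / mean(abs(img[body]))
  }
  matrix_at <- function(lambda, achieved_nf = NULL) {
    R <- -sweep(B, 2L, gn_coefs(dvals, lambda), "*") %*% t(U)
    reconstruction_matrix(R, grid, cfg, lambda = lambda, nf = achieved_nf,
                          y_ref = y_ref)
  }
  list(nf_at = nf_at, matrix_at = matrix_at)
}

tri_areas <- function(m) {
  p <- m$nodes2d; t <- m$tris2d
  abs((p[t[, 2L], 1L] - p[t[, 1L], 1L]) * (p[t[, 3L], 2L] - p[t[, 1L], 2L]) -
      (p[t[, 2L], 2L] - p[t[, 1L], 2L]) * (p[t[, 3L], 1L] - p[t[, 1L], 1L])) / 2
}
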