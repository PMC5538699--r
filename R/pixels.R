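#' Element-to-pixel interpolation matrix
#'
#' Maps values on the 2D (mid-plane) elements of a mesh onto the 32x32 pixel
#' grid. Each pixel value is the area-weighted average of the elements
#' intersecting the pixel; intersection areas are computed by regular
#' subsampling (`sub^2` sample points per pixel). Pixels outside the body mask
#' map to zero.
#'
#' @param m an `eit_mesh`
#' @param grid a [rasterize()] pixel grid of the same geometry
#' @param sub subsamples per pixel per axis
#' @return sparse matrix (n^2 x n 2D elements) in row-major pixel order
#'   (pixel index = (row - 1) * n + col, row 1 anterior); attribute `coverage`
#'   holds the fraction of each pixel's samples that fall inside the mesh.
#' @export
pixel_interp_matrix <- function(m, grid, sub = 8L) {
  n <- grid$n
  nt <- nrow(m$tris2d)
  # sample points: sub x sub per pixel
  fx <- (seq_len(n * sub) - 0.5) / sub  # in pixel units
  xs <- grid$bbox[["xmin"]] + fx * grid$dx
  ys <- grid$bbox[["ymin"]] + fx * grid$dy
  px <- rep(xs, times = n * sub)
  py <- rep(ys, each = n * sub)
  col_pix <- rep(ceiling(fx), times = n * sub)      # column index per sample
  row_pix <- rep(ceiling(fx), each = n * sub)
  pix_id <- (row_pix - 1L) * n + col_pix

  tri_id <- locate_triangles(m$nodes2d, m$tris2d, px, py)
  ok <- !is.na(tri_id)
  cnt <- tabulate(pix_id[ok], nbins = n * n)
  Tmat <- Matrix::sparseMatrix(i = pix_id[ok], j = tri_id[ok], x = 1,
                               dims = c(n * n, nt))
  # area-weighted average: normalize by per-pixel in-mesh sample count
  norm <- ifelse(cnt > 0, 1 / cnt, 0)
  # zero pixels outside the body mask (row-major: row-first index)
  body <- as.vector(t(grid$body_mask))  # [row,col] -> (row-1)*n+col order
  norm[!body] <- 0
  Tmat <- Matrix::Diagonal(x = norm) %*% Tmat
  attr(Tmat, "coverage") <- cnt / (sub * sub)
  Tmat
}

# Index of the triangle containing each query point (NA when outside).
# Vectorized per triangle over its bounding-box candidates.
locate_triangles <- function(nodes, tris, px, py) {
  out <- rep(NA_integer_, length(px))
  ord_x <- order(px)
  sx <- px[ord_x]
  for (t in seq_len(nrow(tris))) {
    v <- nodes[tris[t, ], , drop = FALSE]
    xr <- range(v[, 1L]); yr <- range(v[, 2L])
    lo <- findInterval(xr[1L], sx) + 1L
    hi <- findInterval(xr[2L], sx)
    if (hi < lo) next
    cand <- ord_x[lo:hi]
    cand <- cand[py[cand] >= yr[1L] & py[cand] <= yr[2L] & is.na(out[cand])]
    if (!length(cand)) next
    # barycentric containment
    d <- (v[2L, 2L] - v[3L, 2L]) * (v[1L, 1L] - v[3L, 1L]) +
         (v[3L, 1L] - v[2L, 1L]) * (v[1L, 2L] - v[3L, 2L])
    l1 <- ((v[2L, 2L] - v[3L, 2L]) * (px[cand] - v[3L, 1L]) +
           (v[3L, 1L] - v[2L, 1L]) * (py[cand] - v[3L, 2L])) / d
    l2 <- ((v[3L, 2L] - v[1L, 2L]) * (px[cand] - v[3L, 1L]) +
           (v[1L, 1L] - v[3L, 1L]) * (py[cand] - v[3L, 2L])) / d
    inside <- l1 >= -1e-12 & l2 >= -1e-12 & (l1 + l2) <= 1 + 1e-12
    out[cand[inside]] <- t
  }
  out
}

#' Interpolate 2D element values onto the pixel grid
#'
#' @param values numeric vector over the mesh's 2D elements, or a matrix with
#'   one column per image
#' @param m an `eit_mesh`
#' @param grid a [rasterize()] pixel grid
#' @param interp optional precomputed [pixel_interp_matrix()]
#' @return an n x n matrix (rows anterior to posterior), or an n^2 x k matrix
#'   in row-major pixel order when `values` is a matrix
#' @export
element_to_pixel <- function(values, m, grid, interp = NULL) {
  if (is.null(interp)) interp <- pixel_interp_matrix(m, grid)
  if (is.matrix(values)) return(as.matrix(interp %*% values))
  matrix(as.vector(interp %*% values), grid$n, grid$n, byrow = TRUE)
}

# row-major pixel vector <-> image matrix ([row, col], row 1 = anterior)
pixvec_to_image <- function(v, n = 32L) matrix(v, n, n, byrow = TRUE)
image_to_pixvec <- function(img) as.vector(t(img))
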