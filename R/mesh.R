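#' Build a 2.5D extruded finite-element mesh of a thorax geometry
#'
#' Generates a 2D triangulation of the thorax cross-section and extrudes it
#' symmetrically about the electrode plane into a tetrahedral slab. Boundary
#' nodes are placed at the electrode patch edges so that each of the
#' electrodes is covered by whole boundary faces; lung and heart contours are
#' seeded as interior node rings so the triangulation follows the organ
#' boundaries. Element region labels (`background`/`lung`/`heart`) are
#' assigned from the position of each element's mid-plane centroid.
#'
#' The extrusion uses six node levels graded towards the mid-plane; the
#' electrode patches are rectangular bands of lateral faces centered on the
#' mid-plane with height `patch_height_frac` times the extrusion height.
#' Mesh generation is fully deterministic for identical inputs.
#'
#' @param g a [thorax_geometry()]
#' @param layout an [place_electrodes()] layout on `g$thorax`; built with
#'   defaults when NULL.
#' @param target_elements requested tetrahedron count (within about +/-30%).
#'   Reconstruction-grade models default to 20k elements; finer meshes are a
#'   configuration choice.
#' @param extrusion_height slab height in mm; default 1.0 x effective thorax
#'   radius.
#' @param patch_height_frac electrode patch height as a fraction of the
#'   extrusion height.
#' @param lattice_offset length-2 fractional offset (in units of the lattice
#'   pitch) applied to the interior point lattice. Simulation meshes use a
#'   different offset than reconstruction meshes so the two discretizations
#'   share no interior nodes.
#' @param layer_refine integer subdivision factor of the graded extrusion
#'   layers (1 = the default five layers). Mesh-refinement studies must
#'   refine the extrusion along with the section.
#' @return an `eit_mesh` object
#' @export
build_mesh <- function(g, layout = NULL, target_elements = 20000L,
                       extrusion_height = NULL, patch_height_frac = 0.1,
                       lattice_offset = c(0, 0), layer_refine = 1L) {
  stopifnot(inherits(g, "thorax_geometry"))
  if (target_elements < 1000L)
    stop("invalid argument: target_elements must be >= 1000", call. = FALSE)
  if (is.null(layout)) layout <- place_electrodes(g$thorax)
  H <- if (is.null(extrusion_height)) effective_radius(g) else extrusion_height

  A <- contour_area(g$thorax)
  n_layers <- 5L * layer_refine      # graded z-levels, optionally subdivided
  tets_per_tri <- 3L * n_layers
  n2_target <- target_elements / tets_per_tri
  h <- sqrt(4 * A / (sqrt(3) * n2_target))

  tri <- NULL
  for (attempt in 1:4) {
    tri <- triangulate_section(g, layout, h, lattice_offset)
    n_tets <- tets_per_tri * nrow(tri$tris)
    if (abs(n_tets - target_elements) <= 0.25 * target_elements) break
    h <- h * sqrt(n_tets / target_elements)
  }
  n_tets <- tets_per_tri * nrow(tri$tris)
  if (abs(n_tets - target_elements) > 0.3 * target_elements)
    stop("meshing error: achieved ", n_tets, " elements for target ",
         target_elements, call. = FALSE)

  # z-levels graded so the mid-plane band matches the electrode patch height
  ph <- patch_height_frac * H
  base_levels <- c(-H / 2, -H / 5, -ph / 2, ph / 2, H / 5, H / 2)
  levels <- base_levels
  if (layer_refine > 1L) {
    levels <- unique(sort(unlist(lapply(seq_len(length(base_levels) - 1L),
      function(i) seq(base_levels[i], base_levels[i + 1L],
                      length.out = layer_refine + 1L)))))
  }
  ext <- extrude_section(tri$nodes, tri$tris, levels)

  # the electrode band spans the (refined) layers between -ph/2 and ph/2
  mid_lo <- which(abs(levels + ph / 2) < 1e-9)
  faces <- electrode_faces(tri, layout, bands = mid_lo:(which(abs(levels - ph / 2) < 1e-9) - 1L))
  region2d <- label_regions(tri, g)

  m <- structure(list(
    nodes = ext$nodes, elems = ext$elems,
    tri2d = ext$tri2d, layer = ext$layer,
    nodes2d = tri$nodes, tris2d = tri$tris,
    boundary_idx = tri$boundary_idx, boundary_arc = tri$boundary_arc,
    region2d = region2d, elem_region = region2d[ext$tri2d],
    elec_faces = faces, levels = levels, plane_height = H,
    layout = layout, geometry = g, h = h
  ), class = "eit_mesh")
  vol <- tet_volumes(m)
  if (any(vol <= 0)) stop("meshing error: non-positive element volume", call. = FALSE)
  m$volumes <- vol
  m
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf(paste0("<eit_mesh> %d nodes, %d tetrahedra (%d x 2D triangles),",
                     " %d electrodes, slab %.1f mm\n"),
              nrow(x$nodes), nrow(x$elems), nrow(x$tris2d),
              length(x$elec_faces), x$plane_height))
  tab <- table(x$elem_region)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- 2D section triangulation ------------------------------------------------

triangulate_section <- function(g, layout, h, lattice_offset = c(0, 0)) {
  v <- unclass(g$thorax)
  per <- layout$perimeter

  # boundary nodes: electrode patch edges, intervals subdivided to mean
  # spacing <= h with cosine clustering towards the patch edges (the CEM
  # field is singular there; grading restores near-second-order convergence)
  edges_arc <- sort(unique(round(
    c(outer(layout$arc, c(-0.5, 0.5) * layout$width, "+")) %% per, 9)))
  barc <- c()
  for (i in seq_along(edges_arc)) {
    a0 <- edges_arc[i]
    a1 <- if (i < length(edges_arc)) edges_arc[i + 1L] else edges_arc[1L] + per
    gap <- a1 - a0
    k <- max(2L, ceiling(gap / h) + 1L)
    t <- (seq_len(k) - 1L) / k
    barc <- c(barc, a0 + gap * (1 - cos(pi * t)) / 2)
  }
  barc <- sort(barc %% per)
  bpts <- t(vapply(barc, function(s) point_at_arc(v, s), numeric(2L)))

  # organ boundary rings (arc offset follows the lattice offset so meshes
  # with different offsets share no organ-ring nodes)
  opts <- NULL
  for (o in c(g$lungs, if (!is.null(g$heart)) list(g$heart))) {
    ov <- unclass(o)
    operi <- contour_perimeter(o)
    k <- max(12L, ceiling(operi / h))
    oarc <- operi * ((seq_len(k) - 1L + lattice_offset[1L]) / k)
    opts <- rbind(opts, t(vapply(oarc, function(s) point_at_arc(ov, s), numeric(2L))))
  }

  # interior hexagonal lattice
  bb <- apply(v, 2L, range)
  ys <- seq(bb[1L, 2L] + lattice_offset[2L] * h, bb[2L, 2L], by = h * sqrt(3) / 2)
  lat <- do.call(rbind, lapply(seq_along(ys), function(i) {
    x0 <- bb[1L, 1L] + lattice_offset[1L] * h + (i %% 2L) * h / 2
    xs <- seq(x0, bb[2L, 1L], by = h)
    cbind(xs, ys[i])
  }))
  keep <- points_in_contour(lat[, 1L], lat[, 2L], g$thorax)
  lat <- lat[keep, , drop = FALSE]
  fixed <- rbind(bpts, opts)
  if (nrow(lat)) {
    d2 <- min_dist2(lat, fixed)
    lat <- lat[d2 > (0.55 * h)^2, , drop = FALSE]
  }

  pts <- rbind(bpts, opts, lat)
  nb <- nrow(bpts)

  # deldir occasionally prints workspace-growth notes to stdout; keep quiet
  junk <- utils::capture.output({
    dd <- deldir::deldir(pts[, 1L], pts[, 2L], suppressMsge = TRUE)
    tl <- deldir::triang.list(dd)
  })
  tris <- t(vapply(tl, function(t) as.integer(t$ptNum), integer(3L)))

  # keep triangles whose centroid is inside the thorax (removes convex-hull
  # fill across boundary concavities)
  cx <- (pts[tris[, 1L], 1L] + pts[tris[, 2L], 1L] + pts[tris[, 3L], 1L]) / 3
  cy <- (pts[tris[, 1L], 2L] + pts[tris[, 2L], 2L] + pts[tris[, 3L], 2L]) / 3
  tris <- tris[points_in_contour(cx, cy, g$thorax), , drop = FALSE]

  # enforce counter-clockwise triangles
  a2 <- (pts[tris[, 2L], 1L] - pts[tris[, 1L], 1L]) *
        (pts[tris[, 3L], 2L] - pts[tris[, 1L], 2L]) -
        (pts[tris[, 2L], 2L] - pts[tris[, 1L], 2L]) *
        (pts[tris[, 3L], 1L] - pts[tris[, 1L], 1L])
  flip <- a2 < 0
  tris[flip, 2:3] <- tris[flip, 3:2]

  list(nodes = pts, tris = tris, boundary_idx = seq_len(nb), boundary_arc = barc,
       perimeter = per)
}

min_dist2 <- function(a, b) {
  # squared distance from each row of a to nearest row of b (sizes are modest)
  out <- rep(Inf, nrow(a))
  chunk <- 2000L
  for (s in seq(1L, nrow(b), by = chunk)) {
    idx <- s:min(nrow(b), s + chunk - 1L)
    d <- outer(a[, 1L], b[idx, 1L], "-")^2 + outer(a[, 2L], b[idx, 2L], "-")^2
    out <- pmin(out, apply(d, 1L, min))
  }
  out
}

label_regions <- function(tri, g) {
  pts <- tri$nodes; tris <- tri$tris
  cx <- (pts[tris[, 1L], 1L] + pts[tris[, 2L], 1L] + pts[tris[, 3L], 1L]) / 3
  cy <- (pts[tris[, 1L], 2L] + pts[tris[, 2L], 2L] + pts[tris[, 3L], 2L]) / 3
  lab <- rep("background", nrow(tris))
  for (l in g$lungs) lab[points_in_contour(cx, cy, l)] <- "lung"
  if (!is.null(g$heart)) lab[points_in_contour(cx, cy, g$heart)] <- "heart"
  lab
}

# ---- extrusion ---------------------------------------------------------------

# Split each prism into 3 tetrahedra with the index-sorted diagonal rule so
# faces are conforming across neighboring prisms.
extrude_section <- function(nodes2d, tris, levels) {
  nn <- nrow(nodes2d)
  nl <- length(levels)
  nodes <- cbind(nodes2d[rep(seq_len(nn), nl), , drop = FALSE],
                 rep(levels, each = nn))
  colnames(nodes) <- c("x", "y", "z")

  srt <- t(apply(tris, 1L, sort))
  i0 <- srt[, 1L]; i1 <- srt[, 2L]; i2 <- srt[, 3L]
  nt <- nrow(tris)
  elems <- vector("list", nl - 1L)
  for (k in seq_len(nl - 1L)) {
    b <- (k - 1L) * nn; t <- k * nn
    elems[[k]] <- rbind(
      cbind(i0 + b, i1 + b, i2 + b, i0 + t),
      cbind(i1 + b, i2 + b, i0 + t, i1 + t),
      cbind(i2 + b, i0 + t, i1 + t, i2 + t))
  }
  elems <- do.call(rbind, elems)
  tri2d <- rep(rep(seq_len(nt), 3L), nl - 1L)
  layer <- rep(seq_len(nl - 1L), each = 3L * nt)

  # orient for positive volume
  v <- tet_volumes_raw(nodes, elems)
  neg <- v < 0
  elems[neg, c(3L, 4L)] <- elems[neg, c(4L, 3L)]
  list(nodes = nodes, elems = elems, tri2d = tri2d, layer = layer)
}

tet_volumes_raw <- function(nodes, elems) {
  a <- nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 2L], , drop = FALSE] - a
  c_ <- nodes[elems[, 3L], , drop = FALSE] - a
  d <- nodes[elems[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) -
   b[, 2L] * (c_[, 1L] * d[, 3L] - c_[, 3L] * d[, 1L]) +
   b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Element volumes of a mesh (mm^3)
#' @param m an `eit_mesh`
#' @export
tet_volumes <- function(m) tet_volumes_raw(m$nodes, m$elems)

# ---- electrode patches -------------------------------------------------------

# Lateral boundary faces under each electrode, over the mid-plane band
# layers. Faces use the same index-sorted diagonal as the prism split so
# they coincide with tetrahedron faces.
electrode_faces <- function(tri, layout, bands) {
  nb <- length(tri$boundary_idx)
  nn <- nrow(tri$nodes)
  barc <- tri$boundary_arc
  per <- tri$perimeter
  faces <- vector("list", layout$n)
  edge_mid <- ((barc + c(barc[-1L], barc[1L] + per)) / 2) %% per
  for (l in seq_len(layout$n)) {
    lo <- (layout$arc[l] - layout$width / 2) %% per
    hi <- (layout$arc[l] + layout$width / 2) %% per
    inside <- if (lo < hi) edge_mid > lo & edge_mid < hi else edge_mid > lo | edge_mid < hi
    idx <- which(inside)
    if (!length(idx))
      stop("meshing error: electrode ", l, " has no boundary faces", call. = FALSE)
    f <- lapply(idx, function(i) {
      a <- tri$boundary_idx[i]
      b <- tri$boundary_idx[if (i == nb) 1L else i + 1L]
      lo_i <- min(a, b); hi_i <- max(a, b)
      do.call(rbind, lapply(bands, function(k) {
        b0 <- (k - 1L) * nn; t0 <- k * nn
        rbind(c(lo_i + b0, hi_i + b0, lo_i + t0),
              c(hi_i + b0, lo_i + t0, hi_i + t0))
      }))
    })
    faces[[l]] <- do.call(rbind, f)
  }
  faces
}
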