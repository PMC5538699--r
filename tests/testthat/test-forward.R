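test_that("skip-4 scheme enumerates drives, channels and validity", {
  s <- skip4_scheme()
  expect_equal(nrow(s$drives), 32L)
  expect_length(s$valid, 1024L)
  expect_equal(sum(s$valid), 928L)
  # 29 valid measurements for every drive
  per_drive <- colSums(matrix(s$valid, 32L, 32L))
  expect_true(all(per_drive == 29L))
  # drive 1 (electrodes 1,6): invalid measurements are 1, 6 and 28
  # (measurement 28 uses electrodes 28 and 28+5-32 = 1)
  expect_equal(which(!s$valid[1:32]), c(1L, 6L, 28L))
  # drive pairs skip four electrodes
  expect_equal(s$drives[1L, ], c(1L, 6L))
  expect_equal(s$drives[32L, ], c(32L, 5L))
  expect_error(skip4_scheme(amplitude = 0), "amplitude")
})

test_that("forward solution obeys reciprocity", {
  m <- fix_small_mesh()
  s <- fix_scheme()
  v <- solve_forward(m, weighted_background(m, "uniform"), s)
  V <- matrix(unclass(v), 32L, 32L)  # [measurement, drive]
  rel <- abs(V - t(V)) / pmax(abs(V), abs(t(V)))
  expect_lt(max(rel, na.rm = TRUE), 1e-8)
})

test_that("forward solution scales linearly with the admittance", {
  m <- fix_small_mesh()
  s <- fix_scheme()
  sig <- weighted_background(m, "uniform")
  v1 <- unclass(solve_forward(m, sig, s))
  # scaling sigma by k (and the contact admittance with it) scales u by 1/k
  v2 <- unclass(solve_forward(m, 2 * sig, s, z_contact = 1e4 / 2))
  expect_lt(max(abs(2 * v2 - v1) / abs(v1), na.rm = TRUE), 1e-10)
})

test_that("Jacobian matches central finite differences", {
  m <- fix_small_mesh()
  s <- fix_scheme()
  sig <- weighted_background(m, "uniform")
  J <- eit_jacobian(m, sig, s)
  expect_equal(dim(J), c(928L, nrow(m$elems)))
  set.seed(31)
  cache <- ventrecon:::cem_cache(m)
  for (e in sample(ncol(J), 6L)) {
    d <- 1e-3
    sp_ <- sig; sp_[e] <- sig[e] + d
    sm_ <- sig; sm_[e] <- sig[e] - d
    vp <- unclass(solve_forward(m, sp_, s, cache = cache))
    vm <- unclass(solve_forward(m, sm_, s, cache = cache))
    fd <- ((vp - vm) / (2 * d))[attr(J, "valid")]
    expect_lt(max(abs(fd - J[, e])) / max(abs(J[, e])), 1e-3)
  }
})

test_that("Jacobian columns aggregate consistently onto the 2D basis", {
  m <- fix_small_mesh()
  s <- fix_scheme()
  J <- eit_jacobian(m, weighted_background(m, "uniform"), s)
  J2 <- jacobian_2d(J, m)
  expect_equal(ncol(J2), nrow(m$tris2d))
  k <- 17L
  expect_equal(J2[, k], rowSums(J[, m$tri2d == k, drop = FALSE]))
})

test_that("weighted background assigns tissue conductivities", {
  m <- fix_organ_mesh()
  sig <- weighted_background(m, "weighted")
  expect_true(all(sig[m$elem_region == "lung"] == 0.2))
  expect_true(all(sig[m$elem_region == "heart"] == 1.5))
  expect_true(all(sig[m$elem_region == "background"] == 1))
  expect_true(all(weighted_background(m, "uniform") == 1))
  expect_error(weighted_background(fix_small_mesh(), "weighted"),
               "organ labels")
})

test_that("anomaly voltages converge under mesh refinement", {
  # concentric circular anomaly (smooth profile, so both meshes resolve the
  # conductivity itself); the anomaly-induced channel voltages of a ~5k mesh
  # agree with a 4x finer mesh (refined in-plane and across layers) within 2%
  g <- fix_circle_geometry()
  s <- fix_scheme()
  m1 <- build_mesh(g, target_elements = 5000)
  m2 <- build_mesh(g, target_elements = 20000, layer_refine = 2L)
  anom <- function(m) {
    ec <- (m$nodes[m$elems[, 1L], 1:2] + m$nodes[m$elems[, 2L], 1:2] +
           m$nodes[m$elems[, 3L], 1:2] + m$nodes[m$elems[, 4L], 1:2]) / 4
    1 - 0.5 * exp(-rowSums(ec^2) / 30^2)
  }
  dsig <- function(m) {
    unclass(solve_forward(m, anom(m), s)) -
      unclass(solve_forward(m, rep(1, nrow(m$elems)), s))
  }
  d1 <- dsig(m1); d2 <- dsig(m2)
  rel <- sqrt(sum((d1 - d2)^2, na.rm = TRUE) / sum(d2^2, na.rm = TRUE))
  expect_lt(rel, 0.02)
})
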