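test_that("mesh satisfies validity invariants", {
  m <- fix_small_mesh()
  vol <- tet_volumes(m)
  expect_true(all(vol > 0))
  expect_length(m$elec_faces, 32L)
  expect_true(all(vapply(m$elec_faces, nrow, 0L) > 0L))
  # element count within 30% of target
  expect_lt(abs(nrow(m$elems) - 3000) / 3000, 0.3)
  # slab height and symmetry about the electrode plane
  expect_equal(max(m$nodes[, 3L]), -min(m$nodes[, 3L]))
  expect_equal(max(m$nodes[, 3L]) - min(m$nodes[, 3L]),
               effective_radius(fix_circle_geometry()), tolerance = 1e-9)
  expect_error(build_mesh(fix_circle_geometry(), target_elements = 500),
               "1000")
})

test_that("region labels follow mid-plane centroids and partition the mesh", {
  m <- fix_organ_mesh()
  g <- make_phantom("averaged")
  expect_setequal(unique(m$elem_region), c("background", "lung", "heart"))
  # oracle: ray-casting on tetrahedron mid-plane centroid projections
  ec <- (m$nodes[m$elems[, 1L], 1:2] + m$nodes[m$elems[, 2L], 1:2] +
         m$nodes[m$elems[, 3L], 1:2] + m$nodes[m$elems[, 4L], 1:2]) / 4
  in_lung <- oracle_in_poly(ec[, 1L], ec[, 2L], unclass(g$lungs[[1L]])) |
             oracle_in_poly(ec[, 1L], ec[, 2L], unclass(g$lungs[[2L]]))
  # boundary-straddling elements aside, centroid-in-lung implies label lung
  agree <- mean((m$elem_region == "lung") == in_lung)
  expect_gt(agree, 0.98)
  # every element carries exactly one region label
  expect_false(anyNA(m$elem_region))
})

test_that("mesh generation is deterministic", {
  g <- make_phantom("averaged")
  m1 <- build_mesh(g, target_elements = 3000)
  m2 <- build_mesh(g, target_elements = 3000)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$elec_faces, m2$elec_faces)
})

test_that("electrode patches sit in the mid-plane band under each electrode", {
  m <- fix_small_mesh()
  ph <- 0.1 * m$plane_height
  for (l in c(1L, 9L, 17L, 25L)) {
    f <- m$elec_faces[[l]]
    z <- m$nodes[as.vector(f), 3L]
    expect_true(all(abs(z) <= ph / 2 + 1e-9))
    # faces lie near the electrode position
    fc <- cbind(rowMeans(matrix(m$nodes[f, 1L], nrow(f))),
                rowMeans(matrix(m$nodes[f, 2L], nrow(f))))
    d <- sqrt((fc[, 1L] - m$layout$positions[l, 1L])^2 +
              (fc[, 2L] - m$layout$positions[l, 2L])^2)
    expect_true(all(d <= m$layout$width))
  }
})
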