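test_that("phantom kinds meet their shape contracts", {
  ci <- make_phantom("circular")
  nv <- unclass(normalize_contour(ci$thorax))
  r <- sqrt(rowSums(nv^2))
  # a circle: all vertices equidistant from the centroid, radius 1 up to the
  # polygonal area deficit of the 64-gon
  expect_lt(diff(range(r)) / mean(r), 1e-9)
  expect_equal(mean(r), 1, tolerance = 2e-3)
  expect_length(ci$lungs, 0L)

  av <- make_phantom("averaged")
  expect_length(av$lungs, 2L)
  expect_false(is.null(av$heart))

  # same seed -> identical geometry; different seed -> different
  g1 <- make_phantom("individual", seed = 123L)
  g2 <- make_phantom("individual", seed = 123L)
  g3 <- make_phantom("individual", seed = 124L)
  expect_identical(g1, g2)
  expect_false(isTRUE(all.equal(unclass(g1$thorax), unclass(g3$thorax))))
})

test_that("individual phantoms sit in the expected mismatch band", {
  av <- make_phantom("averaged")
  for (s in 1001:1004) {
    ds <- symmetric_difference(make_phantom("individual", seed = s)$thorax,
                               av$thorax)
    expect_gt(ds, 3); expect_lt(ds, 8)
  }
})

test_that("breathing configuration enforces its invariants", {
  expect_error(breathing_config(duration = 5), "1.5 breaths")
  expect_error(breathing_config(sim_mesh_refinement = 1), "refinement")
  expect_error(simulate_recording(make_phantom("circular")), "no lungs")
})

test_that("simulated recording has the configured frame count and noise-free null", {
  b <- breathing_config(fs = 12, duration = 20, delta_sigma = 0,
                        noise_snr = 60, seed = 3L)
  rec <- simulate_recording(make_phantom("averaged"), b, recon_elements = 3000)
  expect_equal(nrow(rec$series$V), 20 * 12)
  # no ventilation and no signal swing: every frame equals the first,
  # and there is no aeration ground truth to profile
  d <- difference_voltages(rec$series, 1L, "TD")
  expect_true(all(abs(d$V[, rec$series$valid]) < 1e-12))
  expect_null(rec$truth$vd_truth)
})

test_that("uniform aeration reproduces the lung-geometry profile", {
  g <- make_phantom("averaged")
  b <- breathing_config(ap_gradient = 0)
  tr <- ventrecon:::ground_truth_tidal(g, b)
  # with no gradient the profile is proportional to lung pixels per band
  counts <- rowsum(rowSums(tr$grid$lung_mask), rep(1:32, each = 4L))
  expect_equal(tr$vd_truth$vd, 100 * as.vector(counts) / sum(counts),
               tolerance = 1e-9)
  # with a gradient, the posterior half receives more than the geometry share
  tr2 <- ventrecon:::ground_truth_tidal(g, breathing_config(ap_gradient = 0.5))
  post <- 17:32
  expect_gt(sum(tr2$vd_truth$vd[post]), sum(tr$vd_truth$vd[post]))
})

test_that("ground truth is supported on the lung mask and sums to 100%", {
  rec <- fix_recording()
  expect_true(all(rec$truth$tidal[!rec$truth$grid$lung_mask] == 0))
  expect_true(all(rec$truth$tidal[rec$truth$grid$lung_mask] > 0))
  expect_equal(sum(rec$truth$vd_truth$vd), 100, tolerance = 1e-9)
})

test_that("simulation and reconstruction meshes share no interior nodes", {
  rec <- fix_recording()
  mrec <- fix_organ_mesh()
  msim <- rec$mesh
  key <- function(m) {
    b <- m$boundary_idx
    interior <- setdiff(seq_len(nrow(m$nodes2d)), b)
    paste(round(m$nodes2d[interior, 1L], 6L), round(m$nodes2d[interior, 2L], 6L))
  }
  expect_length(intersect(key(msim), key(mrec)), 0L)
})

test_that("small cohorts are reproducible and breath-detectable", {
  b <- breathing_config(fs = 12, duration = 20, seed = 1L)
  ch1 <- cohort(n = 2L, seed = 5L, breathing = b, recon_elements = 3000)
  ch2 <- cohort(n = 2L, seed = 5L, breathing = b, recon_elements = 3000)
  expect_identical(ch1$subjects[[1L]]$recording$V, ch2$subjects[[1L]]$recording$V)
  expect_identical(unclass(ch1$subjects[[2L]]$geometry$thorax),
                   unclass(ch2$subjects[[2L]]$geometry$thorax))
  # distinct individual geometries, shared averaged contour
  expect_false(isTRUE(all.equal(unclass(ch1$subjects[[1L]]$geometry$thorax),
                                unclass(ch1$subjects[[2L]]$geometry$thorax))))
  # each recording carries the expected complete breaths (2 in 20 s at 6/min)
  rm <- fix_organ_model()
  pl <- ventilation_pipeline(ch1$subjects[[1L]]$recording, rm)
  expect_equal(length(pl$markers$t_in), 2L)
})
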