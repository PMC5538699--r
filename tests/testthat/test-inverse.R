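# A tiny synthetic training set exercises the GREIT algebra without a mesh.
fake_targets <- function(nch = 20L, K = 9L, n = 4L, seed = 2L) {
  set.seed(seed)
  Y <- matrix(stats::rnorm(nch * K), nch, K)
  X <- matrix(stats::rnorm(n * n * K), n * n, K)
  grid <- list(n = n, body_mask = matrix(TRUE, n, n))
  structure(list(Y = Y, X = X, y_ref = Y[, 1L], grid = grid,
                 cfg = greit_config()), class = "training_targets")
}

test_that("GREIT training norm shrinks monotonically with lambda", {
  tg <- fake_targets()
  norms <- vapply(10^seq(0, 6, by = 1), function(l) {
    norm(greit_train(tg, lambda = l)$R, "F")
  }, 0.0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3 * norms[1L])
})

test_that("single-target training reproduces its desired image at lambda 0", {
  tg <- fake_targets(K = 1L)
  rm <- greit_train(tg, lambda = 0)
  expect_equal(as.vector(rm$R %*% tg$Y[, 1L]), tg$X[, 1L], tolerance = 1e-8)
})

test_that("noise figure is scale-invariant and matches a hand calculation", {
  tg <- fake_targets()
  rm <- greit_train(tg, lambda = 10)
  nf1 <- noise_figure(rm)
  rm_scaled <- rm
  rm_scaled$R <- 7.3 * rm$R
  expect_equal(noise_figure(rm_scaled), nf1, tolerance = 1e-12)

  # orthonormal-row map, y_c = e1: amplification of noise is 1 per row,
  # signal image is the first column -> closed form by hand
  n <- 4L
  R <- cbind(diag(n * n), matrix(0, n * n, 4L))   # 16 pixels x 20 channels
  y <- c(1, rep(0, 19L))
  rm2 <- reconstruction_matrix(R, list(n = n, body_mask = matrix(TRUE, n, n)),
                               greit_config(), y_ref = y)
  # mean row norm = 1; mean|y| = 1/20; mean|R y| = 1/16
  expect_equal(noise_figure(rm2), 1 * (1 / 20) / (1 / 16), tolerance = 1e-12)
  expect_error(noise_figure(reconstruction_matrix(
    R, list(n = n, body_mask = matrix(TRUE, n, n)), greit_config(),
    y_ref = rep(0, 20L))), "zero reference")
})

test_that("noise figure decreases with lambda on the operating branch", {
  tr <- ventrecon:::greit_trainer(fix_circle_targets())
  nfs <- vapply(10^seq(-8, -4, by = 0.5), tr$nf_at, 0.0)
  expect_true(all(diff(nfs) < 0))
})

test_that("noise-figure calibration closes within 1% and is monotone", {
  tr <- ventrecon:::greit_trainer(fix_circle_targets())
  cal3 <- calibrate_nf(tr$nf_at, 0.3)
  expect_lt(abs(cal3$nf - 0.3) / 0.3, 0.01)
  # independent recomputation on the trained matrix
  rm <- tr$matrix_at(cal3$lambda)
  expect_lt(abs(noise_figure(rm) - 0.3) / 0.3, 0.01)
  cal2 <- calibrate_nf(tr$nf_at, 0.2)
  cal4 <- calibrate_nf(tr$nf_at, 0.4)
  expect_gt(cal2$lambda, cal4$lambda)   # lower nf needs more regularization
  expect_error(calibrate_nf(tr$nf_at, 1e6), "achievable range")
})

test_that("training targets cover the body and grow with ts", {
  m <- fix_small_mesh()
  g <- fix_circle_geometry()
  grid <- rasterize(g)
  J2 <- fix_circle_J2()
  cfg <- greit_config(ts = 0.1, rw = 0.2, background = "uniform")
  tg <- make_training_targets(m, J2, grid, cfg)
  expect_true(all(points_in_contour(tg$centers[, 1L], tg$centers[, 2L],
                                    g$thorax)))
  expect_equal(ncol(tg$Y), nrow(tg$centers))
  # central desired image: disc pixel count near pi*(rw*R/pitch)^2
  ic <- which.min(tg$centers[, 1L]^2 + tg$centers[, 2L]^2)
  r_px <- cfg$rw * effective_radius(g) / grid$dx
  expect_equal(sum(tg$X[, ic] > 0), pi * r_px^2, tolerance = 0.25)
  # signature norms increase strictly with ts
  norms <- vapply(c(0.05, 0.1, 0.2, 0.4), function(ts) {
    tgk <- make_training_targets(m, J2, grid,
                                 greit_config(ts = ts, background = "uniform"))
    norm(tgk$Y, "F")
  }, 0.0)
  expect_true(all(diff(norms) > 0))
})

test_that("all Gauss-Newton priors are symmetric positive semidefinite", {
  set.seed(9)
  J <- matrix(stats::rnorm(40), 10L, 4L)
  adj <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  L <- ventrecon:::element_laplacian(4L, adj)
  P_lap <- as.matrix(L %*% L)
  expect_equal(P_lap, t(P_lap))
  expect_true(all(eigen(P_lap, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_true(all(colSums(J^2) > 0))  # NOSER diagonal positive
})

test_that("Tikhonov map converges to the pseudo-inverse as lambda vanishes", {
  set.seed(10)
  J <- matrix(stats::rnorm(40), 10L, 4L)   # overdetermined, full column rank
  pinv <- solve(crossprod(J), t(J))
  M <- gn_map(J, "Tikhonov", lambda = 1e-8)
  expect_equal(as.matrix(M), pinv, tolerance = 1e-6)
  # Laplace map with strong regularization smooths towards the prior null space
  Ml <- gn_map(J, "Laplace", lambda = 1e-8,
               adjacency = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  expect_equal(as.matrix(Ml), pinv, tolerance = 1e-4)
})

test_that("Gauss-Newton calibration closes for every prior", {
  m <- fix_small_mesh()
  grid <- rasterize(fix_circle_geometry())
  J2 <- fix_circle_J2()
  for (prior in c("Tikhonov", "NOSER", "Laplace")) {
    tr <- ventrecon:::gn_trainer(m, J2, grid,
                                 gn_config(nf = 0.3, prior = prior,
                                           background = "uniform"))
    cal <- calibrate_nf(tr$nf_at, 0.3)
    rm <- tr$matrix_at(cal$lambda)
    expect_lt(abs(noise_figure(rm) - 0.3) / 0.3, 0.01)
  }
})
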