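test_that("ap_profile aggregates rows into normalized bands", {
  img <- matrix(0, 32L, 32L)
  img[1L, ] <- 2
  p <- ap_profile(img)
  expect_equal(nrow(p), 32L)
  expect_equal(p$vd, c(100, rep(0, 31L)))
  expect_equal(sum(p$vd), 100)

  uni <- ap_profile(matrix(1, 32L, 32L))
  expect_equal(uni$vd, rep(100 / 32, 32L))

  # 128x128 image, mass uniform in rows 1..64 -> 6.25% in the first 16 bands
  big <- matrix(0, 128L, 128L)
  big[1:64, ] <- 1
  pb <- ap_profile(big)
  expect_equal(pb$vd, c(rep(6.25, 16L), rep(0, 16L)))

  # invariant to global positive scaling
  set.seed(4)
  r <- matrix(stats::runif(32 * 32), 32L)
  expect_equal(ap_profile(r)$vd, ap_profile(17.3 * r)$vd, tolerance = 1e-12)
  expect_error(ap_profile(matrix(0, 32L, 32L)), "not positive")
  expect_error(ap_profile(matrix(1, 16L, 16L)), "fewer rows")
})

test_that("profile RMSE follows its closed form and is symmetric", {
  a <- c(100, rep(0, 31L))
  b <- c(0, 100, rep(0, 30L))
  expect_equal(profile_rmse(a, a), 0)
  expect_equal(profile_rmse(a, b), 25)       # sqrt(2*100^2/32)
  expect_equal(profile_rmse(b, a), 25)
  expect_error(profile_rmse(a, b[1:16]), "interface error")
})

test_that("pooled Pearson matches a two-pass oracle and handles filters", {
  expect_equal(pooled_pearson(data.frame(ref = c(1, 2, 3), eit = c(2, 4, 6))), 1)
  expect_equal(pooled_pearson(data.frame(ref = c(1, 2, 4), eit = c(3, 5, 9))), 1)
  set.seed(12)
  d <- data.frame(ref = stats::runif(50, 0, 10), eit = stats::runif(50, 0, 10))
  r <- pooled_pearson(d, filter_zero = FALSE)
  # independent two-pass product-moment formula
  mx <- mean(d$ref); my <- mean(d$eit)
  r_oracle <- sum((d$ref - mx) * (d$eit - my)) /
    sqrt(sum((d$ref - mx)^2) * sum((d$eit - my)^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)
  # zero-zero pairs are dropped by the agreement filter
  d2 <- rbind(d, data.frame(ref = rep(0, 30L), eit = rep(0, 30L)))
  expect_equal(pooled_pearson(d2), r, tolerance = 1e-12)
  expect_error(pooled_pearson(data.frame(ref = c(1, 1, 1), eit = 1:3)),
               "zero variance")
})

test_that("Bland-Altman uses median bias and interpolated 95% quantiles", {
  same <- data.frame(ref = c(1, 2, 3, 4), eit = c(1, 2, 3, 4))
  ba <- bland_altman(same)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
  # worked quantile example: differences -2..2
  d <- data.frame(ref = rep(1, 5L), eit = 1 + c(-2, -1, 0, 1, 2))
  ba2 <- bland_altman(d)
  expect_equal(ba2$bias, 0)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(-2, 2))
  # both-zero pairs are excluded from the differences
  dz <- rbind(d, data.frame(ref = 0, eit = 0))
  expect_equal(bland_altman(dz)$n, 5L)
  expect_error(bland_altman(data.frame(ref = c(0, 0, 1), eit = c(0, 0, 2))),
               "retained pairs")
})

test_that("2D image correlation is affine-invariant over the body mask", {
  g <- make_phantom("averaged")
  grid <- rasterize(g)
  set.seed(6)
  ref <- matrix(stats::runif(128 * 128), 128L)
  eit <- block_mean(ref, 32L)
  expect_equal(image_correlation_2d(eit, ref, grid), 1, tolerance = 1e-12)
  expect_equal(image_correlation_2d(3 * eit + 2, ref, grid), 1, tolerance = 1e-12)
  # anti-correlated checkerboards
  chk <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  chk_ref <- chk[rep(1:32, each = 4L), rep(1:32, each = 4L)]
  expect_equal(image_correlation_2d(1 - chk, chk_ref, grid), -1, tolerance = 1e-12)
  expect_error(image_correlation_2d(matrix(1, 32L, 32L), ref, grid),
               "constant image")
})
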