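# Decorrelation-stretch enhancement: channel statistics, the whitening
# contract, and the percentile contrast stretch.

test_that("channel statistics match hand-computed population values", {
  img <- array(0, dim = c(2, 1, 3))
  img[2, 1, ] <- 255
  st <- channel_stats(img)
  expect_equal(st$means, rep(127.5, 3))
  expect_equal(unname(st$covariance), matrix(16256.25, 3, 3))

  flat <- array(77, dim = c(3, 3, 3))
  stf <- channel_stats(flat)
  expect_equal(unname(stf$covariance), matrix(0, 3, 3))
  expect_equal(stf$eigenvalues, c(0, 0, 0))

  one <- channel_stats(array(c(10, 20, 30), dim = c(1, 1, 3)))
  expect_equal(unname(one$covariance), matrix(0, 3, 3))
  expect_error(channel_stats(array(0, dim = c(0, 1, 3))), "at least one pixel")
})

test_that("eigen-decomposition is sorted, orthonormal and sign-fixed", {
  img <- correlated_image(8, seed = 7)
  st <- channel_stats(img)
  expect_true(all(diff(st$eigenvalues) <= 1e-12))
  expect_equal(crossprod(st$eigenvectors), diag(3), tolerance = 1e-8)
  for (j in 1:3) {
    expect_gt(st$eigenvectors[which.max(abs(st$eigenvectors[, j])), j], 0)
  }
  # reconstruction
  recon <- st$eigenvectors %*% diag(st$eigenvalues) %*% t(st$eigenvectors)
  expect_equal(recon, unname(st$covariance), tolerance = 1e-8)
})

test_that("independent channels show near-zero off-diagonal correlation", {
  set.seed(101)
  n <- 1e6
  side <- 1000
  arr <- array(pmin(pmax(rnorm(3 * n, 128, 25), 0), 255), dim = c(side, side, 3))
  st <- channel_stats(arr)
  cc <- stats::cov2cor(st$covariance)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.01)
})

test_that("whitening: pre-clip output covariance is target_sd^2 * I", {
  for (seed in c(3, 11, 29)) {
    img <- correlated_image(10, seed = seed, rho = 0.85)
    out <- decorrelation_stretch(img, target_sd = 50, clip = FALSE)
    X <- cbind(as.vector(out[, , 1]), as.vector(out[, , 2]), as.vector(out[, , 3]))
    S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
    expect_equal(unname(S), diag(50^2, 3), tolerance = 1e-6)
    expect_equal(colMeans(X), rep(127.5, 3), tolerance = 1e-8)
  }
})

test_that("already-white input reduces to per-channel standardization", {
  img <- orthogonal_design_image(s = 30, center = 120)
  out <- decorrelation_stretch(img, target_sd = 40, clip = FALSE)
  expected <- (img - 120) * (40 / 30) + 127.5
  expect_equal(as.vector(out), as.vector(expected), tolerance = 1e-8)
})

test_that("degenerate images return the recenter value", {
  flat <- array(200, dim = c(4, 4, 3))
  out <- decorrelation_stretch(flat)
  expect_true(all(out == 127.5))
  bad <- array(1, dim = c(2, 2, 3)); bad[1, 1, 1] <- NaN
  expect_error(decorrelation_stretch(bad), "non-finite")
})

test_that("output matches an independent per-pixel oracle on tiny images", {
  for (seed in c(5, 17)) {
    img <- correlated_image(4, seed = seed)   # 16 px
    out <- decorrelation_stretch(img, clip = FALSE)
    orc <- ds_oracle(img)
    expect_equal(as.vector(out), as.vector(orc), tolerance = 1e-8)
  }
})

test_that("re-applying the stretch is an affine per-channel map", {
  img <- correlated_image(8, seed = 23)
  # target_sd small enough that no clipping occurs, so the unclipped
  # composition is observable end to end
  once <- decorrelation_stretch(img, target_sd = 25, clip = FALSE)
  expect_true(min(once) >= 0 && max(once) <= 255)
  twice <- decorrelation_stretch(once, target_sd = 25, clip = FALSE)
  for (ch in 1:3) {
    fit <- stats::lm(as.vector(twice[, , ch]) ~ as.vector(once[, , ch]))
    expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  }
})

test_that("permuting input channels permutes output channels identically", {
  img <- correlated_image(8, seed = 31)
  perm <- c(3, 1, 2)
  out1 <- decorrelation_stretch(img, clip = FALSE)
  out2 <- decorrelation_stretch(img[, , perm], clip = FALSE)
  expect_equal(as.vector(out2), as.vector(out1[, , perm]), tolerance = 1e-8)
})

test_that("contrast stretch maps the stated percentiles to the full range", {
  # full-range channel with extreme percentiles is the identity
  v <- matrix(seq(0, 255, length.out = 64), 8, 8)
  img <- array(rep(v, 3), dim = c(8, 8, 3))
  expect_equal(contrast_stretch(img, 0, 100), img, ignore_attr = TRUE)
  # uniform [100, 150] stretches to [0, 255]
  u <- matrix(seq(100, 150, length.out = 64), 8, 8)
  img2 <- array(rep(u, 3), dim = c(8, 8, 3))
  out <- contrast_stretch(img2, 0, 100)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(out[, , 1], (u - 100) * 255 / 50, ignore_attr = TRUE)
  # constant channel passes through unchanged
  img3 <- array(42, dim = c(4, 4, 3))
  expect_equal(contrast_stretch(img3), img3, ignore_attr = TRUE)
  expect_error(contrast_stretch(img, 50, 10))
})
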