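# SIFT: pyramid structure, DoG identities, detection against a brute-force
# oracle, orientation behavior, descriptor contracts, and invariances.

test_that("scale-space pyramid has the documented geometry", {
  img <- matrix(runif(64 * 64) * 255, 64, 64)
  pyr <- build_scale_space(img)
  expect_equal(pyr$n_octaves, 4)                 # floor(log2(64)) - 2
  expect_equal(length(pyr$octaves[[1]]), 6)      # s + 3
  expect_equal(pyr$k, 2^(1 / 3), tolerance = 1e-12)
  # adjacent octave base is the downsampled level-s image
  seed <- pyr$octaves[[1]][[pyr$s + 1]]
  down <- seed[seq(1, nrow(seed), 2), seq(1, ncol(seed), 2)]
  expect_identical(pyr$octaves[[2]][[1]], down)
  expect_error(build_scale_space(matrix(0, 5, 5)), "at least 16x16")
})

test_that("constant images blur to constant levels and yield no keypoints", {
  pyr <- build_scale_space(matrix(100, 64, 64))
  for (o in pyr$octaves) for (lv in o) {
    expect_lt(max(lv) - min(lv), 1e-9)
  }
  kp <- detect_keypoints(build_dog(pyr))
  expect_equal(nrow(kp), 0)
})

test_that("DoG levels reconstruct the Gaussian pyramid bitwise", {
  pyr <- build_scale_space(test_patch("ear", seed = 4), n_octaves = 3)
  dog <- build_dog(pyr)
  for (o in seq_along(dog$octaves)) {
    expect_equal(length(dog$octaves[[o]]), length(pyr$octaves[[o]]) - 1)
    for (j in seq_along(dog$octaves[[o]])) {
      expect_identical(dog$octaves[[o]][[j]] + pyr$octaves[[o]][[j]],
                       pyr$octaves[[o]][[j + 1]])
    }
  }
})

test_that("a Gaussian blob is detected at its center and scale", {
  sigma_blob <- 4
  img <- blob_image(128, sigma_blob)   # center at (63.5, 63.5), 0-based
  pyr <- build_scale_space(img)
  dog <- build_dog(pyr)
  kp <- detect_keypoints(dog)
  expect_gt(nrow(kp), 0)
  best <- kp[which.max(abs(kp$response)), ]
  expect_lt(abs(best$x - 63.5), 2)
  expect_lt(abs(best$y - 63.5), 2)
  expect_lt(max(best$sigma / sigma_blob, sigma_blob / best$sigma), 1.5)

  # brute-force oracle: the globally strongest DoG voxel sits at the same
  # place in the original frame
  best_val <- 0; best_loc <- NULL
  for (o in seq_along(dog$octaves)) {
    pix <- dog$base_scale * 2^(o - 1)
    for (j in seq_along(dog$octaves[[o]])) {
      D <- dog$octaves[[o]][[j]]
      i <- which.max(abs(D))
      if (abs(D[i]) > best_val) {
        rc <- arrayInd(i, dim(D))
        best_val <- abs(D[i])
        best_loc <- c(x = (rc[2] - 1) * pix, y = (rc[1] - 1) * pix)
      }
    }
  }
  expect_lt(abs(best$x - best_loc["x"]), 2)
  expect_lt(abs(best$y - best_loc["y"]), 2)
})

test_that("an ideal step edge produces no surviving keypoints", {
  img <- matrix(0, 64, 64)
  img[, 33:64] <- 255
  kp <- detect_keypoints(build_dog(build_scale_space(img)))
  expect_equal(nrow(kp), 0)
})

test_that("orientation follows the gradient on a linear ramp", {
  size <- 64
  ramp_x <- matrix(rep(seq(0, 255, length.out = size), each = size), size,
                   byrow = FALSE)   # increases along +x (columns)
  pyr <- build_scale_space(ramp_x)
  kp <- data.frame(x = 32, y = 32, sigma = 3.2, octave = 0L, response = 0.1,
                   row_oct = 64, col_oct = 64, level_oct = 1, sig_oct = 2)
  class(kp) <- c("keypoints", "data.frame")
  ori <- assign_orientations(pyr, kp)
  ang <- ori$orientation[1]
  bw <- 2 * pi / 36
  expect_lt(min(ang, 2 * pi - ang), bw)   # ~0 rad, circularly

  # same ramp rotated 90 degrees: gradient now along +y
  ramp_y <- t(ramp_x)
  ori_y <- assign_orientations(build_scale_space(ramp_y), kp)
  expect_lt(abs(ori_y$orientation[1] - pi / 2), bw)
})

test_that("zero-gradient neighborhoods are flagged, not dropped silently", {
  pyr <- build_scale_space(matrix(100, 64, 64))
  kp <- data.frame(x = 32, y = 32, sigma = 3.2, octave = 0L, response = 0.1,
                   row_oct = 64, col_oct = 64, level_oct = 1, sig_oct = 2)
  class(kp) <- c("keypoints", "data.frame")
  ori <- assign_orientations(pyr, kp)
  expect_true(ori$degenerate[1])
  expect_equal(ori$orientation[1], 0)
})

test_that("descriptors are 128-long unit vectors", {
  fs <- extract_features(decorrelation_stretch(test_patch("ear", seed = 2)))
  expect_gt(nrow(fs$descriptors), 5)
  expect_equal(ncol(fs$descriptors), 128)
  norms <- sqrt(rowSums(fs$descriptors^2))
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-6)
  expect_true(all(fs$descriptors >= 0))
  expect_equal(nrow(fs$keypoints), nrow(fs$descriptors))
})

test_that("feature extraction is deterministic", {
  img <- test_patch("background", seed = 9)
  f1 <- extract_features(img)
  f2 <- extract_features(img)
  expect_identical(f1$descriptors, f2$descriptors)
  expect_identical(f1$keypoints, f2$keypoints)
})

test_that("90-degree rotation maps the keypoint set", {
  img <- decorrelation_stretch(test_patch("ear", seed = 6))
  f0 <- extract_features(img)
  # rotate image 90 degrees counter-clockwise: (x, y) -> (y, W-1-x)
  rot <- array(0, dim = dim(img))
  for (ch in 1:3) rot[, , ch] <- t(img[, , ch])[ncol(img[, , ch]):1, ]
  f1 <- extract_features(rot)
  n0 <- nrow(f0$keypoints); n1 <- nrow(f1$keypoints)
  expect_gt(n0, 10)
  expect_lt(abs(n1 - n0) / n0, 0.10)
  W <- f0$width
  mapped_x <- f0$keypoints$y
  mapped_y <- W - 1 - f0$keypoints$x
  d <- sapply(seq_len(n0), function(i) {
    min(sqrt((f1$keypoints$x - mapped_x[i])^2 + (f1$keypoints$y - mapped_y[i])^2))
  })
  expect_gt(mean(d < 1.5), 0.8)   # most keypoints have a mapped partner
})

test_that("descriptors are stable under 45-degree rotation", {
  # asymmetric two-blob figure so the dominant orientation is well defined
  size <- 128
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), size), size)
  fig <- 255 * (exp(-((xs - 64.5)^2 + (ys - 64.5)^2) / (2 * 25)) +
                0.6 * exp(-((xs - 80.5)^2 + (ys - 64.5)^2) / (2 * 9)))
  rot45 <- as.matrix(EBImage::rotate(EBImage::Image(t(fig / 255)), -45,
                                     output.dim = c(size, size))) |> t()
  rot45 <- rot45 * 255
  f0 <- extract_features(fig)
  f1 <- extract_features(rot45)
  pick_central <- function(f, cx, cy) {
    d <- sqrt((f$keypoints$x - cx)^2 + (f$keypoints$y - cy)^2)
    which.min(d)
  }
  i0 <- pick_central(f0, 63.5, 63.5)
  i1 <- pick_central(f1, 63.5, 63.5)
  cosine <- sum(f0$descriptors[i0, ] * f1$descriptors[i1, ])
  expect_gte(cosine, 0.8)
})

test_that("blob keypoints match across a 2x rescale", {
  size <- 96
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), size), size)
  fig <- 255 * (exp(-((xs - 48.5)^2 + (ys - 48.5)^2) / (2 * 16)) +
                0.6 * exp(-((xs - 60.5)^2 + (ys - 48.5)^2) / (2 * 6)))
  fig2 <- resize_bilinear_test(fig, 2 * size, 2 * size)
  f0 <- extract_features(fig)
  f1 <- extract_features(fig2)
  i0 <- which.min((f0$keypoints$x - 47.5)^2 + (f0$keypoints$y - 47.5)^2)
  i1 <- which.min((f1$keypoints$x - 2 * 47.5)^2 + (f1$keypoints$y - 2 * 47.5)^2)
  expect_lt(abs(f1$keypoints$sigma[i1] / f0$keypoints$sigma[i0] - 2), 0.8)
  cosine <- sum(f0$descriptors[i0, ] * f1$descriptors[i1, ])
  expect_gte(cosine, 0.8)
})

test_that("dense sampling mode produces a regular oriented grid", {
  img <- test_patch("ear", seed = 3)
  fs <- extract_features(img, params = list(dense = TRUE, dense_step = 16))
  expect_gt(nrow(fs$keypoints), 10)
  expect_true(all(fs$keypoints$orientation == 0))
  expect_true(all(fs$keypoints$x %% 16 == 0))
})
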