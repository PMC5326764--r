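# Spatial-pyramid pooling: region counts, layout, conservation, nesting
# and translation behavior.

one_hot <- function(word, K) { v <- numeric(K); v[word] <- 1; v }

test_that("region counts follow the 4^l geometric sum", {
  expect_equal(spm_region_count(3), 21)
  expect_equal(spm_region_count(1), 1)
  expect_equal(spm_region_count(2), 5)
})

test_that("the pooled vector has length regions x K", {
  codes <- matrix(one_hot(1, 2000), nrow = 1)
  v <- pool_spm(codes, matrix(c(10, 10), 1), c(100, 100), K = 2000)
  expect_equal(length(v), 42000)
  v1 <- pool_spm(codes, matrix(c(10, 10), 1), c(100, 100), K = 2000, levels = 1)
  expect_equal(length(v1), 2000)
})

test_that("hand-placed one-hot codes pool to the hand-computed 84-vector", {
  K <- 4
  # three keypoints on a 80x80 image: word 1 at (10,10) [top-left
  # everywhere], word 2 at (70,10) [top-right at levels 1-2], word 3 at
  # (50,50) [cell (2,2) at level 2]
  codes <- rbind(one_hot(1, K), one_hot(2, K), one_hot(3, K))
  pos <- rbind(c(10, 10), c(70, 10), c(50, 50))
  v <- pool_spm(codes, pos, c(80, 80), K = K, normalize = FALSE)
  expected <- numeric(21 * K)
  w <- c(0.25, 0.25, 0.5)
  # level 0: single cell
  expected[1:4] <- c(1, 1, 1, 0) * w[1]
  # level 1 (2x2, row-major): (10,10)->cell 0; (70,10)->cell 1; (50,50)->cell 3
  l1 <- function(cell, word) 4 + cell * K + word
  expected[l1(0, 1)] <- w[2]
  expected[l1(1, 2)] <- w[2]
  expected[l1(3, 3)] <- w[2]
  # level 2 (4x4, row-major): (10,10)->cell 0; (70,10)->cell 3; (50,50)->cell 10
  l2 <- function(cell, word) 4 + 16 + cell * K + word
  expected[l2(0, 1)] <- w[3]
  expected[l2(3, 2)] <- w[3]
  expected[l2(10, 3)] <- w[3]
  expect_equal(as.numeric(v), expected)
  # and the normalized version is the same vector scaled to unit L1 mass
  vn <- pool_spm(codes, pos, c(80, 80), K = K)
  expect_equal(as.numeric(vn), expected / sum(expected))
})

test_that("keypoints confined to one quadrant leave other cells empty", {
  K <- 3
  set.seed(4)
  n <- 20
  codes <- t(replicate(n, one_hot(sample(3, 1), K)))
  pos <- cbind(runif(n, 0, 39), runif(n, 0, 39))   # top-left quadrant of 80x80
  v <- pool_spm(codes, pos, c(80, 80), K = K, normalize = FALSE)
  lvl1 <- matrix(v[(K + 1):(5 * K)], nrow = K)   # 4 cells
  expect_true(all(lvl1[, 2:4] == 0))
  expect_gt(sum(lvl1[, 1]), 0)
})

test_that("sum pooling conserves keypoint mass per level", {
  K <- 5
  set.seed(8)
  n <- 17
  codes <- t(replicate(n, one_hot(sample(K, 1), K)))
  pos <- cbind(runif(n, 0, 64), runif(n, 0, 64))
  v <- pool_spm(codes, pos, c(64, 64), K = K, level_weights = c(1, 1, 1),
                normalize = FALSE)
  expect_equal(sum(v[1:K]), n)
  expect_equal(sum(v[(K + 1):(5 * K)]), n)
  expect_equal(sum(v[(5 * K + 1):(21 * K)]), n)
})

test_that("each level-1 cell equals the sum of its four level-2 children", {
  K <- 4
  set.seed(12)
  n <- 30
  codes <- t(replicate(n, one_hot(sample(K, 1), K)))
  pos <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  v <- pool_spm(codes, pos, c(100, 100), K = K, level_weights = c(1, 1, 1),
                normalize = FALSE)
  l1 <- array(v[(K + 1):(5 * K)], dim = c(K, 2, 2))      # [word, gx, gy]
  l2 <- array(v[(5 * K + 1):(21 * K)], dim = c(K, 4, 4))
  for (cy in 1:2) for (cx in 1:2) {
    children <- l2[, (2 * cx - 1):(2 * cx), (2 * cy - 1):(2 * cy)]
    expect_equal(l1[, cx, cy], apply(children, 1, sum))
  }
})

test_that("global histogram is translation invariant, finer levels are not", {
  K <- 3
  set.seed(16)
  n <- 12
  codes <- t(replicate(n, one_hot(sample(K, 1), K)))
  pos <- cbind(runif(n, 0, 49), runif(n, 0, 99))
  shifted <- pos; shifted[, 1] <- shifted[, 1] + 50   # half the width
  v0 <- pool_spm(codes, pos, c(100, 100), K = K, level_weights = c(1, 1, 1),
                 normalize = FALSE)
  v1 <- pool_spm(codes, shifted, c(100, 100), K = K, level_weights = c(1, 1, 1),
                 normalize = FALSE)
  expect_equal(v0[1:K], v1[1:K])
  expect_false(isTRUE(all.equal(v0[(K + 1):(5 * K)], v1[(K + 1):(5 * K)])))
})

test_that("max pooling and LLC codes stay non-negative via absolute values", {
  K <- 4
  codes <- rbind(c(0.7, -0.3, 0.6, 0), c(0.2, 0.9, -0.1, 0))
  pos <- rbind(c(5, 5), c(6, 6))
  vs <- pool_spm(codes, pos, c(10, 10), K = K, normalize = FALSE)
  vm <- pool_spm(codes, pos, c(10, 10), K = K, mode = "max", normalize = FALSE)
  expect_true(all(as.numeric(vs) >= 0))
  expect_true(all(as.numeric(vm) >= 0))
  expect_equal(vm[1:K], c(0.7, 0.9, 0.6, 0) * 0.25)
  expect_equal(vs[1:K], c(0.9, 1.2, 0.7, 0) * 0.25)
})

test_that("edge cases: empty codes warn, out-of-range positions error", {
  expect_warning(v <- pool_spm(matrix(0, 0, 4), matrix(0, 0, 2), c(10, 10), K = 4),
                 "no codes")
  expect_equal(as.numeric(v), rep(0, 84))
  expect_true(attr(v, "empty"))
  codes <- matrix(one_hot(1, 4), nrow = 1)
  expect_error(pool_spm(codes, matrix(c(10, 10), 1), c(10, 10), K = 4),
               "positions")
})
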