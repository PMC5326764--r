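# Shared fixtures and independent oracles, all built in code.

# Image whose empirical (population) channel covariance is exactly s^2 * I:
# the 8 sign patterns of {-1, +1}^3, scaled and shifted into [0, 255].
orthogonal_design_image <- function(s = 30, center = 120) {
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  arr <- array(0, dim = c(2, 4, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(center + s * g[, ch], 2, 4)
  arr
}

# Small correlated-channel image for whitening checks.
correlated_image <- function(n_side = 8, seed = 42, rho = 0.9) {
  set.seed(seed)
  n <- n_side^2
  shared <- rnorm(n)
  arr <- array(0, dim = c(n_side, n_side, 3))
  for (ch in 1:3) {
    v <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
    arr[, , ch] <- matrix(120 + 30 * v, n_side, n_side)
  }
  pmin(pmax(arr, 0), 255)
}

# Independent decorrelation-stretch oracle: per-pixel loops, explicit
# covariance accumulation and an explicit whitening product, sharing no
# code with the package implementation.
ds_oracle <- function(image, target_sd = 50, recenter = 127.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  n <- H * W
  mu <- c(0, 0, 0)
  for (r in 1:H) for (c in 1:W) mu <- mu + image[r, c, ]
  mu <- mu / n
  S <- matrix(0, 3, 3)
  for (r in 1:H) for (c in 1:W) {
    d <- image[r, c, ] - mu
    S <- S + d %o% d
  }
  S <- S / n
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  delta <- 1e-6 * max(e$values)
  Tm <- V %*% diag(1 / sqrt(pmax(e$values, delta))) %*% t(V)
  out <- array(0, dim = dim(image))
  for (r in 1:H) for (c in 1:W) {
    out[r, c, ] <- as.numeric(Tm %*% (image[r, c, ] - mu)) * target_sd + recenter
  }
  out
}

# Centered Gaussian blob on black, the canonical scale-space fixture.
blob_image <- function(size = 128, sigma_blob = 4, center = (size + 1) / 2,
                       amplitude = 255) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), size), size)
  amplitude * exp(-((xs - center)^2 + (ys - center)^2) / (2 * sigma_blob^2))
}

empirical_channel_cor <- function(image) {
  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  stats::cor(X)
}

# Equality-constrained least-squares oracle for LLC: solves
#   min ||x - B'c||^2 + reg ||c||^2  s.t.  sum(c) = 1
# through the full KKT system, independently of the covariance-solve route
# used by the implementation. B is k x d (rows are the local basis).
llc_kkt_oracle <- function(B, x, lambda) {
  k <- nrow(B)
  Z <- B - matrix(x, k, length(x), byrow = TRUE)
  reg <- lambda * sum(Z^2)
  if (reg <= 0) reg <- lambda
  G <- B %*% t(B) + diag(reg, k)
  KKT <- rbind(cbind(2 * G, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(2 * as.numeric(B %*% x), 1)
  solve(KKT, rhs)[seq_len(k)]
}

# Exhaustive K-means oracle: minimal within-cluster sum of squares over
# every assignment of n points to K non-empty clusters.
kmeans_exhaustive <- function(X, K) {
  n <- nrow(X)
  best <- list(cost = Inf)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, ]
    if (length(unique(a)) < K) next
    cost <- 0
    centers <- matrix(0, K, ncol(X))
    for (k in seq_len(K)) {
      pts <- X[a == k, , drop = FALSE]
      centers[k, ] <- colMeans(pts)
      cost <- cost + sum(sweep(pts, 2, centers[k, ])^2)
    }
    if (cost < best$cost - 1e-12) best <- list(cost = cost, centers = centers)
  }
  best
}

# Seeded default-condition patches, shared across test files.
test_patch <- function(class = "ear", seed = 1, ...) {
  make_patch(fixture_spec(class, seed = seed, ...))$image
}

sorted_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

resize_bilinear_test <- function(m, h, w) {
  t(as.matrix(EBImage::resize(EBImage::Image(t(m / 255)), w = w, h = h))) * 255
}

# One small dataset and feature cache shared across pipeline test blocks.
.pipeline_env <- new.env(parent = emptyenv())
pipeline_test_dataset <- function() {
  if (is.null(.pipeline_env$ds)) {
    dir <- file.path(tempdir(), "spikesight-test-ds")
    unlink(dir, recursive = TRUE)
    .pipeline_env$ds <- make_dataset(8, seed = 42, out_dir = dir, size = 64)
    .pipeline_env$cache <- feature_cache()
  }
  list(ds = .pipeline_env$ds, cache = .pipeline_env$cache)
}

pipeline_test_config <- function(k = 25) {
  cfg <- default_config()
  cfg$codebook$k <- k
  cfg
}
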