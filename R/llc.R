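# Descriptor-to-codebook projection: locality-constrained linear coding
# (approximated LLC: constrained least squares over the k nearest
# codewords) and hard vector quantization as the ablation baseline.
# Codes are returned as sparse n x K matrices (rows sum to 1).

#' Locality-constrained linear coding
#'
#' Encodes each descriptor as an affine combination (weights summing to 1)
#' of its `k_nn` nearest codebook centers, minimizing the local
#' reconstruction error \code{||x - B'c||^2 + lambda*tr(C_local)*||c||^2}
#' subject to \code{sum(c) = 1}, solved in closed form through the local
#' covariance system. Weights may be negative (the constraint is affine);
#' all remaining entries of the K-vector are zero.
#'
#' @param codebook A [fit_kmeans()] codebook.
#' @param descriptors A descriptor vector or n x d matrix.
#' @param k_nn Number of nearest centers in the local basis; default 5.
#' @param lambda Regularization of the local covariance (relative to its
#'   trace); default 1e-4. Also the absolute ridge when the local
#'   covariance is exactly zero (descriptor coincides with every neighbor).
#' @return A sparse `Matrix::dgCMatrix` of dimension n x K; each row holds
#'   at most `k_nn` nonzeros summing to 1. Attribute `method = "llc"`.
#' @export
encode_llc <- function(codebook, descriptors, k_nn = 5, lambda = 1e-4) {
  stopifnot(inherits(codebook, "codebook"))
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, nrow = 1)
  if (any(!is.finite(X))) stop("descriptors must be finite")
  K <- codebook$K
  k_nn <- as.integer(k_nn)
  if (k_nn < 1L || k_nn > K) stop("k_nn must be between 1 and K = ", K)
  n <- nrow(X)
  d2 <- pairwise_sqdist(X, codebook$centers)
  ii <- integer(n * k_nn); jj <- integer(n * k_nn); ww <- numeric(n * k_nn)
  ones <- rep(1, k_nn)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k_nn)]          # stable: ties -> lowest index
    Z <- codebook$centers[nb, , drop = FALSE] -
      matrix(X[i, ], k_nn, ncol(X), byrow = TRUE)
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    reg <- if (tr > 0) lambda * tr else lambda
    diag(G) <- diag(G) + reg
    w <- solve(G, ones)
    w <- w / sum(w)
    sl <- ((i - 1L) * k_nn + 1L):(i * k_nn)
    ii[sl] <- i; jj[sl] <- nb; ww[sl] <- w
  }
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, K))
  attr(out, "method") <- "llc"
  out
}

#' Hard vector-quantization coding
#'
#' One-hot baseline coder: each descriptor maps to weight 1 on its nearest
#' codeword (ties to the lowest index) and 0 elsewhere.
#'
#' @inheritParams encode_llc
#' @return A sparse n x K matrix with exactly one 1 per row. Attribute
#'   `method = "hard"`.
#' @export
encode_hard <- function(codebook, descriptors) {
  stopifnot(inherits(codebook, "codebook"))
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, nrow = 1)
  idx <- assign_nearest(codebook, X)
  out <- Matrix::sparseMatrix(i = seq_len(nrow(X)), j = idx, x = 1,
                              dims = c(nrow(X), codebook$K))
  attr(out, "method") <- "hard"
  out
}

# Reconstruction error ||x - sum_j c_j b_j|| of one coded descriptor.
llc_reconstruction_error <- function(codebook, descriptor, code_row) {
  recon <- as.numeric(code_row %*% codebook$centers)
  sqrt(sum((descriptor - recon)^2))
}
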