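#' Per-channel statistics of an RGB image
#'
#' Computes the channel means, the 3 x 3 population covariance (denominator
#' n) or correlation matrix across all pixels, and its eigen-decomposition.
#' Eigenvalues are sorted in descending order; each eigenvector column's
#' sign is fixed so that its largest-magnitude entry is positive (first
#' index on ties), making the decomposition deterministic.
#'
#' @param image height x width x 3 array on \code{[0, 255]}.
#' @param matrix Decompose the `"covariance"` (default) or `"correlation"`
#'   matrix between the RGB bands.
#' @return An object of class `channel_stats`: list with `means`
#'   (length 3), `covariance` (3 x 3; the decomposed matrix), `eigenvalues`
#'   (descending) and `eigenvectors` (orthonormal columns).
#' @export
channel_stats <- function(image, matrix = c("covariance", "correlation")) {
  image <- validate_image(image)
  matrix <- match.arg(matrix)
  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  S <- crossprod(Xc) / n
  if (matrix == "correlation") {
    sd <- sqrt(diag(S))
    sd[sd == 0] <- 1       # flat channel: leave unit-scaled, correlation 0
    S <- S / (sd %o% sd)
    diag(S)[diag(crossprod(Xc) / n) == 0] <- 0
  }
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(means = mu, covariance = S, eigenvalues = e$values, eigenvectors = V,
         n_pixels = n, matrix = matrix),
    class = "channel_stats"
  )
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("channel_stats (", x$matrix, ", ", x$n_pixels, " px)\n", sep = "")
  cat("means:", format(x$means, digits = 5), "\n")
  cat("eigenvalues:", format(x$eigenvalues, digits = 5), "\n")
  invisible(x)
}

#' Decorrelation stretch of an RGB image
#'
#' Removes inter-channel correlation by PCA whitening and re-stretches the
#' result for display: pixels are mean-centered, rotated into the principal
#' axes of the channel covariance, scaled component-wise by
#' \code{1/sqrt(v_i)} (so every principal component gets unit variance),
#' rotated back to RGB, multiplied by `target_sd` and re-centered at
#' mid-range. Subtle color differences between spectrally similar surfaces
#' (young ears against leaves) are thereby exaggerated, and the output
#' channel statistics no longer depend on the scene's ambient illumination.
#'
#' Degenerate eigenvalues are floored at \code{delta = 1e-6 * max(v)} before
#' inversion, so flat channels stretch to nothing instead of dividing by
#' zero; for every eigenvalue above that floor the whitening is exact and
#' the pre-clip output covariance is \code{target_sd^2 * I}.
#'
#' @param image height x width x 3 array on \code{[0, 255]}.
#' @param target_sd Standard deviation applied to every output channel
#'   (intensity units); default 50.
#' @param recenter Output channel mean (intensity units); default 127.5,
#'   mid-range for 8-bit display.
#' @param matrix Whiten against the `"covariance"` (default) or
#'   `"correlation"` matrix; with `"correlation"` each channel is first
#'   standardized by its own standard deviation.
#' @param clip Clip the result to \code{[0, 255]} (default). Set `FALSE` to
#'   inspect the raw whitened values, e.g. to verify the covariance
#'   contract.
#' @return The enhanced image (same shape), with attribute `provenance`
#'   recording the parameters used.
#' @export
decorrelation_stretch <- function(image, target_sd = 50, recenter = 127.5,
                                  matrix = c("covariance", "correlation"),
                                  clip = TRUE) {
  image <- validate_image(image)
  matrix <- match.arg(matrix)
  stopifnot(target_sd > 0)
  st <- channel_stats(image, matrix = matrix)
  d <- dim(image)
  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  Xc <- sweep(X, 2L, st$means)
  if (matrix == "correlation") {
    sdv <- sqrt(diag(crossprod(Xc) / nrow(Xc)))
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2L, sdv, "/")
  }
  v <- st$eigenvalues
  R <- st$eigenvectors
  if (max(v) <= 0) {
    out <- array(recenter, dim = d)
  } else {
    delta <- 1e-6 * max(v)
    Tm <- R %*% diag(1 / sqrt(pmax(v, delta))) %*% t(R)   # symmetric whitener
    Y <- (Xc %*% Tm) * target_sd + recenter
    out <- array(Y, dim = d)
  }
  if (clip) out <- pmin(pmax(out, 0), 255)
  attr(out, "provenance") <- list(target_sd = target_sd, recenter = recenter,
                                  matrix = matrix, clipped = clip)
  out
}

#' Percentile contrast stretch
#'
#' Per-channel linear rescale mapping the `low_pct` percentile to 0 and the
#' `high_pct` percentile to 255, clipped. A channel with zero dynamic range
#' between the two percentiles passes through unchanged.
#'
#' @param image height x width x 3 array.
#' @param low_pct,high_pct Percentiles in \code{[0, 100]}, `low_pct <
#'   high_pct`.
#' @return The stretched image.
#' @export
contrast_stretch <- function(image, low_pct = 1, high_pct = 99) {
  image <- validate_image(image)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  for (ch in 1:3) {
    v <- image[, , ch]
    q <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE)
    if (q[2] <= q[1]) next
    image[, , ch] <- pmin(pmax((v - q[1]) * 255 / (q[2] - q[1]), 0), 255)
  }
  image
}
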