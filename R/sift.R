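# Scale-invariant feature transform: scale-space pyramid, DoG extrema,
# sub-pixel keypoint refinement, orientation histograms and 4x4x8 gradient
# descriptors. All geometry is kept in two frames: the "octave frame"
# (pixel grid of one pyramid octave, used for sampling windows) and the
# original-image frame (0-based x = column, y = row, used in all outputs).

gaussian_blur <- function(m, sigma) {
  if (sigma < 1e-8) return(m)
  r <- max(1L, ceiling(3 * sigma))
  # filter2 requires the kernel to fit inside the image
  r <- min(r, (min(dim(m)) - 1L) %/% 2L)
  if (r < 1L) return(m)
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  k <- outer(g, g)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

resize_bilinear <- function(m, h, w) {
  as.matrix(EBImage::resize(EBImage::Image(t(m)), w = w, h = h)) |> t()
}

#' Build a Gaussian scale-space pyramid
#'
#' Constructs the multi-octave stack of progressively blurred images that
#' underlies SIFT detection. Each octave holds `scales_per_octave + 3`
#' levels separated by the constant factor \code{k = 2^(1/s)}; the next
#' octave starts from the level with twice the base blur, downsampled by 2.
#' With `upsample = TRUE` (the default) the input is first doubled by
#' bilinear interpolation, which roughly doubles the number of usable
#' small-scale keypoints.
#'
#' @param image Single-channel matrix (intensities on \code{[0, 255]} or
#'   \code{[0, 1]}; internally rescaled to \code{[0, 1]}). A 3-channel
#'   array is converted to luminance.
#' @param sigma0 Base smoothing scale of each octave (pixels); default 1.6.
#' @param scales_per_octave Number of scales `s` sampled per octave
#'   (default 3), so adjacent levels differ by \code{k = 2^(1/s)}.
#' @param n_octaves Number of octaves, or `NULL` (default) for
#'   \code{floor(log2(min(H, W))) - 2}, computed on the input size.
#' @param upsample Double the image before the first octave (default TRUE).
#' @param assumed_blur Blur assumed already present in the input (pixels);
#'   default 0.5.
#' @return An object of class `gaussian_pyramid`.
#' @export
build_scale_space <- function(image, sigma0 = 1.6, scales_per_octave = 3,
                              n_octaves = NULL, upsample = TRUE,
                              assumed_blur = 0.5) {
  if (length(dim(image)) == 3L) image <- luminance(image)
  m <- as.matrix(image)
  if (max(m) > 1 + 1e-9) m <- m / 255
  H <- nrow(m); W <- ncol(m)
  base_scale <- if (upsample) 0.5 else 1
  h0 <- round(H / base_scale); w0 <- round(W / base_scale)
  if (min(h0, w0) < 16L) {
    stop("image too small for scale-space construction: need at least 16x16 ",
         "pixels after optional 2x upsampling, got ", h0, "x", w0)
  }
  s <- as.integer(scales_per_octave)
  stopifnot(s >= 1L)
  k <- 2^(1 / s)
  if (is.null(n_octaves)) n_octaves <- floor(log2(min(H, W))) - 2
  # keep the top octave at least 8 px on a side
  n_max <- floor(log2(min(h0, w0) / 8)) + 1
  n_octaves <- max(1L, min(as.integer(n_octaves), n_max))

  base <- if (upsample) resize_bilinear(m, h0, w0) else m
  cur_blur <- assumed_blur / base_scale
  if (sigma0 > cur_blur) base <- gaussian_blur(base, sqrt(sigma0^2 - cur_blur^2))

  octaves <- vector("list", n_octaves)
  for (o in seq_len(n_octaves)) {
    levels <- vector("list", s + 3L)
    levels[[1]] <- base
    for (j in 2:(s + 3L)) {
      sig_prev <- sigma0 * k^(j - 2)
      sig_next <- sigma0 * k^(j - 1)
      levels[[j]] <- gaussian_blur(levels[[j - 1]], sqrt(sig_next^2 - sig_prev^2))
    }
    octaves[[o]] <- levels
    if (o < n_octaves) {
      seed <- levels[[s + 1L]]   # blur sigma0 * 2 relative to this octave
      base <- seed[seq(1L, nrow(seed), by = 2L), seq(1L, ncol(seed), by = 2L), drop = FALSE]
    }
  }
  structure(
    list(octaves = octaves, sigma0 = sigma0, k = k, s = s,
         n_octaves = n_octaves, base_scale = base_scale,
         width = W, height = H),
    class = "gaussian_pyramid"
  )
}

#' @export
print.gaussian_pyramid <- function(x, ...) {
  cat("gaussian_pyramid:", x$n_octaves, "octaves x", x$s + 3, "levels, sigma0 =",
      x$sigma0, ", k =", format(x$k, digits = 5), "\n")
  invisible(x)
}

#' Difference-of-Gaussians pyramid
#'
#' Subtracts adjacent scale-space levels within each octave, the band-pass
#' approximation of the scale-normalized Laplacian used for keypoint
#' detection. Each octave ends up with one level fewer than its Gaussian
#' counterpart.
#'
#' @param pyramid A [build_scale_space()] result.
#' @return An object of class `dog_pyramid`.
#' @export
build_dog <- function(pyramid) {
  stopifnot(inherits(pyramid, "gaussian_pyramid"))
  octaves <- lapply(pyramid$octaves, function(levels) {
    lapply(seq_len(length(levels) - 1L), function(j) levels[[j + 1L]] - levels[[j]])
  })
  structure(
    list(octaves = octaves, sigma0 = pyramid$sigma0, k = pyramid$k, s = pyramid$s,
         n_octaves = pyramid$n_octaves, base_scale = pyramid$base_scale,
         width = pyramid$width, height = pyramid$height),
    class = "dog_pyramid"
  )
}

# Strict 26-neighbor extrema of a DoG octave stack, interior voxels only.
# Returns an integer matrix of (row, col, level) candidates.
local_extrema <- function(A, prefilter) {
  H <- dim(A)[1]; W <- dim(A)[2]; L <- dim(A)[3]
  if (H < 3L || W < 3L || L < 3L) return(matrix(integer(0), ncol = 3))
  out <- vector("list", L - 2L)
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  for (j in 2:(L - 1L)) {
    ctr <- A[ri, ci, j]
    mx <- NULL; mn <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0L && dy == 0L && dx == 0L) next
      nb <- A[ri + dy, ci + dx, j + dz]
      if (is.null(mx)) { mx <- nb; mn <- nb } else { mx <- pmax(mx, nb); mn <- pmin(mn, nb) }
    }
    hit <- (abs(ctr) > prefilter) & ((ctr > mx) | (ctr < mn))
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) out[[j - 1L]] <- cbind(idx[, 1] + 1L, idx[, 2] + 1L, j)
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 3))))
}

# Quadratic refinement of one candidate in the octave DoG stack.
# Returns NULL (rejected) or list(r, c, j, offset, value, edge_ok).
refine_candidate <- function(A, r, c, j, contrast_threshold, edge_ratio) {
  H <- dim(A)[1]; W <- dim(A)[2]; L <- dim(A)[3]
  for (it in 1:5) {
    D <- A[r, c, j]
    g <- c((A[r, c + 1, j] - A[r, c - 1, j]) / 2,    # d/dx
           (A[r + 1, c, j] - A[r - 1, c, j]) / 2,    # d/dy
           (A[r, c, j + 1] - A[r, c, j - 1]) / 2)    # d/ds
    dxx <- A[r, c + 1, j] + A[r, c - 1, j] - 2 * D
    dyy <- A[r + 1, c, j] + A[r - 1, c, j] - 2 * D
    dss <- A[r, c, j + 1] + A[r, c, j - 1] - 2 * D
    dxy <- (A[r + 1, c + 1, j] - A[r + 1, c - 1, j] -
            A[r - 1, c + 1, j] + A[r - 1, c - 1, j]) / 4
    dxs <- (A[r, c + 1, j + 1] - A[r, c - 1, j + 1] -
            A[r, c + 1, j - 1] + A[r, c - 1, j - 1]) / 4
    dys <- (A[r + 1, c, j + 1] - A[r - 1, c, j + 1] -
            A[r + 1, c, j - 1] + A[r - 1, c, j - 1]) / 4
    Hm <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3)
    off <- tryCatch(-solve(Hm, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(NULL)
    off <- pmin(pmax(off, -1), 1)   # clamp pathological steps
    if (max(abs(off)) <= 0.5) {
      val <- D + 0.5 * sum(g * off)
      if (abs(val) < contrast_threshold) return(NULL)
      tr <- dxx + dyy
      det <- dxx * dyy - dxy^2
      r_e <- edge_ratio
      if (det <= 0 || tr^2 / det >= (r_e + 1)^2 / r_e) return(NULL)
      return(list(r = r, c = c, j = j, offset = off, value = val))
    }
    c <- c + round(off[1]); r <- r + round(off[2]); j <- j + round(off[3])
    if (r < 2L || r > H - 1L || c < 2L || c > W - 1L || j < 2L || j > L - 1L) return(NULL)
  }
  NULL
}

#' Detect scale-space keypoints
#'
#' Finds strict extrema among the 26 space-scale neighbors of every interior
#' DoG voxel (the 3 x 3 spatial neighborhood in the same, previous and next
#' scale), refines each candidate by quadratic sub-pixel interpolation, and
#' rejects low-contrast responses (|interpolated DoG| below
#' `contrast_threshold`, on \code{[0, 1]}-scaled intensities) and edge-like
#' responses whose spatial-Hessian trace-squared-to-determinant ratio is at
#' least \code{(edge_ratio + 1)^2 / edge_ratio}. Candidates within one pixel
#' of any spatial or scale border are skipped.
#'
#' @param dog A [build_dog()] result.
#' @param contrast_threshold Minimum absolute interpolated DoG response;
#'   default 0.03.
#' @param edge_ratio Maximum principal-curvature ratio; default 10.
#' @return A data.frame of class `keypoints`: `x`, `y` (sub-pixel, 0-based,
#'   original-image frame), `sigma` (absolute scale, original frame),
#'   `octave` (0-based), `response`, plus octave-frame bookkeeping columns
#'   (`row_oct`, `col_oct`, `level_oct`, `sig_oct`) consumed by the
#'   orientation and descriptor stages.
#' @export
detect_keypoints <- function(dog, contrast_threshold = 0.03, edge_ratio = 10) {
  stopifnot(inherits(dog, "dog_pyramid"))
  rows <- list()
  pix0 <- dog$base_scale
  for (o in seq_len(dog$n_octaves)) {
    A <- simplify2array(dog$octaves[[o]])
    cand <- local_extrema(A, prefilter = 0.5 * contrast_threshold)
    if (!nrow(cand)) next
    pix <- pix0 * 2^(o - 1)
    for (i in seq_len(nrow(cand))) {
      kp <- refine_candidate(A, cand[i, 1], cand[i, 2], cand[i, 3],
                             contrast_threshold, edge_ratio)
      if (is.null(kp)) next
      scale_idx <- (kp$j - 1) + kp$offset[3]           # 0-based in-octave level
      x <- (kp$c - 1 + kp$offset[1]) * pix
      y <- (kp$r - 1 + kp$offset[2]) * pix
      if (x < 0 || x >= dog$width || y < 0 || y >= dog$height) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = x, y = y,
        sigma = dog$sigma0 * dog$k^scale_idx * pix,
        octave = o - 1L, response = kp$value,
        row_oct = kp$r - 1 + kp$offset[2], col_oct = kp$c - 1 + kp$offset[1],
        level_oct = scale_idx, sig_oct = dog$sigma0 * dog$k^scale_idx
      )
    }
  }
  kp <- if (length(rows)) do.call(rbind, rows) else data.frame(
    x = numeric(0), y = numeric(0), sigma = numeric(0), octave = integer(0),
    response = numeric(0), row_oct = numeric(0), col_oct = numeric(0),
    level_oct = numeric(0), sig_oct = numeric(0))
  class(kp) <- c("keypoints", "data.frame")
  kp
}

# Per-level image gradients, cached inside a pyramid-scoped environment.
# Borders carry zero gradient.
level_gradients <- function(pyr, cache, o, lvl) {
  key <- paste0(o, ".", lvl)
  if (!is.null(cache[[key]])) return(cache[[key]])
  L <- pyr$octaves[[o]][[lvl]]
  H <- nrow(L); W <- ncol(L)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3) gx[, 2:(W - 1)] <- (L[, 3:W] - L[, 1:(W - 2)]) / 2
  if (H >= 3) gy[2:(H - 1), ] <- (L[3:H, ] - L[1:(H - 2), ]) / 2
  cache[[key]] <- list(gx = gx, gy = gy)
  cache[[key]]
}

# Nearest Gaussian level index for a keypoint's interpolated scale.
nearest_level <- function(pyr, level_oct) {
  min(max(round(level_oct) + 1L, 1L), pyr$s + 3L)
}

#' Assign keypoint orientations
#'
#' For each keypoint, accumulates a 36-bin histogram of gradient
#' orientations over a Gaussian-weighted window (weight sigma = 1.5 x the
#' keypoint's in-octave scale) on the Gaussian level nearest the keypoint's
#' scale, then assigns the dominant peak (parabolic interpolation). Every
#' additional local peak reaching 80% of the maximum emits a duplicate
#' keypoint with that orientation. A zero-gradient window keeps orientation
#' 0 and is flagged `degenerate`.
#'
#' @param pyramid The [build_scale_space()] pyramid the keypoints came from.
#' @param keypoints A [detect_keypoints()] data.frame.
#' @param n_bins Histogram bins over \code{[0, 2*pi)}; default 36.
#' @param peak_ratio Secondary-peak acceptance ratio; default 0.8.
#' @return The keypoints with `orientation` (radians in \code{[0, 2*pi)})
#'   and `degenerate` columns, possibly with duplicated rows.
#' @export
assign_orientations <- function(pyramid, keypoints, n_bins = 36, peak_ratio = 0.8) {
  stopifnot(inherits(pyramid, "gaussian_pyramid"))
  if (!nrow(keypoints)) {
    keypoints$orientation <- numeric(0)
    keypoints$degenerate <- logical(0)
    return(keypoints)
  }
  cache <- new.env(parent = emptyenv())
  bw <- 2 * pi / n_bins
  out <- vector("list", nrow(keypoints))
  for (i in seq_len(nrow(keypoints))) {
    kp <- keypoints[i, ]
    o <- kp$octave + 1L
    lvl <- nearest_level(pyramid, kp$level_oct)
    gr <- level_gradients(pyramid, cache, o, lvl)
    H <- nrow(gr$gx); W <- ncol(gr$gx)
    sw <- 1.5 * kp$sig_oct
    rad <- max(2L, round(3 * sw))
    rc <- kp$row_oct + 1; cc <- kp$col_oct + 1        # 1-based octave frame
    r0 <- max(1L, floor(rc - rad)); r1 <- min(H, ceiling(rc + rad))
    c0 <- max(1L, floor(cc - rad)); c1 <- min(W, ceiling(cc + rad))
    rs <- r0:r1; cs <- c0:c1
    gx <- gr$gx[rs, cs, drop = FALSE]; gy <- gr$gy[rs, cs, drop = FALSE]
    mag <- sqrt(gx^2 + gy^2)
    dr <- outer(rs - rc, rep(1, length(cs)))
    dc <- outer(rep(1, length(rs)), cs - cc)
    wgt <- exp(-(dr^2 + dc^2) / (2 * sw^2)) * mag
    hist <- numeric(n_bins)
    nz <- which(mag > 1e-10)   # guard against FFT round-off on flat windows
    if (length(nz)) {
      ang <- atan2(gy[nz], gx[nz]) %% (2 * pi)
      bin <- (floor(ang / bw) %% n_bins) + 1L
      acc <- rowsum(wgt[nz], bin)
      hist[as.integer(rownames(acc))] <- acc
    }
    if (max(hist) <= 0) {
      kp$orientation <- 0; kp$degenerate <- TRUE
      out[[i]] <- kp
      next
    }
    for (pass in 1:2) {   # circular [1,1,1]/3 smoothing
      hist <- (c(hist[n_bins], hist[-n_bins]) + hist + c(hist[-1], hist[1])) / 3
    }
    hmax <- max(hist)
    left <- c(hist[n_bins], hist[-n_bins]); right <- c(hist[-1], hist[1])
    peaks <- which(hist >= peak_ratio * hmax & hist > left & hist >= right)
    if (!length(peaks)) peaks <- which.max(hist)
    rows <- lapply(peaks, function(b) {
      denom <- hist[b] - 0.5 * (left[b] + right[b])
      off <- if (abs(denom) > 1e-12) 0.5 * (left[b] - right[b]) / (2 * denom) else 0
      off <- min(max(off, -0.5), 0.5)
      k2 <- kp
      k2$orientation <- ((b - 1 + 0.5 + off) * bw) %% (2 * pi)
      k2$degenerate <- FALSE
      k2
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  class(res) <- c("keypoints", "data.frame")
  rownames(res) <- NULL
  res
}

#' Compute 128-element SIFT descriptors
#'
#' Samples a 16 x 16 grid around each keypoint (spacing scaled by the
#' keypoint's scale, grid rotated to its orientation), bilinearly
#' interpolates image gradients, and accumulates a trilinearly-binned
#' 4 x 4 spatial x 8 orientation histogram with a Gaussian spatial weight.
#' The 128-vector is Euclidean-normalized, clipped at 0.2, and normalized
#' again. Samples falling outside the image contribute nothing; a window
#' with no gradient yields an all-zero descriptor flagged in the result.
#'
#' @param pyramid The [build_scale_space()] pyramid.
#' @param keypoints Oriented keypoints from [assign_orientations()].
#' @return A list: `descriptors` (n x 128 matrix) and `flagged` (logical,
#'   TRUE for degenerate all-zero descriptors).
#' @export
compute_descriptors <- function(pyramid, keypoints) {
  stopifnot(inherits(pyramid, "gaussian_pyramid"))
  n <- nrow(keypoints)
  D <- matrix(0, n, 128)
  flagged <- rep(FALSE, n)
  if (!n) return(list(descriptors = D, flagged = flagged))
  if (is.null(keypoints$orientation)) stop("keypoints must be oriented first")
  cache <- new.env(parent = emptyenv())
  d_grid <- 4L; n_ori <- 8L
  grid <- as.matrix(expand.grid(i = 0:15, j = 0:15))
  for (i in seq_len(n)) {
    kp <- keypoints[i, ]
    if (isTRUE(kp$degenerate)) { flagged[i] <- TRUE; next }
    o <- kp$octave + 1L
    lvl <- nearest_level(pyramid, kp$level_oct)
    gr <- level_gradients(pyramid, cache, o, lvl)
    H <- nrow(gr$gx); W <- ncol(gr$gx)
    hw <- 3 * kp$sig_oct              # histogram (spatial bin) width, pixels
    step <- hw / 4
    th <- kp$orientation
    ct <- cos(th); st <- sin(th)
    u <- (grid[, 1] - 7.5) * step     # along-orientation offset
    v <- (grid[, 2] - 7.5) * step
    px <- kp$col_oct + 1 + ct * u - st * v   # 1-based octave-frame col
    py <- kp$row_oct + 1 + st * u + ct * v   # 1-based octave-frame row
    r0 <- floor(py); c0 <- floor(px)
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    if (!any(ok)) { flagged[i] <- TRUE; next }
    r0k <- r0[ok]; c0k <- c0[ok]
    fr <- py[ok] - r0k; fc <- px[ok] - c0k
    i00 <- cbind(r0k, c0k); i01 <- cbind(r0k, c0k + 1)
    i10 <- cbind(r0k + 1, c0k); i11 <- cbind(r0k + 1, c0k + 1)
    gx <- gr$gx[i00] * (1 - fr) * (1 - fc) + gr$gx[i01] * (1 - fr) * fc +
          gr$gx[i10] * fr * (1 - fc) + gr$gx[i11] * fr * fc
    gy <- gr$gy[i00] * (1 - fr) * (1 - fc) + gr$gy[i01] * (1 - fr) * fc +
          gr$gy[i10] * fr * (1 - fc) + gr$gy[i11] * fr * fc
    mag <- sqrt(gx^2 + gy^2)
    nz <- mag > 1e-10
    if (!any(nz)) { flagged[i] <- TRUE; next }
    uk <- u[ok][nz]; vk <- v[ok][nz]
    ang <- (atan2(gy[nz], gx[nz]) - th) %% (2 * pi)
    rbin <- vk / hw + 1.5; cbin <- uk / hw + 1.5
    obin <- ang / (2 * pi / n_ori) - 0.5
    wgt <- mag[nz] * exp(-((rbin - 1.5)^2 + (cbin - 1.5)^2) / (2 * (d_grid / 2)^2))
    rb0 <- floor(rbin); cb0 <- floor(cbin); ob0 <- floor(obin)
    frb <- rbin - rb0; fcb <- cbin - cb0; fob <- obin - ob0
    desc <- numeric(128)
    for (dr in 0:1) for (dc in 0:1) for (do in 0:1) {
      rr <- rb0 + dr; cc <- cb0 + dc
      oo <- (ob0 + do) %% n_ori
      w <- wgt * (if (dr) frb else 1 - frb) *
                 (if (dc) fcb else 1 - fcb) *
                 (if (do) fob else 1 - fob)
      keep <- rr >= 0 & rr <= 3 & cc >= 0 & cc <= 3 & w > 0
      if (!any(keep)) next
      idx <- rr[keep] * 32 + cc[keep] * 8 + oo[keep] + 1
      acc <- rowsum(w[keep], idx)
      ii <- as.integer(rownames(acc))
      desc[ii] <- desc[ii] + acc
    }
    nrm <- sqrt(sum(desc^2))
    if (nrm <= 0) { flagged[i] <- TRUE; next }
    desc <- pmin(desc / nrm, 0.2)
    desc <- desc / sqrt(sum(desc^2))
    D[i, ] <- desc
  }
  list(descriptors = D, flagged = flagged)
}

#' Extract a full feature set from an image
#'
#' Composition of the SIFT stages on the luminance of an (optionally
#' enhanced) image: scale space, DoG, keypoint detection, orientation
#' assignment and descriptors. Degenerate (zero-gradient) keypoints are
#' dropped, so descriptors and keypoints correspond row-for-row. With
#' `dense = TRUE` in `params`, detection is replaced by a regular grid of
#' fixed-scale keypoints (orientation 0), for dense-sampling experiments.
#'
#' @param image height x width x 3 array (or single-channel matrix).
#' @param params Named list overriding any of: `sigma0`, `scales_per_octave`,
#'   `upsample`, `n_octaves`, `contrast_threshold`, `edge_ratio`, `dense`,
#'   `dense_step`, `dense_sigma`.
#' @return An object of class `feature_set`: `keypoints` (data.frame with
#'   `x`, `y`, `sigma`, `orientation`), `descriptors` (n x 128 matrix),
#'   `width`, `height`.
#' @export
extract_features <- function(image, params = list()) {
  p <- utils::modifyList(list(
    sigma0 = 1.6, scales_per_octave = 3, upsample = TRUE, n_octaves = NULL,
    contrast_threshold = 0.03, edge_ratio = 10,
    dense = FALSE, dense_step = 8, dense_sigma = 2), params)
  lum <- if (length(dim(image)) == 3L) luminance(image) else as.matrix(image)
  pyr <- build_scale_space(lum, sigma0 = p$sigma0,
                           scales_per_octave = p$scales_per_octave,
                           n_octaves = p$n_octaves, upsample = p$upsample)
  H <- pyr$height; W <- pyr$width
  if (isTRUE(p$dense)) {
    xs <- seq(p$dense_step, W - p$dense_step, by = p$dense_step)
    ys <- seq(p$dense_step, H - p$dense_step, by = p$dense_step)
    g <- expand.grid(x = xs, y = ys)
    kp <- data.frame(
      x = g$x, y = g$y, sigma = p$dense_sigma * pyr$base_scale * 2,
      octave = 0L, response = NA_real_,
      row_oct = g$y / pyr$base_scale, col_oct = g$x / pyr$base_scale,
      level_oct = 0, sig_oct = p$dense_sigma)
    kp$orientation <- 0
    kp$degenerate <- FALSE
    class(kp) <- c("keypoints", "data.frame")
  } else {
    dog <- build_dog(pyr)
    kp <- detect_keypoints(dog, contrast_threshold = p$contrast_threshold,
                           edge_ratio = p$edge_ratio)
    kp <- assign_orientations(pyr, kp)
  }
  dd <- compute_descriptors(pyr, kp)
  keep <- !dd$flagged & !isTRUE_vec(kp$degenerate)
  kp <- kp[keep, , drop = FALSE]
  rownames(kp) <- NULL
  structure(
    list(keypoints = kp[, c("x", "y", "sigma", "orientation"), drop = FALSE],
         descriptors = dd$descriptors[keep, , drop = FALSE],
         width = W, height = H, params = p),
    class = "feature_set"
  )
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else (!is.na(x) & x)

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", nrow(x$descriptors), "keypoints on a", x$width, "x",
      x$height, "image\n")
  invisible(x)
}
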