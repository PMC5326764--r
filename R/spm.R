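# Spatial-pyramid pooling: per-cell histograms of code weights over nested
# 1x1 / 2x2 / 4x4 grids, concatenated into the final 21*K image vector.

#' Number of spatial-pyramid sub-regions
#'
#' \code{sum_{l=0}^{levels-1} 4^l}: 1 region at level 0, 4 at level 1, 16
#' at level 2 — 21 in total for the default three levels.
#'
#' @param levels Number of pyramid levels; default 3.
#' @return Integer region count.
#' @export
spm_region_count <- function(levels = 3) {
  stopifnot(levels >= 1)
  sum(4^(0:(levels - 1)))
}

#' Pool codes over a spatial pyramid
#'
#' Accumulates per-codeword histograms of the absolute code weights within
#' each cell of nested \code{2^l x 2^l} grids (1x1, 2x2, 4x4 for the
#' default three levels). A keypoint at \code{(x, y)} (0-based) falls in
#' cell \code{(floor(g*x/W), floor(g*y/H))}, clamped to the last cell on
#' the right/bottom edge. Each level's block is scaled by its level weight,
#' blocks are concatenated (level 0 first, then each level's cells in
#' row-major order), and the final vector is L1-normalized, ready for the
#' Hellinger feature map.
#'
#' @param codes n x K matrix (dense or sparse) of code weights, one row per
#'   keypoint.
#' @param positions n x 2 matrix of 0-based keypoint positions (columns
#'   `x`, `y`).
#' @param image_size Length-2 vector `(W, H)` in pixels.
#' @param K Codebook size (must match `ncol(codes)`).
#' @param mode Per-cell accumulation: `"sum"` (histogram; default) or
#'   `"max"` (max pooling), both over absolute weights.
#' @param level_weights One weight per level; default `c(0.25, 0.25, 0.5)`,
#'   the standard pyramid-match weighting that doubles toward finer levels.
#' @param levels Number of pyramid levels; default 3 (set 1 to disable the
#'   pyramid and pool a single global histogram of length K).
#' @param normalize L1-normalize the concatenated vector (default TRUE).
#' @return Numeric vector of length \code{spm_region_count(levels) * K}
#'   with attributes `K`, `levels`, `mode`, `level_weights`, `normalized`,
#'   `empty` (TRUE when no codes were pooled).
#' @export
pool_spm <- function(codes, positions, image_size, K = ncol(codes),
                     mode = c("sum", "max"),
                     level_weights = c(0.25, 0.25, 0.5), levels = 3,
                     normalize = TRUE) {
  mode <- match.arg(mode)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L, length(image_size) == 2L, K >= 1L)
  W <- image_size[1]; H <- image_size[2]
  if (length(level_weights) < levels) {
    level_weights <- rep_len(level_weights, levels)
  }
  n <- if (is.null(dim(codes))) 0L else nrow(codes)
  total_len <- spm_region_count(levels) * K
  empty <- n == 0L
  if (!empty) {
    positions <- matrix(as.numeric(as.matrix(positions)), ncol = 2)
    if (nrow(positions) != n) stop("codes and positions must have equal length")
    if (any(positions[, 1] < 0 | positions[, 1] >= W |
            positions[, 2] < 0 | positions[, 2] >= H)) {
      stop("positions must lie in [0, W) x [0, H)")
    }
    A <- abs(as.matrix(codes))
    if (ncol(A) != K) stop("codes have ", ncol(A), " columns but K = ", K)
  }
  out <- numeric(total_len)
  offset <- 0L
  for (l in 0:(levels - 1L)) {
    g <- 2L^l
    if (!empty) {
      cx <- pmin(floor(g * positions[, 1] / W), g - 1L)
      cy <- pmin(floor(g * positions[, 2] / H), g - 1L)
      cell <- cy * g + cx                       # row-major cell id, 0-based
      for (cid in 0:(g * g - 1L)) {
        sel <- cell == cid
        if (any(sel)) {
          block <- if (mode == "sum") colSums(A[sel, , drop = FALSE])
                   else apply(A[sel, , drop = FALSE], 2L, max)
          out[(offset + cid * K + 1L):(offset + (cid + 1L) * K)] <-
            block * level_weights[l + 1L]
        }
      }
    }
    offset <- offset + g * g * K
  }
  if (empty) warning("no codes to pool; returning an all-zero pyramid vector")
  if (normalize) {
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  structure(out, K = K, levels = levels, mode = mode,
            level_weights = level_weights[seq_len(levels)],
            normalized = normalize, empty = empty, class = "spm_vector")
}

#' @export
print.spm_vector <- function(x, ...) {
  cat("spm_vector: length", length(x), "(", attr(x, "levels"), "levels, K =",
      attr(x, "K"), ", mode", attr(x, "mode"), ")\n")
  invisible(x)
}
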