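# Seeded synthetic two-class imagery: "ear" patches (elongated,
# chevron-textured blobs on a smooth base, echoing emerged wheat ears) and
# "background" patches (oriented low-frequency stripes, echoing leaf
# canopy, with occasional smooth soil regions). The two classes differ in
# texture statistics by construction, so a classifier failure on them
# signals a pipeline defect rather than data ambiguity. Channels share one
# texture signal plus independent noise calibrated to a target
# inter-channel correlation, so the decorrelation stretch has correlation
# to remove. Every stochastic choice flows from the spec's seed; the RNG
# state of the session is restored on exit.

smooth_noise <- function(size, sigma) {
  m <- gaussian_blur(matrix(stats::rnorm(size * size), size, size), sigma)
  (m - mean(m)) / stats::sd(m)    # unit-sd band-limited field
}

ear_texture <- function(size, blob_count, elongation, orientation_jitter,
                        streak_prob) {
  base <- 0.15 * smooth_noise(size, sigma = size / 8) +
    0.25 * smooth_noise(size, sigma = 1.5) +      # fine sun-fleck speckle
    0.2 * smooth_noise(size, sigma = 3)           # spikelet-sized mottling
  tex <- base
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), size), size)          # row index
  for (b in seq_len(blob_count)) {
    cx <- stats::runif(1, 0.15, 0.85) * size
    cy <- stats::runif(1, 0.15, 0.85) * size
    th <- stats::runif(1, 0, pi) + stats::rnorm(1, 0, orientation_jitter)
    len <- stats::runif(1, 0.18, 0.30) * size
    wid <- len / elongation
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- exp(-(u^2 / (2 * len^2) + v^2 / (2 * wid^2)))
    # spikelet-like chevron texture inside the blob: high-frequency
    # modulation along the blob axis plus an angled cross-component
    freq <- stats::runif(1, 0.9, 1.4)
    phase <- stats::runif(1, 0, 2 * pi)
    chevron <- sign(sin(freq * u + 0.8 * freq * abs(v) + phase)) *
      abs(sin(freq * u + 0.8 * freq * abs(v) + phase))^0.5   # ridge-like
    tex <- tex + mask * (0.5 + 0.6 * chevron)
    if (stats::runif(1) < streak_prob) {   # awn-like thin streak off one end
      sa <- th + stats::rnorm(1, 0, 0.2)
      su <- (xs - cx) * cos(sa) + (ys - cy) * sin(sa)
      sv <- -(xs - cx) * sin(sa) + (ys - cy) * cos(sa)
      streak <- exp(-(sv^2 / 2) - ((su - len) * (su < len))^2 / (2 * len^2)) *
        (su > 0) * (su < 2.2 * len)
      tex <- tex + 0.35 * streak
    }
  }
  tex
}

background_texture <- function(size, stripe_freq, stripe_orientation,
                               soil_prob = 0.3) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), size), size)
  th <- stripe_orientation + stats::rnorm(1, 0, 0.25)
  u <- xs * cos(th) + ys * sin(th)
  phase <- stats::runif(1, 0, 2 * pi)
  tex <- 0.5 + 0.4 * sin(2 * pi * stripe_freq * u / size + phase)
  # a second, fainter leaf layer at a slightly different angle
  th2 <- th + stats::runif(1, 0.3, 0.7)
  u2 <- xs * cos(th2) + ys * sin(th2)
  tex <- tex + 0.2 * sin(2 * pi * stripe_freq * 0.7 * u2 / size +
                         stats::runif(1, 0, 2 * pi))
  # leaf-vein edges: sharpen the stripe extrema into ridges
  tex <- tex + 0.25 * abs(sin(2 * pi * stripe_freq * u / size + phase))^8
  tex <- tex + 0.1 * smooth_noise(size, sigma = size / 10) +
    0.2 * smooth_noise(size, sigma = 1.5) +       # fine speckle
    0.15 * smooth_noise(size, sigma = 3)          # leaf-surface mottling
  if (stats::runif(1) < soil_prob) {   # smooth soil patch, low texture
    cx <- stats::runif(1, 0.2, 0.8) * size
    cy <- stats::runif(1, 0.2, 0.8) * size
    rr <- stats::runif(1, 0.15, 0.3) * size
    mask <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * rr^2))
    tex <- tex * (1 - 0.8 * mask) + 0.25 * mask
  }
  tex
}

#' Specification for one synthetic patch
#'
#' Collects every knob of the patch generator with the package's default
#' study conditions. All probabilities must lie in \code{[0, 1]}; the seed
#' fully determines the output bitwise.
#'
#' @param class `"ear"` or `"background"`.
#' @param seed Integer seed for this patch.
#' @param size Patch side length in pixels (>= 32); default 96.
#' @param blob_count Number of ear-like blobs; default 6.
#' @param elongation Blob length-to-width ratio; default 3.
#' @param orientation_jitter SD (radians) of blob orientation noise;
#'   default 0.3.
#' @param streak_prob Probability of an awn-like streak per blob;
#'   default 0.5.
#' @param stripe_freq Background stripe frequency (cycles per patch);
#'   default 4.
#' @param stripe_orientation Mean background stripe angle (radians);
#'   default pi/3.
#' @param illum_gain,illum_offset Per-channel illumination shift applied to
#'   the finished patch; defaults 1 and 0 (no shift).
#' @param occlusion Fraction of the patch covered by smooth occluders in
#'   \code{[0, 1]}; default 0.
#' @param channel_cor Target inter-channel correlation of the color model;
#'   default 0.95.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(class = c("ear", "background"), seed = 0, size = 96,
                         blob_count = 6, elongation = 3,
                         orientation_jitter = 0.3, streak_prob = 0.5,
                         stripe_freq = 4, stripe_orientation = pi / 3,
                         illum_gain = 1, illum_offset = 0, occlusion = 0,
                         channel_cor = 0.95) {
  class <- match.arg(class)
  stopifnot(streak_prob >= 0, streak_prob <= 1,
            occlusion >= 0, occlusion <= 1,
            channel_cor >= 0, channel_cor <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate one synthetic patch
#'
#' Renders the textured luminance signal for the requested class, colors it
#' with three channels sharing that signal plus independent noise sized so
#' the channels correlate at `channel_cor`, applies class-specific channel
#' tones (ears golden, background green), optional smooth occluders and
#' the illumination shift, and clips to \code{[0, 255]}.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `image` (size x size x 3 array) and `label`.
#' @export
make_patch <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$size < 32) stop("patch size must be at least 32 px")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(spec$seed))
  size <- spec$size
  tex <- if (spec$class == "ear") {
    ear_texture(size, spec$blob_count, spec$elongation,
                spec$orientation_jitter, spec$streak_prob)
  } else {
    background_texture(size, spec$stripe_freq, spec$stripe_orientation)
  }
  tex <- tex - mean(tex)
  v_tex <- stats::var(as.vector(tex))
  rho <- spec$channel_cor
  sd_noise <- if (rho > 0 && v_tex > 0) sqrt(v_tex * (1 - rho) / rho) else
    if (v_tex > 0) sqrt(v_tex) * 10 else 1
  tones <- if (spec$class == "ear") {
    list(offset = c(150, 140, 70), gain = c(55, 50, 40))
  } else {
    list(offset = c(80, 130, 60), gain = c(45, 55, 35))
  }
  img <- array(0, dim = c(size, size, 3))
  scale <- if (v_tex > 0) 1 / sqrt(v_tex) else 0
  for (ch in 1:3) {
    noise <- matrix(stats::rnorm(size * size, sd = sd_noise), size, size)
    img[, , ch] <- tones$offset[ch] + tones$gain[ch] * (tex + noise) * scale / 2.5
  }
  if (spec$occlusion > 0) {
    xs <- matrix(rep(seq_len(size), each = size), size)
    ys <- matrix(rep(seq_len(size), size), size)
    covered <- matrix(FALSE, size, size)
    target <- spec$occlusion * size^2
    guard <- 0L
    while (sum(covered) < target && guard < 50L) {
      guard <- guard + 1L
      cx <- stats::runif(1, 0.1, 0.9) * size
      cy <- stats::runif(1, 0.1, 0.9) * size
      rr <- stats::runif(1, 0.15, 0.35) * size
      mask <- ((xs - cx)^2 + (ys - cy)^2) <= rr^2
      covered <- covered | mask
      soft <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * (rr / 1.5)^2))
      occ_tone <- c(95, 80, 60)   # smooth soil-like occluder
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - soft) + occ_tone[ch] * soft
      }
    }
  }
  img <- pmin(pmax(img, 0), 255)
  img <- apply_illumination(img, spec$illum_gain, spec$illum_offset)
  list(image = img, label = spec$class)
}

#' Standard illumination-shift probe
#'
#' The package's fixed ambient-light perturbation for robustness checks: a
#' cloudy-day dimming of roughly half the brightness with a slight color
#' cast (per-channel gains 0.5/0.6/0.55, offsets -10/+15/+5). Applying it
#' to test images emulates evaluating a model trained under one sky on
#' images acquired under another.
#'
#' @return List with `gain` and `offset`, suitable for
#'   [apply_illumination()].
#' @export
illumination_probe <- function() {
  list(gain = c(0.5, 0.6, 0.55), offset = c(-10, 15, 5))
}

#' Write a synthetic two-class dataset to disk
#'
#' Generates `n_per_class` ear and background patches, splits them 80/20
#' into train and test, and writes the directory-per-class layout
#' (`root/train/<class>/*.png`, `root/test/<class>/*.png`) together with a
#' tab-delimited manifest recording each image's sub-seed and parameters.
#' Per-image sub-seeds are drawn once from the master seed, so different
#' masters give disjoint pixel content in an identical layout.
#'
#' @param n_per_class Images per class (>= 2); default 50.
#' @param seed Master seed; default 0.
#' @param out_dir Output directory (created if needed).
#' @param size Patch side length; default 96.
#' @param train_fraction Fraction per class assigned to train; default 0.8.
#' @param ... Further [fixture_spec()] arguments applied to every patch
#'   (e.g. `occlusion`, `channel_cor`).
#' @return The dataset, as loaded back by [load_dataset()].
#' @export
make_dataset <- function(n_per_class = 50, seed = 0, out_dir, size = 96,
                         train_fraction = 0.8, ...) {
  stopifnot(n_per_class >= 2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  classes <- c("ear", "background")
  subseeds <- matrix(sample.int(.Machine$integer.max, 2 * n_per_class),
                     nrow = n_per_class)
  n_train <- round(train_fraction * n_per_class)
  manifest <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (i in seq_len(n_per_class)) {
      split <- if (i <= n_train) "train" else "test"
      dir <- file.path(out_dir, split, cl)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      sp <- fixture_spec(class = cl, seed = subseeds[i, ci], size = size, ...)
      patch <- make_patch(sp)
      fn <- file.path(dir, sprintf("%s_%03d.png", cl, i))
      write_image(patch$image, fn)
      manifest[[length(manifest) + 1L]] <- data.frame(
        path = fn, class = cl, split = split, seed = subseeds[i, ci],
        size = size, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  load_dataset(out_dir)
}
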