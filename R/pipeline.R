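# Orchestration: configuration, dataset layout, feature caching, the
# end-to-end train/classify cycle, the ablation harness and the
# learning-curve experiment. Every stage derives its seed from one master
# seed, so a fixed configuration reproduces models bitwise.

#' Default pipeline configuration
#'
#' Nested list of every tunable knob, with the package defaults. Any subset
#' can be overridden via [load_config()] or `utils::modifyList()`.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 0,
    ds = list(enabled = TRUE, target_sd = 50, recenter = 127.5,
              matrix = "covariance", clip_pct = NULL),
    sift = list(sigma0 = 1.6, scales_per_octave = 3, upsample = TRUE,
                contrast_threshold = 0.03, edge_ratio = 10,
                dense = FALSE, dense_step = 8, dense_sigma = 2,
                max_px = Inf),
    codebook = list(k = 2000, max_descriptors = 200000, init = "kmeans++",
                    max_iter = 100, tol = 1e-4),
    encode = list(method = "llc", knn = 5, lambda = 1e-4),
    spm = list(enabled = TRUE, levels = 3, mode = "sum",
               weights = c(0.25, 0.25, 0.5)),
    svm = list(c = 1.0, c_grid = NULL)
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it over [default_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

# 32-bit FNV-1a over a serialized object; cheap content/config fingerprint
# for cache keys and artifact provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor the low byte, then multiply mod 2^32 with split arithmetic so the
    # product stays inside double precision
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load a directory-per-class dataset
#'
#' Expects the layout `root/train/<class>/*` and `root/test/<class>/*`
#' (PNG/JPEG/TIFF). Mirrors the study design of balanced positive
#' (ear) and negative (background) patch sets.
#'
#' @param root Dataset root directory.
#' @return An object of class `bovw_dataset`: `root` and `images`
#'   (data.frame with `path`, `class`, `split`).
#' @export
load_dataset <- function(root) {
  rows <- list()
  for (split in c("train", "test")) {
    sd <- file.path(root, split)
    if (!dir.exists(sd)) next
    for (cl in list.dirs(sd, recursive = FALSE, full.names = FALSE)) {
      paths <- list.files(file.path(sd, cl), full.names = TRUE,
                          pattern = "\\.(png|jpg|jpeg|tif|tiff)$", ignore.case = TRUE)
      if (length(paths)) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = paths, class = cl, split = split, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no images found under ", root)
  images <- do.call(rbind, rows)
  if (length(unique(images$class[images$split == "train"])) < 2L) {
    stop("training split must contain at least two classes")
  }
  structure(list(root = root, images = images), class = "bovw_dataset")
}

#' @export
print.bovw_dataset <- function(x, ...) {
  cat("bovw_dataset at", x$root, "\n")
  print(table(x$images$class, x$images$split))
  invisible(x)
}

derive_seed <- function(master, salt) {
  as.integer((as.numeric(master) + 999983 * salt) %% (2^31 - 1))
}

#' Create a feature cache
#'
#' Features are expensive; the pipeline caches them keyed by image identity
#' plus the enhancement/extraction configuration, in memory and (when
#' `dir` is given) on disk, so ablation cells and learning-curve points
#' that share a configuration reuse extractions.
#'
#' @param dir Optional directory for on-disk persistence.
#' @return A cache object to pass as `cache =` to the pipeline functions.
#' @export
feature_cache <- function(dir = NULL) {
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(env = new.env(parent = emptyenv()), dir = dir),
            class = "feature_cache")
}

cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  v <- cache$env[[key]]
  if (!is.null(v)) return(v)
  if (!is.null(cache$dir)) {
    f <- file.path(cache$dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      v <- readRDS(f)
      cache$env[[key]] <- v
      return(v)
    }
  }
  NULL
}

cache_put <- function(cache, key, value) {
  if (is.null(cache)) return(invisible(NULL))
  cache$env[[key]] <- value
  if (!is.null(cache$dir)) saveRDS(value, file.path(cache$dir, paste0(key, ".rds")))
  invisible(NULL)
}

# Enhancement + feature extraction for one image, under one configuration.
pipeline_features <- function(image, config, cache = NULL, key_id = NULL) {
  key <- if (!is.null(key_id)) {
    paste0(config_hash(list(key_id, config$ds, config$sift)), "_",
           config_hash(key_id))
  }
  if (!is.null(key)) {
    hit <- cache_get(cache, key)
    if (!is.null(hit)) return(hit)
  }
  if (is.character(image)) image <- read_image(image)
  image <- validate_image(image)
  if (is.finite(config$sift$max_px) && prod(dim(image)[1:2]) > config$sift$max_px) {
    f <- sqrt(config$sift$max_px / prod(dim(image)[1:2]))
    h <- max(16L, round(dim(image)[1] * f)); w <- max(16L, round(dim(image)[2] * f))
    arr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- resize_bilinear(image[, , ch], h, w)
    image <- pmin(pmax(arr, 0), 255)
  }
  if (isTRUE(config$ds$enabled)) {
    image <- decorrelation_stretch(image, target_sd = config$ds$target_sd,
                                   recenter = config$ds$recenter,
                                   matrix = config$ds$matrix)
    if (!is.null(config$ds$clip_pct)) {
      image <- contrast_stretch(image, config$ds$clip_pct[1], config$ds$clip_pct[2])
    }
  }
  fs <- extract_features(image, params = config$sift)
  if (!is.null(key)) cache_put(cache, key, fs)
  fs
}

image_key <- function(path) {
  fi <- file.info(path)
  list(path = normalizePath(path), size = fi$size, mtime = as.numeric(fi$mtime))
}

# Encode + pool one feature set into the image representation.
pipeline_vector <- function(fs, codebook, config) {
  levels <- if (isTRUE(config$spm$enabled)) config$spm$levels else 1L
  if (nrow(fs$descriptors) == 0L) {
    return(suppressWarnings(pool_spm(matrix(0, 0, codebook$K),
                                     matrix(0, 0, 2), c(fs$width, fs$height),
                                     K = codebook$K, mode = config$spm$mode,
                                     level_weights = config$spm$weights,
                                     levels = levels)))
  }
  codes <- if (config$encode$method == "llc") {
    encode_llc(codebook, fs$descriptors, k_nn = config$encode$knn,
               lambda = config$encode$lambda)
  } else {
    encode_hard(codebook, fs$descriptors)
  }
  pool_spm(codes, as.matrix(fs$keypoints[, c("x", "y")]),
           c(fs$width, fs$height), K = codebook$K, mode = config$spm$mode,
           level_weights = config$spm$weights, levels = levels)
}

#' Train the full categorization pipeline
#'
#' Runs enhance (optional decorrelation stretch) -> SIFT extraction ->
#' K-means vocabulary -> encoding -> spatial-pyramid pooling -> one-vs-all
#' Hellinger-map SVM over the training split. Unreadable images are skipped
#' with a warning (an entirely unreadable class is an error). All stage
#' seeds derive from `config$seed`.
#'
#' @param dataset A [load_dataset()] (or [make_dataset()]) object.
#' @param config Configuration list; see [default_config()].
#' @param cache Optional [feature_cache()].
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_model`: `codebook`, `svm`,
#'   `config`, `classes`, `manifest` (consumed training images),
#'   `config_hash`.
#' @export
train_pipeline <- function(dataset, config = default_config(), cache = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "bovw_dataset"))
  tr <- dataset$images[dataset$images$split == "train", , drop = FALSE]
  say <- function(...) if (verbose) message(...)
  feats <- vector("list", nrow(tr))
  ok <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    f <- tryCatch(
      pipeline_features(tr$path[i], config, cache, image_key(tr$path[i])),
      error = function(e) {
        warning("skipping unreadable image ", tr$path[i], ": ", conditionMessage(e))
        NULL
      })
    if (is.null(f)) ok[i] <- FALSE else feats[[i]] <- f
  }
  for (cl in unique(tr$class)) {
    if (!any(ok & tr$class == cl)) stop("all images of class '", cl, "' unreadable")
  }
  tr <- tr[ok, , drop = FALSE]; feats <- feats[ok]
  say("extracted features for ", nrow(tr), " training images")
  desc <- do.call(rbind, lapply(feats, function(f) f$descriptors))
  if (is.null(desc) || nrow(desc) < config$codebook$k) {
    stop("only ", if (is.null(desc)) 0L else nrow(desc), " descriptors ",
         "available for a vocabulary of K = ", config$codebook$k,
         "; lower codebook$k or supply more/larger training patches")
  }
  seed_cb <- derive_seed(config$seed, 1L)
  if (nrow(desc) > config$codebook$max_descriptors) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed_cb)
    desc <- desc[sample.int(nrow(desc), config$codebook$max_descriptors), ,
                 drop = FALSE]
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  cb <- fit_kmeans(desc, K = config$codebook$k, seed = seed_cb,
                   max_iter = config$codebook$max_iter,
                   tol = config$codebook$tol, init = config$codebook$init)
  say("codebook: K = ", cb$K, ", inertia ", format(cb$inertia, digits = 5))
  Xs <- t(vapply(feats, function(f) as.numeric(pipeline_vector(f, cb, config)),
                 numeric(spm_dim(config))))
  C <- config$svm$c
  if (!is.null(config$svm$c_grid) && length(config$svm$c_grid) > 1L) {
    C <- select_cost(Xs, tr$class, config$svm$c_grid, derive_seed(config$seed, 2L))
    say("grid-selected C = ", C)
  }
  model <- train_svm(Xs, tr$class, C = C, seed = derive_seed(config$seed, 3L))
  structure(
    list(codebook = cb, svm = model, config = config,
         classes = model$classes,
         manifest = tr[, c("path", "class")],
         config_hash = config_hash(config)),
    class = "pipeline_model"
  )
}

spm_dim <- function(config) {
  levels <- if (isTRUE(config$spm$enabled)) config$spm$levels else 1L
  spm_region_count(levels) * config$codebook$k
}

# Small deterministic 3-fold cross-validated cost selection.
select_cost <- function(X, labels, grid, seed) {
  n <- nrow(X)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  fold <- sample(rep_len(1:3, n))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  acc <- vapply(grid, function(C) {
    mean(vapply(1:3, function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L || min(table(labels[tr])) < 2L) return(NA_real_)
      m <- train_svm(X[tr, , drop = FALSE], labels[tr], C = C, seed = seed)
      mean(predict(m, X[!tr, , drop = FALSE])$label == labels[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

#' @export
print.pipeline_model <- function(x, ...) {
  cat("pipeline_model (config ", x$config_hash, ")\n", sep = "")
  print(x$codebook)
  print(x$svm)
  invisible(x)
}

#' Classify one image with a trained pipeline
#'
#' Applies the model's full chain (enhance -> extract -> encode -> pool ->
#' predict) to an image of any resolution; the pyramid vector's
#' normalization makes patch-trained models transfer to larger test
#' images. An image yielding no keypoints is decided by the classifier
#' biases, with a low-confidence warning.
#'
#' @param model A [train_pipeline()] model.
#' @param image Image path or height x width x 3 array.
#' @param cache Optional [feature_cache()].
#' @return A list: `label`, `scores` (1 x n_classes), `n_keypoints`.
#' @export
classify_image <- function(model, image, cache = NULL) {
  stopifnot(inherits(model, "pipeline_model"))
  key <- if (is.character(image)) image_key(image)
  fs <- pipeline_features(image, model$config, cache, key)
  if (nrow(fs$descriptors) == 0L) {
    warning("no keypoints detected; classification is low-confidence")
  }
  v <- suppressWarnings(pipeline_vector(fs, model$codebook, model$config))
  pr <- suppressWarnings(predict(model$svm, as.numeric(v)))
  list(label = pr$label, scores = pr$scores, n_keypoints = nrow(fs$descriptors))
}

#' Evaluate a pipeline on a dataset split
#'
#' Classifies every image of the chosen split (optionally transformed
#' first, e.g. by an illumination shift) and reports precision, recall and
#' accuracy.
#'
#' @param model A trained `pipeline_model`.
#' @param dataset A `bovw_dataset`.
#' @param split `"test"` (default) or `"train"`.
#' @param transform Optional function applied to each image array before
#'   classification.
#' @param cache Optional [feature_cache()] (ignored when `transform` is
#'   given).
#' @return An `eval_report` with an extra `predictions` data.frame.
#' @export
evaluate_pipeline <- function(model, dataset, split = "test",
                              transform = NULL, cache = NULL) {
  imgs <- dataset$images[dataset$images$split == split, , drop = FALSE]
  if (!nrow(imgs)) stop("split '", split, "' is empty")
  preds <- character(nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    img <- read_image(imgs$path[i])
    if (!is.null(transform)) img <- transform(img)
    res <- suppressWarnings(classify_image(
      model, if (is.null(transform)) imgs$path[i] else img,
      cache = if (is.null(transform)) cache else NULL))
    preds[i] <- res$label
  }
  rep <- evaluate_predictions(preds, imgs$class)
  rep$predictions <- data.frame(path = imgs$path, truth = imgs$class,
                                predicted = preds, stringsAsFactors = FALSE)
  rep
}

#' Run an ablation grid
#'
#' Trains and evaluates one pipeline per cell of a factorial grid over the
#' method's design axes (decorrelation on/off, feature detector, coding
#' method, spatial pyramid on/off, vocabulary size), on the dataset's fixed
#' train/test split. Infeasible cells (e.g. an unavailable detector) are
#' reported as skipped and the run continues.
#'
#' @param dataset A `bovw_dataset`.
#' @param grid Named list of axes; any subset of `ds` (logical), `feature`
#'   (`"sift"`), `coding` (`"llc"`/`"hard"`), `spm` (logical), `k`
#'   (integer vector). Missing axes stay at the base configuration.
#' @param config Base configuration.
#' @param cache Optional [feature_cache()]; cells sharing an enhancement
#'   configuration then share feature extractions.
#' @return A data.frame with one row per cell: the axes, `status`,
#'   `accuracy`, mean `precision`/`recall`, the representation dimension
#'   and the resolved config hash.
#' @export
run_ablation <- function(dataset, grid = list(), config = default_config(),
                         cache = NULL) {
  axes <- utils::modifyList(
    list(ds = isTRUE(config$ds$enabled), feature = "sift",
         coding = config$encode$method, spm = isTRUE(config$spm$enabled),
         k = config$codebook$k),
    grid)
  cells <- expand.grid(axes, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, , drop = FALSE]
    row <- data.frame(cell, status = "ok", accuracy = NA_real_,
                      precision = NA_real_, recall = NA_real_,
                      dim = NA_integer_, config_hash = NA_character_,
                      stringsAsFactors = FALSE)
    if (!identical(cell$feature, "sift")) {
      row$status <- paste0("skipped: detector '", cell$feature,
                           "' unavailable in this build")
      out[[i]] <- row
      next
    }
    cfg <- config
    cfg$ds$enabled <- cell$ds
    cfg$encode$method <- cell$coding
    cfg$spm$enabled <- cell$spm
    cfg$codebook$k <- cell$k
    res <- tryCatch({
      model <- train_pipeline(dataset, cfg, cache = cache)
      ev <- evaluate_pipeline(model, dataset, cache = cache)
      list(model = model, ev = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- paste0("skipped: ", conditionMessage(res))
    } else {
      row$accuracy <- res$ev$accuracy
      row$precision <- mean(res$ev$per_class$precision, na.rm = TRUE)
      row$recall <- mean(res$ev$per_class$recall, na.rm = TRUE)
      row$dim <- res$model$svm$d
      row$config_hash <- res$model$config_hash
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Accuracy as a function of training-set size
#'
#' Draws seeded nested subsets of the training split (smaller subsets are
#' contained in larger ones, one permutation per class), trains a pipeline
#' per size and evaluates each on the fixed test split.
#'
#' @param dataset A `bovw_dataset`.
#' @param sizes Per-class training counts, increasing.
#' @param seed Seed for the subset permutation (also becomes the pipeline
#'   master seed).
#' @param config Base configuration.
#' @param cache Optional [feature_cache()] shared across sizes.
#' @return data.frame with `size` and `accuracy`.
#' @export
learning_curve <- function(dataset, sizes, seed = 0,
                           config = default_config(), cache = NULL) {
  tr <- dataset$images[dataset$images$split == "train", , drop = FALSE]
  per_class <- split(seq_len(nrow(tr)), tr$class)
  avail <- min(lengths(per_class))
  if (max(sizes) > avail) {
    stop("requested ", max(sizes), " training images per class but only ",
         avail, " are available")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  perms <- lapply(per_class, function(ix) ix[sample.int(length(ix))])
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  config$seed <- derive_seed(seed, 11L)
  out <- lapply(sort(sizes), function(n) {
    ix <- sort(unlist(lapply(perms, function(p) p[seq_len(n)])))
    sub <- dataset
    sub$images <- rbind(tr[ix, , drop = FALSE],
                        dataset$images[dataset$images$split == "test", , drop = FALSE])
    model <- train_pipeline(sub, config, cache = cache)
    data.frame(size = n, accuracy = evaluate_pipeline(model, sub, cache = cache)$accuracy)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
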