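# Classification: explicit Hellinger feature map (L1-normalize then
# elementwise square root) followed by one-vs-all linear SVMs. The solver
# behind the training surface is libsvm (e1071) with a linear kernel; the
# fitted weights and biases are extracted into a plain, portable model so
# prediction is an explicit dot product.

#' Hellinger feature map
#'
#' Maps a non-negative histogram to the explicit feature space of the
#' Hellinger kernel: L1-normalize, then take elementwise square roots. The
#' ordinary inner product of two mapped vectors then equals
#' \code{sum(sqrt(h_i * h'_i))} of the normalized histograms, and every
#' non-degenerate mapped vector has unit Euclidean norm. An all-zero input
#' is returned as-is with attribute `degenerate = TRUE` (such an image can
#' only be classified by the bias).
#'
#' @param h Non-negative numeric vector (histogram).
#' @return The mapped vector, unit L2 norm unless degenerate.
#' @export
hellinger_map <- function(h) {
  h <- as.numeric(h)
  if (any(h < -1e-9)) stop("hellinger_map requires a non-negative histogram")
  h[h < 0] <- 0
  s <- sum(h)
  if (s <= 0) {
    attr(h, "degenerate") <- TRUE
    return(h)
  }
  sqrt(h / s)
}

map_rows <- function(X) {
  X <- as.matrix(X)
  t(apply(X, 1L, function(r) {
    m <- hellinger_map(r)
    attributes(m) <- NULL
    m
  }))
}

#' Train one-vs-all linear SVMs on Hellinger-mapped pyramid vectors
#'
#' Applies the Hellinger map to every pooled image vector, then fits one
#' linear support vector machine per class, labeling that class +1 and all
#' others -1. The per-class weight vectors and biases are extracted from
#' the solver so the model is a plain weight matrix; prediction is
#' \code{argmax_c (w_c . phi(x) + b_c)}.
#'
#' @param samples n x d matrix of pooled image vectors (rows; raw, not yet
#'   mapped), or a list of vectors of equal length.
#' @param labels Class label per row (factor or character); at least two
#'   classes with at least two samples each.
#' @param C Soft-margin cost; default 1.
#' @param seed Integer recorded in the model for provenance (the linear
#'   solver itself is deterministic).
#' @return An object of class `hellinger_svm_model`: `weights` (d x
#'   n_classes), `bias` (per class), `classes`, `C`, `seed`, `d`.
#' @export
train_svm <- function(samples, labels, C = 1.0, seed = 0) {
  if (is.list(samples) && !is.data.frame(samples)) {
    samples <- do.call(rbind, lapply(samples, as.numeric))
  }
  X <- as.matrix(samples)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("samples and labels differ in length")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes to train")
  if (any(table(labels) < 2L)) stop("need at least two samples per class")
  M <- map_rows(X)
  d <- ncol(M)
  Wm <- matrix(0, d, length(classes))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    y <- factor(ifelse(labels == classes[ci], "+1", "-1"), levels = c("+1", "-1"))
    fit <- e1071::svm(x = M, y = y, kernel = "linear", cost = C,
                      scale = FALSE, type = "C-classification")
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    bb <- -fit$rho
    # libsvm's decision sign follows the first label it encounters; align
    # so positive score means "inside this class"
    if (fit$labels[1] != which(levels(y) == "+1")) { w <- -w; bb <- -bb }
    Wm[, ci] <- w
    b[ci] <- bb
  }
  structure(
    list(weights = Wm, bias = b, classes = classes, C = C,
         seed = as.integer(seed), d = d,
         normalization = "l1-then-sqrt (Hellinger map applied at train and predict)"),
    class = "hellinger_svm_model"
  )
}

#' @export
print.hellinger_svm_model <- function(x, ...) {
  cat("hellinger_svm_model:", length(x$classes), "one-vs-all linear SVMs, d =",
      x$d, ", C =", x$C, "\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict class labels from pooled image vectors
#'
#' Applies the Hellinger map to each raw pooled vector and evaluates every
#' one-vs-all decision function; the predicted label is the class with the
#' highest decision value (ties resolve to the lowest class index). An
#' all-zero vector triggers a warning and is decided by the biases alone.
#'
#' @param object A trained `hellinger_svm_model`.
#' @param newdata One pooled vector or an n x d matrix of them (raw scale).
#' @param ... Unused.
#' @return A list: `label` (character vector) and `scores` (n x n_classes
#'   matrix of decision values).
#' @export
predict.hellinger_svm_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != object$d) {
    stop("input dimension ", ncol(X), " does not match model dimension ", object$d)
  }
  if (any(rowSums(abs(X)) == 0)) {
    warning("all-zero feature vector: prediction falls back to the bias terms")
  }
  M <- map_rows(X)
  S <- M %*% object$weights + matrix(object$bias, nrow(M), length(object$bias),
                                     byrow = TRUE)
  colnames(S) <- object$classes
  list(label = object$classes[max.col(S, ties.method = "first")], scores = S)
}

#' Precision, recall and accuracy of a labeling
#'
#' Retrieval-style evaluation: for each class treated as the retrieved set,
#' precision is the fraction of retrieved images that are relevant
#' (truly of that class) and recall the fraction of all relevant images
#' that were retrieved. Precision is `NA` (undefined, not zero) for a
#' class that retrieved nothing. Overall accuracy is the fraction of
#' correct labels.
#'
#' @param predictions Predicted labels (character/factor).
#' @param truth True labels, same length.
#' @return An object of class `eval_report`: `accuracy`, `per_class`
#'   (data.frame with class, retrieved, relevant, correct, precision,
#'   recall), `confusion` (table).
#' @export
evaluate_predictions <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) stop("length mismatch")
  classes <- sort(unique(c(predictions, truth)))
  confusion <- table(truth = factor(truth, classes),
                     predicted = factor(predictions, classes))
  per <- do.call(rbind, lapply(classes, function(cl) {
    retrieved <- sum(predictions == cl)
    relevant <- sum(truth == cl)
    correct <- sum(predictions == cl & truth == cl)
    data.frame(class = cl, retrieved = retrieved, relevant = relevant,
               correct = correct,
               precision = if (retrieved > 0) correct / retrieved else NA_real_,
               recall = if (relevant > 0) correct / relevant else 0)
  }))
  structure(
    list(accuracy = mean(predictions == truth), per_class = per,
         confusion = confusion),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("accuracy:", format(x$accuracy, digits = 4), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
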