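# Visual vocabulary: Lloyd K-means over descriptor space with k-means++
# seeding, empty-cluster re-seeding and a monotone-inertia guarantee.

# Squared Euclidean distances between rows of X (n x d) and C (k x d).
pairwise_sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- pairwise_sqdist(X, X[centers[1], , drop = FALSE])[, 1]
  if (K > 1L) for (k in 2:K) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0) {
      centers[k] <- sample.int(n, 1L)
    } else {
      centers[k] <- sample.int(n, 1L, prob = p)
    }
    d2 <- pmin(d2, pairwise_sqdist(X, X[centers[k], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

#' Fit a K-means visual vocabulary
#'
#' Lloyd iterations over the training descriptors: assign each descriptor
#' to its closest center, then re-compute each center as the mean of its
#' members, until no descriptor changes cluster (the fixpoint), the
#' relative inertia change falls below `tol`, or `max_iter` is reached.
#' The within-cluster sum of squared distances (inertia) is checked to be
#' non-increasing at every iteration. An emptied cluster is re-seeded with
#' the point currently farthest from its assigned center.
#'
#' @param descriptors n x d numeric matrix (rows are descriptors), n >= K.
#' @param K Vocabulary size; default 2000.
#' @param seed Integer seed controlling initialization.
#' @param max_iter Iteration cap; default 300.
#' @param tol Relative inertia-change stopping tolerance; default 1e-4.
#' @param init `"kmeans++"` (default) or `"random"` (uniform sample of K
#'   distinct descriptors).
#' @return An object of class `codebook`: `centers` (K x d), `K`, `seed`,
#'   `iterations`, `inertia` (final), `inertia_trace` (per iteration),
#'   `init`.
#' @export
fit_kmeans <- function(descriptors, K = 2000, seed = 0, max_iter = 300,
                       tol = 1e-4, init = c("kmeans++", "random")) {
  X <- as.matrix(descriptors)
  init <- match.arg(init)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (nrow(X) < K) {
    stop("need at least as many descriptors (", nrow(X), ") as vocabulary ",
         "entries (K = ", K, "); use a smaller K or more training patches")
  }
  if (any(!is.finite(X))) stop("descriptors must be finite")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  C <- if (init == "kmeans++") kmeanspp_init(X, K) else
    X[sample.int(nrow(X), K), , drop = FALSE]
  assign_prev <- rep(-1L, nrow(X))
  inertia_prev <- Inf
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- pairwise_sqdist(X, C)
    assign_cur <- max.col(-d2, ties.method = "first")
    mind2 <- d2[cbind(seq_len(nrow(X)), assign_cur)]
    # re-seed empty clusters with the farthest point from its own center
    empty <- setdiff(seq_len(K), unique(assign_cur))
    for (e in empty) {
      far <- which.max(mind2)
      C[e, ] <- X[far, ]
      assign_cur[far] <- e
      mind2[far] <- 0
    }
    inertia <- sum(mind2)
    if (inertia > inertia_prev * (1 + 1e-10) + 1e-12) {
      stop("internal error: K-means inertia increased (", inertia_prev,
           " -> ", inertia, ")")
    }
    trace <- c(trace, inertia)
    converged_fix <- all(assign_cur == assign_prev)
    converged_tol <- is.finite(inertia_prev) &&
      (inertia_prev - inertia) <= tol * max(inertia_prev, .Machine$double.eps)
    if (converged_fix || converged_tol || iter >= max_iter) {
      if (!converged_fix) {
        # one more center update so centers match the final assignment
        C <- update_centers(X, C, assign_cur, K)
      }
      break
    }
    C <- update_centers(X, C, assign_cur, K)
    assign_prev <- assign_cur
    inertia_prev <- inertia
  }
  structure(
    list(centers = unname(C), K = K, seed = as.integer(seed),
         iterations = iter, inertia = trace[length(trace)],
         inertia_trace = trace, init = init),
    class = "codebook"
  )
}

update_centers <- function(X, C, assignment, K) {
  sums <- rowsum(X, assignment)
  cnt <- tabulate(assignment, nbins = K)
  present <- as.integer(rownames(sums))
  C[present, ] <- sums / cnt[present]
  C
}

#' @export
print.codebook <- function(x, ...) {
  cat("codebook: K =", x$K, ", d =", ncol(x$centers), ", inertia =",
      format(x$inertia, digits = 6), "after", x$iterations, "iterations (",
      x$init, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Nearest codeword of each descriptor
#'
#' Hard vector quantization: the index (1-based) of the Euclidean-nearest
#' center; ties resolve to the lowest index.
#'
#' @param codebook A [fit_kmeans()] codebook.
#' @param descriptors A single descriptor (vector) or an n x d matrix.
#' @return Integer vector of 1-based center indices.
#' @export
assign_nearest <- function(codebook, descriptors) {
  stopifnot(inherits(codebook, "codebook"))
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, nrow = 1)
  if (ncol(X) != ncol(codebook$centers)) {
    stop("descriptor length ", ncol(X), " does not match codebook width ",
         ncol(codebook$centers))
  }
  d2 <- pairwise_sqdist(X, codebook$centers)
  max.col(-d2, ties.method = "first")
}
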