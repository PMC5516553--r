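# Squared Euclidean distances between rows of X (n x p) and C (k x p).
.dist2 <- function(X, C) {
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d, 0)
}

# k-means++-style seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance from the nearest chosen center.
.kmpp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- .dist2(X, X[centers[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, .dist2(X, X[centers[j], , drop = FALSE])[, 1])
    }
  }
  centers
}

# One Lloyd run from a k-means++ start. Iterates assignment/update until the
# assignment is unchanged or max_iter; empty clusters are repaired by
# reseeding to the point farthest from its current centroid. The within-
# cluster sum of squares is checked to be non-increasing across iterations.
.lloyd_once <- function(X, k, max_iter = 300L) {
  n <- nrow(X)
  C <- X[.kmpp_init(X, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  wss_old <- Inf
  for (iter in seq_len(max_iter)) {
    d <- .dist2(X, C)
    cl <- max.col(-d, ties.method = "first")
    # repair empty clusters deterministically
    empty <- which(tabulate(cl, k) == 0L)
    for (j in empty) {
      dmin <- d[cbind(seq_len(n), cl)]
      far <- which.max(dmin)
      cl[far] <- j
      d[far, ] <- Inf; d[far, j] <- 0
    }
    counts <- tabulate(cl, k)
    C <- rowsum(X, cl) / counts
    wss <- sum((X - C[cl, , drop = FALSE])^2)
    if (wss > wss_old + 1e-8)
      stop("internal error: within-cluster sum of squares increased across a Lloyd iteration")
    if (identical(cl, assign_old)) break
    assign_old <- cl
    wss_old <- wss
  }
  list(cluster = cl, centers = C, wss = wss, iter = iter)
}

#' k-means clustering with restarts
#'
#' Lloyd's algorithm from k-means++-style seeded starts, keeping the restart
#' with minimal within-cluster sum of squares. Deterministic given `seed`.
#' Empty clusters are repaired by reseeding to the point farthest from its
#' centroid.
#'
#' @param X A [build_feature_matrix()] result or a numeric matrix. A
#'   non-standardized matrix triggers a warning but the fit proceeds.
#' @param k Number of clusters (1 <= k <= n).
#' @param restarts Number of random restarts (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param max_iter Iteration cap per restart.
#' @return Object of class `cluster_solution`: `k`, `cluster` (named integer
#'   assignments), `centers`, `wss`, `tss`, `r2 = 1 - wss/tss`, `iter`.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' fit_kmeans(scale(X), k = 2, restarts = 5, seed = 1)
#' @export
fit_kmeans <- function(X, k, restarts = 50L, seed = NULL, max_iter = 300L) {
  ids <- NULL
  if (inherits(X, "feature_matrix")) { ids <- X$ids; X <- X$values }
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of observations")
  if (k < 1L || restarts < 1L) stop("k and restarts must be >= 1")
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 0.1 & sdv > .Machine$double.eps^0.5))
    warning("feature matrix does not look standardized; proceeding anyway")

  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(restarts)) {
      fit <- .lloyd_once(X, k, max_iter)
      if (is.null(b) || fit$wss < b$wss) b <- fit
    }
    b
  })
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  cl <- best$cluster
  if (!is.null(ids)) names(cl) <- ids
  structure(list(k = as.integer(k), cluster = cl, centers = best$centers,
                 wss = best$wss, tss = tss,
                 r2 = if (tss > 0) 1 - best$wss / tss else 0,
                 iter = best$iter),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d; sizes: %s; R^2 = %.3f%s\n",
              x$k, paste(tabulate(x$cluster, x$k), collapse = "/"), x$r2,
              if (!is.null(x$ccc)) sprintf("; CCC = %.2f", x$ccc) else ""))
  invisible(x)
}
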