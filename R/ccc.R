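# Symmetric matrix square root (and inverse square root) via eigendecomposition.
.symsqrt <- function(S, inv = FALSE) {
  e <- eigen(S, symmetric = TRUE)
  d <- pmax(e$values, 1e-12)
  e$vectors %*% diag(if (inv) 1 / sqrt(d) else sqrt(d), length(d)) %*% t(e$vectors)
}

# Effective dimensionality p* for the cubic clustering criterion, together
# with the analytic expected R^2 under Sarle's uniform-hyperbox null.
#
# The null takes the data uniform on a hyperbox aligned with the principal
# components, carved into k cells of common edge c. With s_j the square roots
# of the covariance eigenvalues and u_j = s_j / c, dimensions whose scale
# falls below the cell edge cannot be subdivided and contribute only noise;
# p* counts those that can (iterated, since c depends on p*).
.ccc_expected_r2 <- function(X, k) {
  n <- nrow(X); p <- ncol(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  s <- sqrt(ev)
  pos <- s > .Machine$double.eps^0.5
  if (!any(pos)) stop("feature matrix has zero total variance")
  pstar <- sum(pos)
  repeat {
    cc <- (prod(s[seq_len(pstar)]) / k)^(1 / pstar)
    p_new <- max(sum(s >= cc), 1L)
    if (p_new >= pstar) break
    pstar <- p_new
  }
  u <- s / cc
  num <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < p) num <- num + sum(u[(pstar + 1):p]^2 / (n + u[(pstar + 1):p]))
  er2 <- 1 - (num / sum(u^2)) * ((n - k)^2 / n) * (1 + 4 / n)
  list(er2 = er2, pstar = pstar)
}

# Expected R^2 under the uniform-hyperbox null by covariance-matched
# parametric bootstrap: whitened uniform draws are recolored to the exact
# sample covariance of X and clustered with the same k-means. Deterministic:
# the internal seed is a fixed function of (n, p, k).
.ccc_null_r2 <- function(X, k, B = 12L, restarts = 10L) {
  n <- nrow(X); p <- ncol(X)
  A <- .symsqrt(stats::cov(X))
  seed <- (7919L * k + 104729L * (n %% 4096L) + 31L * p) %% 2147483647L
  with_seed(seed, {
    mean(vapply(seq_len(B), function(b) {
      Z <- sqrt(12) * (matrix(stats::runif(n * p), n, p) - 0.5)
      Y <- Z %*% .symsqrt(stats::cov(Z), inv = TRUE) %*% A
      suppressWarnings(fit_kmeans(Y, k, restarts = restarts)$r2)
    }, numeric(1)))
  })
}

# The criterion's closed form given observed and expected R^2.
.ccc_value <- function(r2, er2, n, pstar) {
  log((1 - er2) / (1 - r2)) * sqrt(n * pstar / 2) / (0.001 + er2)^1.2
}

#' Cubic clustering criterion
#'
#' Sarle's (1983) cubic clustering criterion compares the proportion of
#' variance explained by a k-cluster partition with its expectation under a
#' null in which the data are uniform on a hyperbox aligned with the
#' principal components:
#' \deqn{CCC = \ln\frac{1 - E(R^2)}{1 - R^2} \cdot
#'   \frac{\sqrt{n p^*/2}}{(0.001 + E(R^2))^{1.2}}}
#' where \eqn{p^*} is the effective dimensionality (the number of covariance
#' eigenvalues whose square roots exceed the null cell edge). Values near 0
#' are consistent with unstructured data; local peaks across k indicate
#' candidate cluster counts.
#'
#' Two estimators of \eqn{E(R^2)} are provided. `"bootstrap"` (default)
#' estimates it by a covariance-matched parametric bootstrap — uniform
#' hyperbox samples recolored to the exact sample covariance and clustered
#' with the same k-means — which calibrates the criterion to be near zero on
#' unstructured data for any k. `"analytic"` is the original closed-form
#' volume approximation; it assumes the null partition tiles the box with
#' k hypercube cells, which is geometrically unattainable for small k in
#' high dimension and there overstates \eqn{E(R^2)} considerably.
#'
#' @param r2 Observed R^2 of the partition, in `[0, 1)`.
#' @param X Feature matrix the partition was fitted on (a
#'   [build_feature_matrix()] result or numeric matrix).
#' @param k Number of clusters.
#' @param method `"bootstrap"` or `"analytic"` expected-R^2 estimator.
#' @param B Bootstrap replicates (method `"bootstrap"`).
#' @param restarts k-means restarts per bootstrap replicate.
#' @return The CCC value (scalar). Deterministic for fixed inputs: the
#'   bootstrap uses an internal seed derived from the problem size.
#' @export
cubic_clustering_criterion <- function(r2, X, k, method = c("bootstrap", "analytic"),
                                       B = 12L, restarts = 10L) {
  method <- match.arg(method)
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1); r2 = 1 is a log singularity")
  e <- .ccc_expected_r2(X, k)
  er2 <- if (method == "bootstrap") .ccc_null_r2(X, k, B, restarts) else e$er2
  .ccc_value(r2, er2, nrow(X), e$pstar)
}

#' Select the number of clusters from a CCC profile
#'
#' Applies the local-peak rule: the selected k is the one whose CCC exceeds
#' both neighbors (an interior peak); among multiple interior peaks the one
#' with the largest CCC wins, with ties broken toward smaller k. If no
#' interior peak exists the global maximum is returned and flagged
#' `boundary_max`.
#'
#' @param k Ordered integer vector of candidate cluster counts.
#' @param ccc Parallel numeric vector of CCC values.
#' @return Object of class `ccc_profile`: data frame `profile` (k, ccc),
#'   `selected_k`, `selection_kind` (`"interior_peak"` or `"boundary_max"`).
#' @examples
#' select_k(2:5, c(1, 0.5, 3, 2))$selected_k # 4, interior peak
#' select_k(2:5, c(1, 2, 3, 4))              # 5, boundary maximum
#' @export
select_k <- function(k, ccc) {
  stopifnot(length(k) == length(ccc), length(k) >= 1L)
  ok <- is.finite(ccc)
  if (!any(ok)) stop("no finite CCC values")
  m <- length(k)
  peaks <- integer(0)
  if (m >= 3L) {
    for (i in 2:(m - 1L)) {
      if (ok[i] && ok[i - 1] && ok[i + 1] && ccc[i] > ccc[i - 1] && ccc[i] > ccc[i + 1])
        peaks <- c(peaks, i)
    }
  }
  if (length(peaks)) {
    best <- peaks[ccc[peaks] == max(ccc[peaks])]
    sel <- min(k[best])
    kind <- "interior_peak"
  } else {
    mx <- max(ccc[ok])
    sel <- min(k[ok & ccc == mx])
    kind <- "boundary_max"
  }
  structure(list(profile = data.frame(k = k, ccc = ccc),
                 selected_k = sel, selection_kind = kind),
            class = "ccc_profile")
}

#' @export
print.ccc_profile <- function(x, ...) {
  cat("<ccc_profile>\n")
  print(x$profile, row.names = FALSE)
  cat(sprintf("selected k = %d (%s)\n", x$selected_k, x$selection_kind))
  invisible(x)
}

#' Scan cluster counts and select by CCC local peak
#'
#' Fits k-means for every k in `k_range`, computes the cubic clustering
#' criterion per solution and applies the local-peak selection rule.
#'
#' @inheritParams fit_kmeans
#' @inheritParams cubic_clustering_criterion
#' @param k_range Integer vector of candidate cluster counts (default 2-5).
#' @param ccc_B,ccc_restarts Bootstrap settings passed to
#'   [cubic_clustering_criterion()].
#' @return List with `solutions` (one `cluster_solution` per k, each with its
#'   `ccc` attached) and `ccc` (a `ccc_profile`).
#' @export
run_cluster_scan <- function(X, k_range = 2:5, restarts = 50L, seed = NULL,
                             max_iter = 300L, method = c("bootstrap", "analytic"),
                             ccc_B = 12L, ccc_restarts = 10L) {
  method <- match.arg(method)
  k_range <- sort(unique(as.integer(k_range)))
  solutions <- with_seed(seed, {
    lapply(k_range, function(k) fit_kmeans(X, k, restarts = restarts, seed = NULL,
                                           max_iter = max_iter))
  })
  ccc <- vapply(solutions, function(s)
    cubic_clustering_criterion(min(s$r2, 1 - 1e-12), X, s$k, method = method,
                               B = ccc_B, restarts = ccc_restarts),
    numeric(1))
  for (i in seq_along(solutions)) solutions[[i]]$ccc <- ccc[i]
  names(solutions) <- paste0("k", k_range)
  list(solutions = solutions, ccc = select_k(k_range, ccc))
}

#' Label a four-cluster solution by its clinical profile
#'
#' Assigns the reported subgroup names to a k = 4 solution from the centroid
#' evidence: TD to the cluster with the highest motor-phenotype centroid, RDP
#' to the highest progression-rate centroid among the rest, YO to the lowest
#' age-at-onset centroid among the rest, NTD to the remainder. For k != 4 the
#' clusters are labeled generically `C1..Ck`.
#'
#' @param solution A `cluster_solution`.
#' @param X The `feature_matrix` the solution was fitted on (used to
#'   de-standardize the centroid evidence).
#' @return Character vector of length k mapping cluster index to label, with
#'   the centroid evidence attached as attribute `"evidence"`.
#' @export
label_clusters <- function(solution, X) {
  k <- solution$k
  if (k != 4L) return(paste0("C", seq_len(k)))
  cn <- colnames(solution$centers)
  need <- c("motor_phenotype", "progression_rate", "age_onset")
  if (is.null(cn) || !all(need %in% cn)) return(paste0("C", seq_len(k)))
  cent <- solution$centers
  if (inherits(X, "feature_matrix"))
    cent <- sweep(sweep(cent, 2, X$scale[colnames(cent)], "*"), 2,
                  X$center[colnames(cent)], "+")
  labels <- rep(NA_character_, k)
  td <- which.max(cent[, "motor_phenotype"])
  labels[td] <- "TD"
  rest <- which(is.na(labels))
  labels[rest[which.max(cent[rest, "progression_rate"])]] <- "RDP"
  rest <- which(is.na(labels))
  labels[rest[which.min(cent[rest, "age_onset"])]] <- "YO"
  labels[is.na(labels)] <- "NTD"
  attr(labels, "evidence") <- cent[, need]
  labels
}
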