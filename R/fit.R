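#' Fit the data-driven PD subtyping model
#'
#' End-to-end fit: derives the nine clustering variables from a patient
#' cohort, z-standardizes them, scans k-means solutions over `k_range`,
#' selects the number of clusters by the cubic-clustering-criterion
#' local-peak rule, labels a four-cluster solution by its clinical profile
#' (YO/TD/NTD/RDP), classifies PD-MCI and comorbid symptoms per patient,
#' tabulates per-cluster frequencies, and validates the solution on held-out
#' variables (age, disease duration, H&Y stage, PDQ-39 cognition) with
#' normality-gated omnibus and pairwise comparisons.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] /
#'   [read_cohort_csv()] for the schema) or a [cohort_spec()] to generate one.
#' @param k_range Candidate cluster counts (default 2-5).
#' @param restarts k-means restarts per k.
#' @param seed Integer seed governing all randomness of the fit.
#' @param item_map MDS-UPDRS item configuration, see [default_item_map()].
#' @param battery PD-MCI battery, see [default_battery()].
#' @param ccc_method Expected-R^2 estimator for the CCC, see
#'   [cubic_clustering_criterion()].
#' @param validate Run the held-out validation comparisons (default TRUE).
#' @return An object of class `pd_subtype` with components `features`
#'   (standardized feature matrix), `scan` (all cluster solutions), `ccc`
#'   (profile and selected k), `solution` (the selected `cluster_solution`),
#'   `labels`, `assignments` (factor of cluster labels per clustered
#'   patient), `flags` (per-patient classifications), `freq_table`,
#'   `validation`, `dropped`, `seed` and `call`. Methods: `print`, `summary`,
#'   `coef` (centroids), `fitted`, `predict`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' \donttest{
#' fit <- pd_subtype(cohort_spec(150, seed = 11), restarts = 10, seed = 11)
#' print(fit)
#' head(fitted(fit))
#' }
#' @export
pd_subtype <- function(cohort, k_range = 2:5, restarts = 50L, seed = 1L,
                       item_map = default_item_map(), battery = default_battery(),
                       ccc_method = c("bootstrap", "analytic"), validate = TRUE) {
  cl <- match.call()
  ccc_method <- match.arg(ccc_method)
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  if (!is.data.frame(cohort) || !nrow(cohort)) stop("cohort must be a non-empty data frame")

  features <- build_feature_matrix(cohort, item_map)
  scan <- run_cluster_scan(features, k_range = k_range, restarts = restarts,
                           seed = seed, method = ccc_method)
  sel_k <- scan$ccc$selected_k
  solution <- scan$solutions[[paste0("k", sel_k)]]
  labels <- label_clusters(solution, features)
  assignments <- factor(labels[solution$cluster], levels = unique(labels))
  names(assignments) <- features$ids

  clustered <- cohort[cohort$id %in% features$ids, , drop = FALSE]
  flags <- classify_symptoms(clustered, battery)
  freq <- frequency_table(flags, assignments)
  validation <- if (validate) validate_solution(clustered, assignments) else NULL

  structure(list(cohort = cohort, features = features, scan = scan$solutions,
                 ccc = scan$ccc, k = sel_k, solution = solution, labels = labels,
                 assignments = assignments, flags = flags, freq_table = freq,
                 validation = validation, dropped = features$dropped,
                 item_map = item_map, battery = battery, seed = seed, call = cl),
            class = "pd_subtype")
}

#' @export
print.pd_subtype <- function(x, ...) {
  cat("Data-driven PD subtyping fit\n")
  cat(sprintf("  patients: %d clustered (%d dropped)\n",
              length(x$assignments), length(x$dropped)))
  cat(sprintf("  CCC over k = %s: %s\n",
              paste(x$ccc$profile$k, collapse = ","),
              paste(sprintf("%.2f", x$ccc$profile$ccc), collapse = ", ")))
  cat(sprintf("  selected k = %d (%s)\n", x$k, x$ccc$selection_kind))
  cat("  cluster sizes:\n")
  print(table(x$assignments))
  invisible(x)
}

# Table-1-shaped per-cluster characteristics: mean (SD) of each raw
# clustering variable plus the normality-gated omnibus test.
.cluster_characteristics <- function(x) {
  raw <- x$features$raw
  g <- x$assignments
  vars <- colnames(raw)
  rows <- lapply(vars, function(v) {
    by_group <- split(raw[, v], g)
    cells <- vapply(by_group, function(s)
      sprintf("%.2f (%.2f)", mean(s), stats::sd(s)), character(1))
    parametric <- all(vapply(by_group, function(s)
      length(s) >= 5L && ks_normality(s, v)$p_value > 0.05, logical(1)))
    omni <- omnibus_test(by_group, parametric, variable = v)
    c(variable = v, cells,
      test = sprintf("%s = %.2f, p = %.3g", omni$test, omni$statistic, omni$p_value))
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

#' @export
summary.pd_subtype <- function(object, ...) {
  out <- list(
    k = object$k, selection = object$ccc,
    sizes = table(object$assignments),
    characteristics = .cluster_characteristics(object),
    frequencies = object$freq_table,
    validation = object$validation,
    dropped = length(object$dropped)
  )
  class(out) <- "summary.pd_subtype"
  out
}

#' @export
print.summary.pd_subtype <- function(x, ...) {
  cat(sprintf("Selected k = %d (%s); cluster sizes: %s\n\n",
              x$k, x$selection$selection_kind,
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", ")))
  cat("Cluster characteristics (mean (SD), omnibus test):\n")
  print(x$characteristics, row.names = FALSE)
  cat("\nPD-MCI and comorbid symptom frequencies (%):\n")
  print(x$frequencies)
  if (!is.null(x$validation)) {
    cat("\nValidation on held-out variables (uncorrected alpha = 0.05):\n")
    print(x$validation, row.names = FALSE)
  }
  if (x$dropped) cat(sprintf("\n%d record(s) dropped as incomplete\n", x$dropped))
  invisible(x)
}

#' @export
coef.pd_subtype <- function(object, standardized = FALSE, ...) {
  cent <- object$solution$centers
  rownames(cent) <- object$labels
  if (standardized) return(cent)
  sweep(sweep(cent, 2, object$features$scale, "*"), 2, object$features$center, "+")
}

#' @export
fitted.pd_subtype <- function(object, ...) object$assignments

#' @export
residuals.pd_subtype <- function(object, ...) {
  X <- object$features$values
  C <- object$solution$centers[object$solution$cluster, , drop = FALSE]
  r <- sqrt(rowSums((X - C)^2))
  names(r) <- object$features$ids
  r
}

#' Assign new patients to fitted clusters
#'
#' Derives the clustering variables for `newdata`, standardizes them with
#' the training centering/scaling, and assigns each record to the nearest
#' fitted centroid.
#'
#' @param object A `pd_subtype` fit.
#' @param newdata Cohort data frame with the same schema.
#' @param ... Unused.
#' @return Factor of cluster labels, named by patient id.
#' @export
predict.pd_subtype <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  raw <- .raw_features(newdata, object$item_map)
  Z <- sweep(sweep(raw, 2, object$features$center), 2, object$features$scale, "/")
  d <- .dist2(Z, object$solution$centers)
  cl <- max.col(-d, ties.method = "first")
  out <- factor(object$labels[cl], levels = levels(object$assignments))
  names(out) <- newdata$id
  out
}

#' @export
plot.pd_subtype <- function(x, which = c("ccc", "profile"), ...) {
  which <- match.arg(which)
  if (which == "ccc") {
    pr <- x$ccc$profile
    graphics::plot(pr$k, pr$ccc, type = "b", pch = 19,
                   xlab = "number of clusters k", ylab = "cubic clustering criterion",
                   main = "CCC profile", ...)
    graphics::points(x$k, pr$ccc[pr$k == x$k], col = "red3", pch = 19, cex = 1.5)
    graphics::abline(h = 0, lty = 3)
  } else {
    cent <- coef(x, standardized = TRUE)
    graphics::matplot(t(cent), type = "b", pch = 19, lty = 1,
                      xaxt = "n", xlab = "", ylab = "standardized centroid",
                      main = "Cluster profiles", ...)
    graphics::axis(1, at = seq_len(ncol(cent)), labels = colnames(cent),
                   las = 2, cex.axis = 0.8)
    graphics::legend("topright", legend = rownames(cent), col = seq_len(nrow(cent)),
                     lty = 1, pch = 19, bty = "n")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Simulate cohorts from a fitted subtyping model
#'
#' Estimates generating profiles from the fitted clusters (per-cluster
#' means/SDs of the continuous variables, symptom prevalences from the
#' classified flags, mixing weights from the cluster sizes) and draws new
#' synthetic cohorts from them.
#'
#' @param object A `pd_subtype` fit with k clusters.
#' @param nsim Number of cohorts to simulate.
#' @param seed Integer seed.
#' @param n Patients per simulated cohort (default: size of the fitted
#'   cohort).
#' @param ... Unused.
#' @return A list of cohort data frames of length `nsim`.
#' @export
simulate.pd_subtype <- function(object, nsim = 1, seed = 1L, n = NULL, ...) {
  n <- n %||% length(object$assignments)
  profiles <- .profiles_from_fit(object)
  lapply(seq_len(nsim), function(i)
    generate_cohort(cohort_spec(n, seed = seed + i - 1L, profiles = profiles)))
}

.profiles_from_fit <- function(object) {
  g <- object$assignments
  raw <- object$features$raw
  co <- object$cohort[object$cohort$id %in% object$features$ids, , drop = FALSE]
  rngs <- .variable_ranges
  fitvar <- c(motor_phenotype = "motor_phenotype", age_onset = "age_onset",
              progression_rate = "progression_rate", nart_iq = "nart_iq",
              mmse = "mmse", lm2_z = "lm2_z", tmtb_z = "tmtb_z", bdi = "bdi")
  labs <- levels(g)
  w <- as.numeric(table(g)) / length(g)
  profiles <- lapply(seq_along(labs), function(i) {
    idx <- g == labs[i]
    est <- function(v) c(mean(v[idx]), max(stats::sd(v[idx]), 1e-3))
    cont <- t(vapply(rngs$variable, function(vn) {
      src <- if (vn %in% names(fitvar)) raw[, fitvar[[vn]]]
             else switch(vn,
               disease_duration = co$disease_duration,
               ledd = co$ledd_mg,
               hy_stage = co$hy_stage,
               pdq39_cog = pdq39_dimension_score(co[paste0("pdq39_q", 30:33)]))
      est(src)
    }, numeric(2)))
    tab <- data.frame(variable = rngs$variable,
                      mean = pmin(pmax(cont[, 1], rngs$lower), rngs$upper),
                      sd = cont[, 2], lower = rngs$lower, upper = rngs$upper)
    fl <- object$flags[idx, , drop = FALSE]
    prev <- vapply(c("fog", "hallucination", "scopa_ns", "scopa_ds", "ess", "rbdsq"),
                   function(f) mean(fl[[f]]), numeric(1))
    cluster_profile(labs[i], w[i], tab, prev, mean(fl$pdmci))
  })
  names(profiles) <- labs
  profiles
}
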