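# Instrument range checks applied on read; (column, lower, upper).
.schema_ranges <- list(
  hy_stage = c(1, 3), updrs_1_1 = c(0, 4), updrs_1_2 = c(0, 4),
  mmse = c(0, 30), bdi_total = c(0, 63), ess_total = c(0, 24),
  scopa_ds = c(0, 18), scopa_ns = c(0, 15), rbdsq_total = c(0, 13),
  fogq3 = c(0, 4), scopa_pc1 = c(0, 3), ledd_mg = c(0, Inf)
)

#' Write a cohort to CSV (with a sidecar manifest)
#'
#' One patient per row, UTF-8, comma-separated, `.` decimal separator,
#' header row mandatory. A JSON sidecar (`<path>.meta.json`) records the
#' generating spec (n, seed, mode, profile labels and weights) when the
#' cohort carries one, plus the package version.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  spec <- attr(cohort, "spec")
  meta <- list(
    n = nrow(cohort),
    columns = names(cohort),
    package_version = as.character(utils::packageVersion("pdsubtype"))
  )
  if (!is.null(spec)) {
    meta$spec <- list(n = spec$n, seed = spec$seed, mode = spec$mode,
                      profiles = lapply(spec$profiles, function(p)
                        list(label = p$label, weight = p$weight)))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the documented schema: every mandatory column must be present
#' (a missing one is reported by name) and instrument-scored columns must
#' lie within their ranges (violations are reported with row and column).
#'
#' @param path CSV path written by [write_cohort_csv()] or following the
#'   same schema.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  co <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mandatory <- setdiff(.cohort_columns, c("latent_cluster"))
  missing <- setdiff(mandatory, names(co))
  if (length(missing))
    stop(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  for (col in names(.schema_ranges)) {
    rng <- .schema_ranges[[col]]
    bad <- which(!is.na(co[[col]]) & (co[[col]] < rng[1] | co[[col]] > rng[2]))
    if (length(bad))
      stop(sprintf("out-of-range value in column '%s', row %d: %s",
                   col, bad[1], format(co[[col]][bad[1]])), call. = FALSE)
  }
  co$id <- as.character(co$id)
  co$da_flag <- as.logical(co$da_flag)
  co
}

#' Write the full run report
#'
#' Persists every table of a [pd_subtype()] fit: the cohort and standardized
#' feature matrix, per-patient assignments and classification flags, the CCC
#' profile, the cluster-characteristics table (per-cluster mean/SD with
#' omnibus tests), the held-out validation comparisons, the per-cluster
#' frequency table, and a machine-readable run manifest (call, seed, sizes,
#' selected k, package and R versions). Every percentage in the frequency
#' CSV is reproducible by recounting the flags CSV.
#'
#' @param fit A `pd_subtype` fit.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "pd_subtype"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  write_cohort_csv(fit$cohort, p("cohort.csv"))
  utils::write.csv(data.frame(id = fit$features$ids, fit$features$values,
                              check.names = FALSE),
                   p("feature_matrix.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = names(fit$assignments),
                              cluster_index = fit$solution$cluster,
                              cluster_label = as.character(fit$assignments)),
                   p("assignments.csv"), row.names = FALSE)
  utils::write.csv(fit$ccc$profile, p("ccc_profile.csv"), row.names = FALSE)
  utils::write.csv(.cluster_characteristics(fit), p("cluster_characteristics.csv"),
                   row.names = FALSE)
  if (!is.null(fit$validation))
    utils::write.csv(fit$validation, p("validation.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(fit$freq_table), fit$freq_table,
                              check.names = FALSE),
                   p("frequencies.csv"), row.names = FALSE)
  utils::write.csv(fit$flags, p("flags.csv"), row.names = FALSE)

  manifest <- list(
    call = paste(deparse(fit$call), collapse = " "),
    seed = fit$seed,
    n_total = nrow(fit$cohort),
    n_clustered = length(fit$assignments),
    n_dropped = length(fit$dropped),
    selected_k = fit$k,
    selection_kind = fit$ccc$selection_kind,
    cluster_sizes = as.list(table(fit$assignments)),
    package_version = as.character(utils::packageVersion("pdsubtype")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
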