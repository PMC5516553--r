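#' Default MDS-UPDRS item map for the motor phenotype score
#'
#' The tremor score is the mean of the rest/action tremor items (item 23, the
#' lateralized 54/55 pair resolved to its higher side, and item 59); the
#' non-tremor score is the mean of items 28-44 (speech, facial expression,
#' rigidity, gait/postural items, global spontaneity of movement). Item
#' numbering follows a flattened sequential numbering of the instrument and is
#' configuration: each entry is a character vector of cohort column names, and
#' entries with more than one column are resolved by the elementwise maximum
#' (the higher lateralized score).
#'
#' @return List with elements `tremor` and `nontremor`, each a list of
#'   character vectors of column names.
#' @export
default_item_map <- function() {
  list(
    tremor = list("updrs_23", c("updrs_54", "updrs_55"), "updrs_59"),
    nontremor = as.list(paste0("updrs_", 28:44))
  )
}

#' Rate of disease progression
#'
#' Total MDS-UPDRS score for sections I-III divided by disease duration in
#' years, allowing comparison between patients with differing disease
#' durations assessed at a single time point. Durations are floored at 0.25
#' years so that degenerate synthetic inputs cannot produce explosive rates.
#'
#' @param updrs_total Total MDS-UPDRS I-III score (>= 0). Vectorized.
#' @param duration Disease duration in years (> 0). Vectorized.
#' @return Progression rate in UPDRS points per year.
#' @examples
#' compute_progression_rate(36, 2)   # 18
#' compute_progression_rate(20, 0.1) # 80, via the 0.25-year floor
#' @export
compute_progression_rate <- function(updrs_total, duration) {
  if (any(updrs_total < 0)) stop("updrs_total must be >= 0")
  if (any(duration <= 0)) stop("duration must be > 0")
  updrs_total / pmax(duration, 0.25)
}

#' Higher lateralized item score
#'
#' @param left,right Item scores in `[0, 4]`.
#' @return `max(left, right)`, elementwise.
#' @export
lateralized_max <- function(left, right) {
  stop_if_out_of_range(left, 0, 4, "left item score")
  stop_if_out_of_range(right, 0, 4, "right item score")
  pmax(left, right)
}

.resolve_items <- function(cohort, entries) {
  vals <- lapply(entries, function(cols) {
    missing <- setdiff(cols, names(cohort))
    if (length(missing))
      stop(sprintf("missing MDS-UPDRS item column(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    Reduce(pmax, cohort[cols])
  })
  rowMeans(do.call(cbind, vals))
}

#' Motor phenotype score
#'
#' Mean tremor-item severity divided by mean non-tremor-item severity, each
#' after resolving lateralized items to their higher side. A ratio above 1
#' indicates a tremor-dominant presentation. When the non-tremor score is 0
#' the ratio is capped at 5 (or 0 if the tremor score is also 0), keeping the
#' standardized clustering column finite.
#'
#' @param cohort Cohort data frame (one row per patient).
#' @param item_map Item configuration, see [default_item_map()].
#' @return Data frame with columns `tremor_score`, `nontremor_score`,
#'   `motor_phenotype`.
#' @export
compute_motor_phenotype <- function(cohort, item_map = default_item_map()) {
  tre <- .resolve_items(cohort, item_map$tremor)
  non <- .resolve_items(cohort, item_map$nontremor)
  ratio <- ifelse(non > 0, tre / non, ifelse(tre > 0, 5, 0))
  data.frame(tremor_score = tre, nontremor_score = non, motor_phenotype = ratio)
}

#' Dopaminergic therapy ordinal
#'
#' Collapses daily L-dopa equivalent dose and dopamine-agonist use to a
#' pre-defined 0-2 scale: 0 = no L-dopa and no agonist; 1 = under 1000 mg/day
#' with or without an agonist, or agonist monotherapy; 2 = 1000 mg/day or
#' more with or without a concomitant agonist (the boundary dose is assigned
#' to the higher-exposure class).
#'
#' @param ldopa_mg Daily L-dopa dose in mg (>= 0). Vectorized.
#' @param da_flag Logical, dopamine agonist use. Vectorized.
#' @return Integer vector with values in `{0, 1, 2}`.
#' @examples
#' compute_dopa_ordinal(c(0, 500, 1200), c(FALSE, TRUE, FALSE)) # 0 1 2
#' @export
compute_dopa_ordinal <- function(ldopa_mg, da_flag) {
  if (any(ldopa_mg < 0)) stop("ldopa_mg must be >= 0")
  ifelse(ldopa_mg >= 1000, 2L, ifelse(ldopa_mg > 0 | da_flag, 1L, 0L))
}

#' PDQ-39 dimension scaled score
#'
#' @param item_scores Numeric vector (or one-row-per-patient matrix/data
#'   frame) of item scores in `[0, 4]`.
#' @return Scaled score(s) on 0-100: `100 * sum(items) / (4 * n_items)`.
#' @examples
#' pdq39_dimension_score(c(1, 2, 3, 2)) # 50
#' @export
pdq39_dimension_score <- function(item_scores) {
  if (is.data.frame(item_scores)) item_scores <- as.matrix(item_scores)
  if (!length(item_scores)) stop("item_scores must be non-empty")
  stop_if_out_of_range(item_scores, 0, 4, "PDQ-39 item score")
  if (is.matrix(item_scores)) {
    100 * rowSums(item_scores) / (4 * ncol(item_scores))
  } else {
    100 * sum(item_scores) / (4 * length(item_scores))
  }
}

# The nine clustering variables, in reporting order.
.feature_names <- c("motor_phenotype", "age_onset", "progression_rate", "nart_iq",
                    "mmse", "lm2_z", "tmtb_z", "bdi", "dopa_ordinal")

# Unstandardized n x 9 matrix of the clustering variables.
.raw_features <- function(cohort, item_map = default_item_map()) {
  mp <- compute_motor_phenotype(cohort, item_map)
  cbind(
    motor_phenotype = mp$motor_phenotype,
    age_onset = cohort$age_onset,
    progression_rate = compute_progression_rate(cohort$updrs_total_i_iii,
                                                cohort$disease_duration),
    nart_iq = cohort$nart_iq,
    mmse = cohort$mmse,
    lm2_z = cohort$lm2_z,
    tmtb_z = cohort$tmtb_z,
    bdi = cohort$bdi_total,
    dopa_ordinal = as.numeric(compute_dopa_ordinal(cohort$ledd_mg, cohort$da_flag))
  )
}

#' Build the standardized clustering feature matrix
#'
#' Computes the nine clustering variables per patient — motor phenotype ratio,
#' age of disease onset, rate of disease progression, premorbid IQ estimate
#' (NART-R), MMSE, Logical Memory II z, Trail Making Test B z, BDI-II and the
#' dopaminergic therapy ordinal — and z-standardizes each column (sample SD,
#' n-1 denominator). Records with any missing constituent are dropped and
#' their count reported; a constant column standardizes to zeros with a
#' warning rather than erroring.
#'
#' @param cohort Cohort data frame.
#' @param item_map Item configuration for the motor phenotype, see
#'   [default_item_map()].
#' @return Object of class `feature_matrix`: list with `values` (standardized
#'   n x 9 matrix), `raw` (unstandardized), `center`, `scale`, `ids`, and
#'   `dropped` (ids of excluded records).
#' @export
build_feature_matrix <- function(cohort, item_map = default_item_map()) {
  if (!nrow(cohort)) stop("cohort must be non-empty")
  raw <- .raw_features(cohort, item_map)
  complete <- stats::complete.cases(raw)
  if (!any(complete)) stop("all records are incomplete for the clustering variables")
  dropped <- cohort$id[!complete]
  if (length(dropped))
    message(sprintf("dropped %d record(s) with incomplete clustering variables", length(dropped)))
  raw <- raw[complete, , drop = FALSE]

  center <- colMeans(raw)
  scale_ <- apply(raw, 2, stats::sd)
  const <- scale_ < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sprintf("constant feature column(s) standardized to zero: %s",
                    paste(colnames(raw)[const], collapse = ", ")))
    scale_[const] <- 1
  }
  values <- sweep(sweep(raw, 2, center), 2, scale_, "/")
  values[, const] <- 0

  structure(list(values = values, raw = raw, center = center, scale = scale_,
                 ids = cohort$id[complete], dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d standardized variables (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  cat("variables:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values
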