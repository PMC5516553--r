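# Published cutoffs, each read as "at or above the first abnormal value"
# (the 13/14 slash notation fixes the convention; unslashed cutoffs follow
# the same inclusive reading).
.cutoffs <- list(
  bdi = 14, ess = 10, scopa_ds = 5, scopa_ns = 7, rbdsq = 5,
  fog = 1, scopa_pc = 1, updrs_1_2 = 1
)

#' Default Level-1 neuropsychological battery
#'
#' The eight battery tests considered for the PD-MCI impairment count, as
#' normative z-score columns of the cohort schema: MMSE, Trail Making Tests A
#' and B, digit span, Logical Memory I and II, phonemic (FAS) and semantic
#' (animals) fluency. The premorbid estimate (NART-R) is not itself countable.
#'
#' @return Character vector of cohort column names.
#' @export
default_battery <- function() {
  c("mmse_z", "tmta_z", "tmtb_z", "digit_z", "lm1_z", "lm2_z", "fas_z", "animals_z")
}

#' Level-1 PD-MCI diagnosis
#'
#' Applies the MDS Task Force Level-1 criteria: (1) impairment on two or more
#' neuropsychological tests, where a test is impaired if its normative
#' z-score lies at least 1.5 SD below the premorbid level of cognitive
#' functioning, operationalized as the NART-R expected z,
#' `(NART-R IQ - 100) / 15`; and (2) subjective cognitive problems, defined
#' as a score of 1 or more on MDS-UPDRS part I item 1.1 (cognitive
#' impairment).
#'
#' @param cohort Cohort data frame with `nart_iq`, `updrs_1_1` and every
#'   battery column.
#' @param battery Test columns counted toward the impairment criterion
#'   (default [default_battery()]).
#' @return Data frame with one row per patient: `impaired_test_count`,
#'   `impaired_tests` (comma-separated names), `subjective_flag`, `diagnosis`.
#' @examples
#' fx <- make_count_fixture(c(NTD = 10), c(NTD = 4), "pdmci", seed = 2)
#' table(diagnose_pdmci(fx)$diagnosis)
#' @export
diagnose_pdmci <- function(cohort, battery = default_battery()) {
  missing <- battery[!battery %in% names(cohort)]
  if (length(missing))
    stop(sprintf("missing battery test score(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (is.null(cohort$nart_iq) || anyNA(cohort$nart_iq))
    stop("NART-R estimated IQ is required for the premorbid level")
  premorbid_z <- (cohort$nart_iq - 100) / 15
  Z <- as.matrix(cohort[battery])
  if (anyNA(Z)) stop("missing battery test score(s)")
  impaired <- Z <= premorbid_z - 1.5
  count <- rowSums(impaired)
  subj <- cohort$updrs_1_1 >= 1
  data.frame(
    id = cohort$id %||% seq_len(nrow(cohort)),
    impaired_test_count = count,
    impaired_tests = apply(impaired, 1, function(r) paste(battery[r], collapse = ",")),
    subjective_flag = subj,
    diagnosis = count >= 2 & subj,
    stringsAsFactors = FALSE
  )
}

#' Rating-scale cutoff classifiers
#'
#' Binary symptom classifiers at the published cutoffs, each inclusive at the
#' first abnormal value: BDI-II >= 14 (13/14 cutoff, at least moderate
#' depressive symptomatology), ESS >= 10 (excessive daytime sleepiness),
#' SCOPA-S daytime >= 5 and night-time >= 7 (4/5 and 6/7 cutoffs), RBDSQ >= 5
#' (probable REM sleep behavior disorder), FOG-Q item 3 positive
#' ("freezers"), and hallucinations screened by SCOPA-PC item 1 >= 1 and
#' confirmed by MDS-UPDRS item 1.2 >= 1.
#'
#' @param bdi BDI-II total, 0-63.
#' @return Logical vector (or a two-column data frame for
#'   `classify_scopa_sleep`).
#' @name cutoff_classifiers
#' @examples
#' classify_depression(c(13, 14)) # FALSE TRUE
#' classify_scopa_sleep(c(5, 4), c(6, 7))
#' @export
classify_depression <- function(bdi) {
  stop_if_out_of_range(bdi, 0, 63, "BDI-II")
  bdi >= .cutoffs$bdi
}

#' @rdname cutoff_classifiers
#' @param ess Epworth Sleepiness Scale total, 0-24.
#' @export
classify_ess <- function(ess) {
  stop_if_out_of_range(ess, 0, 24, "ESS")
  ess >= .cutoffs$ess
}

#' @rdname cutoff_classifiers
#' @param ds,ns SCOPA-S daytime (0-18) and night-time (0-15) subscale totals.
#' @export
classify_scopa_sleep <- function(ds, ns) {
  stop_if_out_of_range(ds, 0, 18, "SCOPA-S (DS)")
  stop_if_out_of_range(ns, 0, 15, "SCOPA-S (NS)")
  data.frame(ds_flag = ds >= .cutoffs$scopa_ds, ns_flag = ns >= .cutoffs$scopa_ns)
}

#' @rdname cutoff_classifiers
#' @param rbdsq RBD Screening Questionnaire total, 0-13.
#' @export
classify_rbd <- function(rbdsq) {
  stop_if_out_of_range(rbdsq, 0, 13, "RBDSQ")
  rbdsq >= .cutoffs$rbdsq
}

#' @rdname cutoff_classifiers
#' @param fogq_item3 Freezing of Gait Questionnaire item 3, 0-4.
#' @export
classify_fog <- function(fogq_item3) {
  stop_if_out_of_range(fogq_item3, 0, 4, "FOG-Q item 3")
  fogq_item3 >= .cutoffs$fog
}

#' @rdname cutoff_classifiers
#' @param scopa_pc_item1 SCOPA-PC item 1, 0-3.
#' @param updrs_1_2 MDS-UPDRS part I item 1.2 (hallucinations/psychosis), 0-4.
#' @export
classify_hallucination <- function(scopa_pc_item1, updrs_1_2) {
  stop_if_out_of_range(scopa_pc_item1, 0, 3, "SCOPA-PC item 1")
  stop_if_out_of_range(updrs_1_2, 0, 4, "MDS-UPDRS item 1.2")
  scopa_pc_item1 >= .cutoffs$scopa_pc & updrs_1_2 >= .cutoffs$updrs_1_2
}

#' Classify all symptoms and PD-MCI for a cohort
#'
#' @param cohort Cohort data frame.
#' @param battery Battery for [diagnose_pdmci()].
#' @return Data frame of per-patient logical flags: `pdmci`, `depression`,
#'   `fog`, `hallucination`, `scopa_ns`, `scopa_ds`, `ess`, `rbdsq`.
#' @export
classify_symptoms <- function(cohort, battery = default_battery()) {
  sleep <- classify_scopa_sleep(cohort$scopa_ds, cohort$scopa_ns)
  data.frame(
    id = cohort$id %||% seq_len(nrow(cohort)),
    pdmci = diagnose_pdmci(cohort, battery)$diagnosis,
    depression = classify_depression(cohort$bdi_total),
    fog = classify_fog(cohort$fogq3),
    hallucination = classify_hallucination(cohort$scopa_pc1, cohort$updrs_1_2),
    scopa_ns = sleep$ns_flag,
    scopa_ds = sleep$ds_flag,
    ess = classify_ess(cohort$ess_total),
    rbdsq = classify_rbd(cohort$rbdsq_total),
    stringsAsFactors = FALSE
  )
}

#' Per-cluster frequency table of PD-MCI and comorbid symptoms
#'
#' For every cluster and feature: `100 * positives / cluster size`, rounded
#' to integer percent by the display chain of the source tables (half away
#' from zero to one decimal, then to integer). Empty clusters are reported
#' as `NA`.
#'
#' @param flags Per-patient logical flags, e.g. from [classify_symptoms()].
#' @param groups Cluster assignment per patient (factor or character).
#' @return Integer matrix, features x clusters.
#' @examples
#' fx <- make_count_fixture(c(NTD = 48), c(NTD = 26), "pdmci", seed = 1)
#' frequency_table(classify_symptoms(fx), fx$latent_cluster)["pdmci", ] # 54
#' @export
frequency_table <- function(flags, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(flags))
  feats <- setdiff(names(flags), "id")
  out <- sapply(levels(groups), function(g) {
    idx <- groups == g
    n <- sum(idx)
    if (n == 0L) return(rep(NA_real_, length(feats)))
    vapply(feats, function(f) percent_round(100 * sum(flags[[f]][idx]) / n), numeric(1))
  })
  out <- matrix(as.integer(out), nrow = length(feats),
                dimnames = list(feats, levels(groups)))
  out
}

#' Cluster proportions as printed percentages
#'
#' @param sizes Named integer vector of cluster sizes.
#' @return Named integer vector of percentages of the total, rounded by the
#'   same display chain as [frequency_table()].
#' @examples
#' cluster_proportions(c(YO = 93, TD = 24, NTD = 48, RDP = 44)) # 45 12 23 21
#' @export
cluster_proportions <- function(sizes) {
  out <- as.integer(percent_round(100 * sizes / sum(sizes)))
  names(out) <- names(sizes)
  out
}
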