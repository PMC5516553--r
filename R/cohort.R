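#' Specify a synthetic cohort
#'
#' @param n Number of patients (>= 0).
#' @param seed Integer seed; the same spec always yields the same cohort.
#' @param profiles List of [cluster_profile()] objects whose weights sum to 1.
#' @param mode `"profile"` lets PD-MCI emerge from the sampled
#'   neuropsychological scores; `"prevalence"` forces each patient's PD-MCI
#'   status by a Bernoulli draw at the profile's `mci_prevalence` and
#'   constructs the battery so the Level-1 classifier reproduces it exactly.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L, profiles = default_profiles(),
                        mode = c("profile", "prevalence")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop("n must be a non-negative integer")
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single integer")
  validate_profiles(profiles)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 profiles = profiles, mode = mode),
            class = "cohort_spec")
}

# Columns every complete cohort data frame carries (in this order).
.cohort_columns <- c(
  "id", "latent_cluster", "age", "sex", "age_onset", "disease_duration", "hy_stage",
  "updrs_1_1", "updrs_1_2", "updrs_23",
  paste0("updrs_", 28:44), "updrs_54", "updrs_55", "updrs_59", "updrs_total_i_iii",
  "nart_iq", "mmse", "mmse_z", "tmta_z", "tmtb_z", "digit_z", "lm1_z", "lm2_z",
  "fas_z", "animals_z",
  "bdi_total", "ess_total", "scopa_ds", "scopa_ns", "rbdsq_total",
  "fogq3", "scopa_pc1",
  paste0("pdq39_q", 30:33),
  "ledd_mg", "da_flag"
)

# Questionnaire scores written from a Bernoulli symptom flag: positives land
# at/above the cutoff, negatives strictly below, all inside [0, maxv].
.flagged_score <- function(flag, cutoff, maxv, spread = 2.5) {
  out <- numeric(length(flag))
  np <- sum(flag)
  if (np) out[flag] <- rtrunc_norm(np, cutoff + spread, spread, cutoff, maxv)
  if (np < length(flag))
    out[!flag] <- rtrunc_norm(length(flag) - np, max(cutoff - 1 - spread, 0), spread,
                              0, max(cutoff - 0.1, 0.05))
  out
}

.sample_int <- function(n, values, prob) values[sample.int(length(values), n, replace = TRUE, prob = prob)]

# One within-cluster block of m synthetic patients. Continuous variables are
# truncated-normal; UPDRS items are back-filled so the derived motor phenotype
# and progression rate reproduce each record's sampled targets.
.generate_block <- function(m, profile, mode) {
  ct <- profile$continuous
  draw <- function(v) {
    r <- ct[ct$variable == v, ]
    if (!nrow(r)) stop(sprintf("profile '%s' lacks continuous variable '%s'", profile$label, v))
    rtrunc_norm(m, r$mean, r$sd, r$lower, r$upper)
  }

  age_onset <- draw("age_onset")
  duration  <- draw("disease_duration")
  rate      <- draw("progression_rate")
  mp        <- draw("motor_phenotype")
  nart      <- draw("nart_iq")
  mmse      <- draw("mmse")
  lm2       <- draw("lm2_z")
  tmtb      <- draw("tmtb_z")
  bdi       <- draw("bdi")
  ledd      <- draw("ledd")
  hy        <- pmin(3, pmax(1, round(draw("hy_stage") * 2) / 2))
  pdq_cog   <- draw("pdq39_cog")

  # UPDRS back-fill: common non-tremor severity nv and tremor severity tv with
  # tv/nv equal to the sampled motor-phenotype target (tv capped at the item
  # maximum 4 by shrinking nv for extreme ratios).
  nv <- ifelse(mp > 0 & mp * 1.5 > 4, 4 / mp, 1.5)
  tv <- mp * nv
  total <- rate * pmax(duration, 0.25)

  # Cluster-level cognitive tendency for battery tests not in the profile.
  aux_mean <- mean(c(ct$mean[ct$variable == "lm2_z"], ct$mean[ct$variable == "tmtb_z"]))
  aux <- function() rtrunc_norm(m, aux_mean, 1, -4, 4)
  tmta <- aux(); digit <- aux(); lm1 <- aux(); fas <- aux(); animals <- aux()
  mmse_z <- (mmse - 28) / 1.5

  if (mode == "prevalence") {
    mci <- stats::runif(m) < profile$mci_prevalence
    premorbid_z <- (nart - 100) / 15
    tmta[mci] <- premorbid_z[mci] - 2
    lm1[mci]  <- premorbid_z[mci] - 2
    updrs_1_1 <- ifelse(mci, 1L, 0L)
  } else {
    mci <- rep(NA, m)
    updrs_1_1 <- .sample_int(m, 0:3, c(0.50, 0.30, 0.15, 0.05))
  }

  # Comorbid symptom flags -> questionnaire scores at/above or below cutoff.
  pv <- profile$prevalence
  flag <- function(nm) stats::runif(m) < pv[[nm]]
  f_fog <- flag("fog"); f_hal <- flag("hallucination")
  f_ns <- flag("scopa_ns"); f_ds <- flag("scopa_ds")
  f_ess <- flag("ess"); f_rbd <- flag("rbdsq")

  fogq3 <- ifelse(f_fog, .sample_int(m, 1:4, c(0.55, 0.27, 0.13, 0.05)), 0L)
  scopa_pc1 <- ifelse(f_hal, .sample_int(m, 1:3, c(0.72, 0.20, 0.08)), 0L)
  updrs_1_2 <- ifelse(f_hal, .sample_int(m, 1:4, c(0.60, 0.25, 0.10, 0.05)),
                      .sample_int(m, 0:1, c(0.85, 0.15)))

  out <- data.frame(
    id = NA_character_, latent_cluster = profile$label,
    age = age_onset + duration, sex = sample(c("M", "F"), m, TRUE, prob = c(0.689, 0.311)),
    age_onset = age_onset, disease_duration = duration, hy_stage = hy,
    updrs_1_1 = updrs_1_1, updrs_1_2 = updrs_1_2, updrs_23 = tv,
    stringsAsFactors = FALSE
  )
  for (j in 28:44) out[[paste0("updrs_", j)]] <- nv
  out$updrs_54 <- tv
  out$updrs_55 <- 0.6 * tv
  out$updrs_59 <- tv
  out$updrs_total_i_iii <- total
  out$nart_iq <- nart; out$mmse <- mmse; out$mmse_z <- mmse_z
  out$tmta_z <- tmta; out$tmtb_z <- tmtb; out$digit_z <- digit
  out$lm1_z <- lm1; out$lm2_z <- lm2; out$fas_z <- fas; out$animals_z <- animals
  out$bdi_total <- bdi
  out$ess_total <- .flagged_score(f_ess, 10, 24)
  out$scopa_ds <- .flagged_score(f_ds, 5, 18)
  out$scopa_ns <- .flagged_score(f_ns, 7, 15)
  out$rbdsq_total <- .flagged_score(f_rbd, 5, 13)
  out$fogq3 <- fogq3; out$scopa_pc1 <- scopa_pc1
  for (q in 30:33) out[[paste0("pdq39_q", q)]] <- pdq_cog / 25
  out$ledd_mg <- ledd
  out$da_flag <- stats::runif(m) < 0.29
  if (mode == "prevalence") out$mci_latent <- mci
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws each patient's latent subgroup from the profile mixing weights, then
#' samples continuous clinical variables from cluster-specific truncated
#' normal distributions (rejection sampling within instrument range), draws
#' binary comorbid symptoms Bernoulli at the cluster prevalences and writes
#' them back into the corresponding questionnaire scores (positives at/above
#' the published cutoff, negatives below), and back-fills MDS-UPDRS item
#' scores so that the derived motor-phenotype ratio and progression rate of
#' each record reproduce that record's sampled targets.
#'
#' Assessment age is `age_onset + disease_duration`, matching the reported
#' per-cluster means of both tables exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per patient (see `pdsubtype:::.cohort_columns`
#'   for the schema) and the spec attached as attribute `"spec"`. In
#'   `mode = "prevalence"` an extra logical column `mci_latent` carries the
#'   forced PD-MCI status.
#' @examples
#' cohort <- generate_cohort(cohort_spec(50, seed = 7))
#' table(cohort$latent_cluster)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  labels <- vapply(spec$profiles, function(p) p$label, character(1))
  weights <- vapply(spec$profiles, function(p) p$weight, numeric(1))

  cohort <- with_seed(spec$seed, {
    if (spec$n == 0L) {
      NULL
    } else {
      latent <- sample(labels, spec$n, replace = TRUE, prob = weights)
      blocks <- vector("list", length(labels))
      idx <- vector("list", length(labels))
      for (i in seq_along(labels)) {
        idx[[i]] <- which(latent == labels[i])
        m <- length(idx[[i]])
        if (m) blocks[[i]] <- .generate_block(m, spec$profiles[[i]], spec$mode)
      }
      keep <- !vapply(blocks, is.null, logical(1))
      out <- do.call(rbind, blocks[keep])
      out <- out[order(unlist(idx[keep])), , drop = FALSE]
      rownames(out) <- NULL
      out$id <- sprintf("P%04d", seq_len(spec$n))
      out
    }
  })
  if (is.null(cohort)) {
    cohort <- .generate_block(1L, spec$profiles[[1]], spec$mode)[0, , drop = FALSE]
    cohort$id <- character(0)
  }
  attr(cohort, "spec") <- spec
  cohort
}

#' Deterministic fixture with exact per-subgroup positive counts
#'
#' Builds a cohort in which exactly `positive_counts[g]` patients of subgroup
#' `g` are classified positive for `feature` by the package's classifiers and
#' the rest negative — for exact-count checks of the frequency machinery.
#'
#' @param subgroup_sizes Named integer vector (names among the profile labels).
#' @param positive_counts Named integer vector, same names; each entry between
#'   0 and the subgroup size.
#' @param feature One of `"pdmci"`, `"depression"`, `"fog"`, `"hallucination"`,
#'   `"scopa_ns"`, `"scopa_ds"`, `"ess"`, `"rbdsq"`.
#' @param seed Integer seed for the background values.
#' @param profiles Profiles supplying the background distributions.
#' @return A cohort data frame with `latent_cluster` set.
#' @examples
#' fx <- make_count_fixture(c(NTD = 48), c(NTD = 26), "pdmci", seed = 1)
#' sum(diagnose_pdmci(fx)$diagnosis)
#' @export
make_count_fixture <- function(subgroup_sizes, positive_counts, feature, seed = 1L,
                               profiles = default_profiles()) {
  feature <- match.arg(feature, c("pdmci", "depression", "fog", "hallucination",
                                  "scopa_ns", "scopa_ds", "ess", "rbdsq"))
  groups <- names(subgroup_sizes)
  if (is.null(groups) || !all(groups %in% names(profiles)))
    stop("subgroup_sizes must be named by profile labels")
  pos <- positive_counts[groups]
  pos[is.na(pos)] <- 0L
  if (any(pos < 0) || any(pos > subgroup_sizes))
    stop("positive counts must lie between 0 and the subgroup sizes")

  with_seed(seed, {
    blocks <- lapply(groups, function(g) {
      m <- subgroup_sizes[[g]]
      b <- .generate_block(m, profiles[[g]], mode = "profile")
      flag <- seq_len(m) <= pos[[g]]
      switch(feature,
        pdmci = {
          b$nart_iq <- 100; b$mmse_z <- pmax(b$mmse_z, 0)
          b$tmta_z[flag] <- -2; b$lm1_z[flag] <- -2
          b$updrs_1_1 <- ifelse(flag, 1L, 0L)
        },
        depression = b$bdi_total <- ifelse(flag, 20, 5),
        fog = b$fogq3 <- ifelse(flag, 1L, 0L),
        hallucination = {
          b$scopa_pc1 <- ifelse(flag, 1L, 0L)
          b$updrs_1_2 <- ifelse(flag, 1L, 0L)
        },
        scopa_ns = b$scopa_ns <- ifelse(flag, 8, 3),
        scopa_ds = b$scopa_ds <- ifelse(flag, 6, 2),
        ess = b$ess_total <- ifelse(flag, 12, 4),
        rbdsq = b$rbdsq_total <- ifelse(flag, 7, 2))
      b
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out$id <- sprintf("P%04d", seq_len(nrow(out)))
    out
  })
}
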