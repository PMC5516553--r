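#' Construct a cluster generating profile
#'
#' A `cluster_profile` parameterizes one latent patient subgroup for the
#' synthetic-cohort generator: truncated-normal parameters (mean, SD, valid
#' range) for each continuous clinical variable, Bernoulli prevalences for the
#' binary comorbid symptoms, and a PD-MCI prevalence.
#'
#' @param label Subgroup label, one of `"YO"`, `"TD"`, `"NTD"`, `"RDP"` (or any
#'   short identifier for custom profiles).
#' @param weight Mixing proportion in `[0, 1]`.
#' @param continuous Data frame with columns `variable`, `mean`, `sd`, `lower`,
#'   `upper` — one row per continuous variable.
#' @param prevalence Named numeric vector of symptom prevalences in `[0, 1]`
#'   (names among `fog`, `hallucination`, `scopa_ns`, `scopa_ds`, `ess`,
#'   `rbdsq`).
#' @param mci_prevalence PD-MCI prevalence in `[0, 1]`.
#' @return An object of class `cluster_profile`.
#' @seealso [default_profiles()]
#' @export
cluster_profile <- function(label, weight, continuous, prevalence, mci_prevalence) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(weight), length(weight) == 1L, weight >= 0, weight <= 1,
            is.data.frame(continuous),
            all(c("variable", "mean", "sd", "lower", "upper") %in% names(continuous)))
  if (any(continuous$sd < 0)) stop("every sd must be >= 0")
  if (any(continuous$lower >= continuous$upper)) stop("every valid range needs lower < upper")
  stop_if_out_of_range(prevalence, 0, 1, "prevalence")
  stop_if_out_of_range(mci_prevalence, 0, 1, "mci_prevalence")
  structure(list(label = label, weight = weight, continuous = continuous,
                 prevalence = prevalence, mci_prevalence = mci_prevalence),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %s (weight %.3f, PD-MCI prevalence %.2f)\n",
              x$label, x$weight, x$mci_prevalence))
  print(x$continuous, row.names = FALSE)
  cat("symptom prevalences:\n")
  print(x$prevalence)
  invisible(x)
}

# Valid instrument / plausibility ranges used by the rejection sampler.
.variable_ranges <- data.frame(
  variable = c("age_onset", "disease_duration", "progression_rate", "motor_phenotype",
               "nart_iq", "mmse", "lm2_z", "tmtb_z", "bdi", "ledd", "hy_stage", "pdq39_cog"),
  lower    = c(25,  0.25, 0.1, 0,  70,  0, -4, -6,  0,    0, 1,   0),
  upper    = c(90, 40,   60,   5, 131, 30,  4,  4, 63, 3000, 3, 100)
)

.profile_table <- function(means, sds) {
  rng <- .variable_ranges
  data.frame(variable = rng$variable, mean = means, sd = sds,
             lower = rng$lower, upper = rng$upper)
}

#' Default four-subgroup generating profiles
#'
#' Returns the four published subgroup profiles of the early-PD cohort this
#' package emulates: younger onset (YO), tremor dominant (TD), non-tremor
#' dominant (NTD) and rapid disease progression (RDP). Continuous parameters
#' are the per-cluster means/SDs of the reported group characteristics and
#' validation variables; symptom and PD-MCI prevalences are the reported
#' per-cluster frequencies. Mixing weights are the reported cluster
#' proportions 45/12/23/21%, renormalized to sum to one (the printed rounded
#' percentages sum to 101%).
#'
#' @return Named list of four [cluster_profile()] objects (`YO`, `TD`, `NTD`,
#'   `RDP`) whose weights sum to 1.
#' @examples
#' p <- default_profiles()
#' p$YO$continuous[p$YO$continuous$variable == "age_onset", ]
#' sum(vapply(p, function(x) x$weight, numeric(1)))
#' @export
default_profiles <- function() {
  w <- c(YO = 45, TD = 12, NTD = 23, RDP = 21)
  w <- w / sum(w)

  cont <- list(
    YO  = .profile_table(
      means = c(56.63, 6.59, 5.29, 0.68, 112.84, 29.06,  0.16,  0.37, 10.47, 709.29, 1.96, 22.78),
      sds   = c( 8.2,  4.7,  3.1,  0.6,    8.9,   1.0,   0.9,   0.7,   7.1,  482.7, 0.5, 17.23)),
    TD  = .profile_table(
      means = c(62.28, 3.51, 7.49, 1.86, 104.29, 28.21, -0.63, -0.32,  6.17, 231.06, 1.54, 22.57),
      sds   = c( 8.3,  2.8,  6.4,  0.7,   11.5,   1.4,   0.9,   1.4,   6.0,  258.9, 0.5, 18.46)),
    NTD = .profile_table(
      means = c(59.86, 9.07, 4.61, 0.43, 103.04, 26.71, -0.76, -1.58,  9.60, 846.14, 2.17, 33.59),
      sds   = c( 9.3,  5.7,  3.4,  0.4,    8.9,   1.4,   1.0,   1.7,   5.9,  513.4, 0.6, 21.21)),
    RDP = .profile_table(
      means = c(69.87, 2.14, 17.77, 0.62, 113.41, 29.05,  0.36, -0.49,  9.59, 309.07, 1.99, 20.39),
      sds   = c( 7.0,  1.1,   8.5,  0.5,    9.6,   1.1,   0.75,  1.3,   6.5,  260.1, 0.6, 15.31))
  )

  prev <- list(
    YO  = c(fog = 0.41, hallucination = 0.11, scopa_ns = 0.19, scopa_ds = 0.24, ess = 0.22, rbdsq = 0.41),
    TD  = c(fog = 0.08, hallucination = 0.04, scopa_ns = 0.17, scopa_ds = 0.25, ess = 0.17, rbdsq = 0.29),
    NTD = c(fog = 0.69, hallucination = 0.23, scopa_ns = 0.17, scopa_ds = 0.40, ess = 0.46, rbdsq = 0.56),
    RDP = c(fog = 0.25, hallucination = 0.07, scopa_ns = 0.18, scopa_ds = 0.16, ess = 0.25, rbdsq = 0.32)
  )
  mci <- c(YO = 0.24, TD = 0.42, NTD = 0.54, RDP = 0.25)

  profiles <- lapply(names(w), function(g)
    cluster_profile(g, unname(w[[g]]), cont[[g]], prev[[g]], unname(mci[[g]])))
  names(profiles) <- names(w)
  profiles
}

# Validate a list of profiles as a mixture.
validate_profiles <- function(profiles) {
  if (!length(profiles)) stop("profiles must be non-empty")
  if (!all(vapply(profiles, inherits, logical(1), "cluster_profile")))
    stop("profiles must be a list of cluster_profile objects")
  w <- vapply(profiles, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("profile weights must sum to 1")
  invisible(profiles)
}
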