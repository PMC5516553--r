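# A single comparison record; all group_stats results share this shape.
.comparison <- function(variable, comparison, test, statistic, p_value, alpha = 0.05) {
  data.frame(variable = variable, comparison = comparison, test = test,
             statistic = unname(statistic), p_value = unname(p_value),
             alpha = alpha, significant = !is.na(p_value) & p_value <= alpha,
             stringsAsFactors = FALSE)
}

#' Lilliefors-type Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal distribution with the sample's
#' own mean and SD (Lilliefors correction for the estimated parameters),
#' used as the parametric/nonparametric gate. A degenerate (constant) sample
#' is reported as non-normal (`p = 0`).
#'
#' @param x Numeric sample, `n >= 5`.
#' @param variable Label for the report row.
#' @return One-row comparison data frame (`test = "KS"`).
#' @export
ks_normality <- function(x, variable = deparse(substitute(x))) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("normality test requires n >= 5")
  if (stats::sd(x) < .Machine$double.eps^0.5)
    return(.comparison(variable, "normality", "KS", NA_real_, 0))
  lt <- nortest::lillie.test(x)
  .comparison(variable, "normality", "KS", lt$statistic, lt$p.value)
}

#' Omnibus comparison across groups
#'
#' One-way ANOVA F (parametric route) or Kruskal-Wallis H with tie
#' correction (nonparametric route), two-sided.
#'
#' @param groups Named list of numeric samples (>= 2 groups, each `n >= 2`).
#' @param parametric Logical route switch.
#' @param variable Label for the report row.
#' @return One-row comparison data frame.
#' @export
omnibus_test <- function(groups, parametric, variable = "variable") {
  if (length(groups) < 2L) stop("omnibus comparison requires >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) stop("every group needs n >= 2")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups),
                  vapply(groups, length, integer(1))))
  if (parametric) {
    tt <- stats::oneway.test(x ~ g, var.equal = TRUE)
    .comparison(variable, "omnibus", "ANOVA", tt$statistic, tt$p.value)
  } else {
    kw <- stats::kruskal.test(x, g)
    .comparison(variable, "omnibus", "Kruskal-Wallis", kw$statistic, kw$p.value)
  }
}

#' Pairwise two-group comparison
#'
#' Unpaired two-sided t-test with pooled variance (parametric route; Welch
#' available via `var_equal = FALSE`) or Mann-Whitney U (nonparametric
#' route). The U route uses exact enumeration when the combined sample size
#' is at most 12 and there are no ties, otherwise the normal approximation
#' with midranks, tie-corrected variance and (optionally) continuity
#' correction. U is reported as the smaller of U1 and U2.
#'
#' @param x,y The two samples (each `n >= 2`).
#' @param parametric Logical route switch.
#' @param variable Label for the report row.
#' @param comparison Label for the comparison (e.g. `"YO vs TD"`).
#' @param correct Continuity correction for the U normal approximation.
#' @param var_equal Pooled (`TRUE`, default) or Welch t-test.
#' @return One-row comparison data frame.
#' @examples
#' pairwise_test(c(1, 2), c(3, 4), parametric = FALSE)$p_value # 1/3
#' @export
pairwise_test <- function(x, y, parametric, variable = "variable",
                          comparison = "pairwise", correct = TRUE,
                          var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (parametric) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    .comparison(variable, comparison, "t", tt$statistic, tt$p.value)
  } else {
    exact <- (length(x) + length(y)) <= 12L && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = correct))
    u1 <- unname(wt$statistic)
    u <- min(u1, length(x) * length(y) - u1)
    .comparison(variable, comparison, "Mann-Whitney U", u, wt$p.value)
  }
}

#' Validate a cluster solution on held-out variables
#'
#' Reproduces the post-hoc validation machinery on variables not used for
#' clustering — by default age at assessment, disease duration, Hoehn & Yahr
#' stage and the PDQ-39 cognitive-impairment dimension. Each variable is
#' gated per group by the Lilliefors KS test (parametric route only if every
#' group passes at alpha = 0.05 and has n >= 5), compared across groups by
#' the omnibus test, and, when the omnibus is significant, by all pairwise
#' group comparisons. No multiple-testing correction is applied; the report
#' carries an uncorrected-alpha annotation.
#'
#' @param cohort Cohort data frame.
#' @param groups Cluster assignment per patient.
#' @param variables Held-out variables to compare; `"pdq39_cog"` is computed
#'   from the PDQ-39 item columns via [pdq39_dimension_score()].
#' @param alpha Significance level (two-sided).
#' @return Data frame of comparison rows (normality gates omitted; omnibus
#'   plus conditional pairwise rows per variable), with attribute
#'   `"correction"` set to `"none (uncorrected alpha)"`.
#' @export
validate_solution <- function(cohort, groups,
                              variables = c("age", "disease_duration",
                                            "hy_stage", "pdq39_cog"),
                              alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("validation requires >= 2 groups")
  vals <- lapply(variables, function(v) {
    if (v == "pdq39_cog") {
      pdq39_dimension_score(cohort[paste0("pdq39_q", 30:33)])
    } else {
      if (is.null(cohort[[v]])) stop(sprintf("variable '%s' not found in cohort", v))
      cohort[[v]]
    }
  })
  names(vals) <- variables

  rows <- lapply(variables, function(v) {
    by_group <- split(vals[[v]], groups)
    normal <- vapply(by_group, function(s) {
      length(s) >= 5L && ks_normality(s, v)$p_value > alpha
    }, logical(1))
    parametric <- all(normal)
    omni <- omnibus_test(by_group, parametric, variable = v)
    out <- omni
    if (isTRUE(omni$significant)) {
      combos <- utils::combn(levels(groups), 2, simplify = FALSE)
      pw <- lapply(combos, function(pr)
        pairwise_test(by_group[[pr[1]]], by_group[[pr[2]]], parametric,
                      variable = v, comparison = paste(pr[1], "vs", pr[2])))
      out <- rbind(omni, do.call(rbind, pw))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "correction") <- "none (uncorrected alpha)"
  out
}
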