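# Independent oracles used across the suite.

# Exact two-sided Mann-Whitney p by enumeration of all group assignments,
# using the same two-sided convention as wilcox.test's exact mode
# (double the smaller tail, capped at 1).
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(utils::combn(n, nx), 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Minimal within-cluster sum of squares over all bipartitions (k = 2).
best_bipartition_wss <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 12)
  best <- Inf
  # element n stays in the second group, so both groups are always non-empty
  for (code in 1:(2^(n - 1) - 1)) {
    members <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- X[members, , drop = FALSE]
    b <- X[!members, , drop = FALSE]
    wss <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (wss < best) best <- wss
  }
  best
}

# Adjusted Rand index between two labelings.
adj_rand <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  si <- sc(rowSums(tab)); sj <- sc(colSums(tab)); sij <- sc(as.vector(tab))
  expc <- si * sj / choose(n, 2)
  (sij - expc) / ((si + sj) / 2 - expc)
}

# A small hand-built cohort data frame with full schema, for classifier and
# feature tests; all scores neutral unless overridden.
tiny_cohort <- function(n = 4L) {
  co <- data.frame(id = sprintf("T%02d", seq_len(n)), latent_cluster = "YO",
                   age = 65, sex = "M", age_onset = 60, disease_duration = 5,
                   hy_stage = 2, updrs_1_1 = 0L, updrs_1_2 = 0L, updrs_23 = 1,
                   stringsAsFactors = FALSE)
  for (j in 28:44) co[[paste0("updrs_", j)]] <- 1
  co$updrs_54 <- 1; co$updrs_55 <- 0.5; co$updrs_59 <- 1
  co$updrs_total_i_iii <- 30
  co$nart_iq <- 100; co$mmse <- 29; co$mmse_z <- 0
  co$tmta_z <- 0; co$tmtb_z <- 0; co$digit_z <- 0
  co$lm1_z <- 0; co$lm2_z <- 0; co$fas_z <- 0; co$animals_z <- 0
  co$bdi_total <- 5; co$ess_total <- 4; co$scopa_ds <- 2; co$scopa_ns <- 3
  co$rbdsq_total <- 2; co$fogq3 <- 0L; co$scopa_pc1 <- 0L
  for (q in 30:33) co[[paste0("pdq39_q", q)]] <- 1
  co$ledd_mg <- 500; co$da_flag <- FALSE
  co
}
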