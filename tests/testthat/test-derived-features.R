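test_that("progression rate is UPDRS total over floored duration", {
  expect_equal(compute_progression_rate(36, 2), 18)
  expect_equal(compute_progression_rate(20, 0.1), 80) # 0.25-year floor
  expect_equal(compute_progression_rate(0, 5), 0)
  expect_error(compute_progression_rate(10, 0), "> 0")
  expect_error(compute_progression_rate(-1, 1), ">= 0")
})

test_that("lateralized items resolve to the higher side", {
  expect_equal(lateralized_max(1, 3), 3)
  expect_equal(lateralized_max(2, 2), 2)
  expect_equal(lateralized_max(0, 0), 0)
  expect_equal(lateralized_max(c(1, 4), c(2, 0)), c(2, 4))
  expect_error(lateralized_max(5, 1), "\\[0, 4\\]")
})

test_that("motor phenotype is tremor over non-tremor mean with capped ratio", {
  co <- tiny_cohort(1)
  # all tremor items 2, all non-tremor items 1
  co$updrs_23 <- 2; co$updrs_54 <- 2; co$updrs_55 <- 1; co$updrs_59 <- 2
  got <- compute_motor_phenotype(co)
  expect_equal(unlist(got), c(tremor_score = 2, nontremor_score = 1, motor_phenotype = 2))

  co$updrs_23 <- 0; co$updrs_54 <- 0; co$updrs_55 <- 0; co$updrs_59 <- 0
  for (j in 28:44) co[[paste0("updrs_", j)]] <- 1.5
  expect_equal(compute_motor_phenotype(co)$motor_phenotype, 0)

  # zero non-tremor denominator: capped at 5 (or 0 when both are 0)
  co$updrs_23 <- 2; co$updrs_54 <- 2; co$updrs_59 <- 2
  for (j in 28:44) co[[paste0("updrs_", j)]] <- 0
  expect_equal(compute_motor_phenotype(co)$motor_phenotype, 5)
  co$updrs_23 <- 0; co$updrs_54 <- 0; co$updrs_59 <- 0
  expect_equal(compute_motor_phenotype(co)$motor_phenotype, 0)

  co$updrs_30 <- NULL
  expect_error(compute_motor_phenotype(co), "updrs_30")
})

test_that("dopaminergic therapy ordinal follows the 0-2 dose scale", {
  expect_equal(compute_dopa_ordinal(0, FALSE), 0L)
  expect_equal(compute_dopa_ordinal(500, TRUE), 1L)
  expect_equal(compute_dopa_ordinal(500, FALSE), 1L)
  expect_equal(compute_dopa_ordinal(0, TRUE), 1L)  # agonist monotherapy
  expect_equal(compute_dopa_ordinal(1200, FALSE), 2L)
  expect_equal(compute_dopa_ordinal(1000, FALSE), 2L) # boundary -> higher class
  expect_error(compute_dopa_ordinal(-5, FALSE), ">= 0")
})

test_that("PDQ-39 dimension score scales to 0-100", {
  expect_equal(pdq39_dimension_score(c(0, 0, 0, 0)), 0)
  expect_equal(pdq39_dimension_score(c(4, 4, 4, 4)), 100)
  expect_equal(pdq39_dimension_score(c(1, 2, 3, 2)), 50)
  expect_error(pdq39_dimension_score(c(1, 5)), "\\[0, 4\\]")
  expect_error(pdq39_dimension_score(numeric(0)), "non-empty")
})

test_that("feature matrix is column-standardized with n-1 SD", {
  co <- generate_cohort(cohort_spec(60, seed = 10))
  fm <- build_feature_matrix(co)
  expect_equal(unname(colMeans(fm$values)), rep(0, 9), tolerance = 1e-9)
  expect_equal(unname(apply(fm$values, 2, sd)), rep(1, 9), tolerance = 1e-9)
  expect_equal(colnames(fm$values),
               c("motor_phenotype", "age_onset", "progression_rate", "nart_iq",
                 "mmse", "lm2_z", "tmtb_z", "bdi", "dopa_ordinal"))

  # (1, 2, 3) standardizes to (-1, 0, 1) under the sample-SD convention
  co3 <- tiny_cohort(3)
  co3$bdi_total <- c(1, 2, 3)
  fm3 <- suppressWarnings(build_feature_matrix(co3))
  expect_equal(unname(fm3$values[, "bdi"]), c(-1, 0, 1))
  # constant columns standardize to zeros with a warning
  expect_true(all(fm3$values[, "mmse"] == 0))
})

test_that("constant columns warn and records with missing constituents drop", {
  co <- tiny_cohort(3)
  co$bdi_total <- c(1, 2, 3)
  expect_warning(build_feature_matrix(co), "constant")

  co$nart_iq[2] <- NA
  expect_message(fm <- suppressWarnings(build_feature_matrix(co)), "dropped 1")
  expect_equal(fm$dropped, "T02")
  expect_equal(nrow(fm$values), 2L)

  co_all_na <- tiny_cohort(2)
  co_all_na$nart_iq <- NA
  expect_error(suppressWarnings(build_feature_matrix(co_all_na)), "incomplete")
})

test_that("standardization is scale-equivariant and order-stable", {
  co <- generate_cohort(cohort_spec(50, seed = 11))
  fm <- build_feature_matrix(co)

  sc <- co
  sc$nart_iq <- sc$nart_iq * 3          # positive rescale of a raw column
  expect_equal(build_feature_matrix(sc)$values, fm$values, tolerance = 1e-9)

  perm <- sample(nrow(co))
  fm_p <- build_feature_matrix(co[perm, ])
  expect_equal(fm_p$values, fm$values[perm, ], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fm_p$ids, fm$ids[perm])
})

test_that("motor phenotype exceeds 1 exactly when tremor dominates", {
  co <- generate_cohort(cohort_spec(200, seed = 12))
  mp <- compute_motor_phenotype(co)
  pos <- mp$nontremor_score > 0
  expect_equal(mp$motor_phenotype[pos] > 1, (mp$tremor_score > mp$nontremor_score)[pos])
})
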