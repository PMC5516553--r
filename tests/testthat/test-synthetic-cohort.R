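test_that("default profiles carry the published subgroup parameters", {
  p <- default_profiles()
  expect_named(p, c("YO", "TD", "NTD", "RDP"))

  yo_onset <- p$YO$continuous[p$YO$continuous$variable == "age_onset", ]
  expect_equal(yo_onset$mean, 56.63)
  expect_equal(yo_onset$sd, 8.2)
  expect_equal(p$NTD$mci_prevalence, 0.54)
  expect_equal(p$NTD$prevalence[["fog"]], 0.69)

  # printed proportions sum to 101% and are renormalized to 1
  w <- vapply(p, function(x) x$weight, numeric(1))
  expect_equal(sum(w), 1)
  expect_equal(unname(w * 101), c(45, 12, 23, 21))
})

test_that("profile validation rejects malformed mixtures", {
  p <- default_profiles()
  p$YO$weight <- 0.9
  expect_error(pdsubtype:::validate_profiles(p), "sum to 1")
  bad <- default_profiles()$YO
  bad$continuous$sd[1] <- -1
  expect_error(do.call(cluster_profile, unname(bad[c("label", "weight", "continuous",
                                                     "prevalence", "mci_prevalence")])),
               "sd")
  expect_error(cohort_spec(-1), "non-negative")
})

test_that("cohort generation is seeded, bounded and empty-safe", {
  expect_equal(nrow(generate_cohort(cohort_spec(0))), 0L)

  a <- generate_cohort(cohort_spec(209, seed = 1))
  b <- generate_cohort(cohort_spec(209, seed = 1))
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(a, b)
  expect_false(identical(a$bdi_total,
                         generate_cohort(cohort_spec(209, seed = 2))$bdi_total))

  # instrument ranges respected (rejection sampling never clips)
  expect_true(all(a$bdi_total >= 0 & a$bdi_total <= 63))
  expect_true(all(a$mmse >= 0 & a$mmse <= 30))
  expect_true(all(a$hy_stage %in% seq(1, 3, by = 0.5)))
  expect_true(all(a$ess_total >= 0 & a$ess_total <= 24))
  expect_true(all(a$fogq3 %in% 0:4 & a$scopa_pc1 %in% 0:3))
  items <- as.matrix(a[grep("^updrs_(2[38]|[34][0-9]|5[459])$", names(a))])
  expect_true(all(items >= 0 & items <= 4))
  expect_true(all(abs(a$age - a$age_onset - a$disease_duration) <= 1))
})

test_that("derivation round-trips the sampled motor phenotype and progression rate", {
  co <- generate_cohort(cohort_spec(300, seed = 42))
  mp <- compute_motor_phenotype(co)
  rate <- compute_progression_rate(co$updrs_total_i_iii, co$disease_duration)
  # regenerate the targets: they equal the derived values by construction
  fm <- build_feature_matrix(co)
  expect_equal(unname(fm$raw[, "motor_phenotype"]), mp$motor_phenotype, tolerance = 1e-10)
  expect_true(all(mp$motor_phenotype >= 0 & mp$motor_phenotype <= 5))
  expect_true(all(rate > 0 & rate <= 60 / 0.25))
  # the back-filled tremor/non-tremor items reproduce the ratio exactly
  expect_equal(mp$tremor_score / pmax(mp$nontremor_score, 1e-12),
               mp$motor_phenotype, tolerance = 1e-8)
})

test_that("per-cluster sample means converge to the profile means", {
  co <- generate_cohort(cohort_spec(20000, seed = 5))
  p <- default_profiles()
  for (g in names(p)) {
    want <- p[[g]]$continuous
    got <- mean(co$age_onset[co$latent_cluster == g])
    expect_lt(abs(got - want$mean[want$variable == "age_onset"]), 0.2)
  }
})

test_that("prevalence mode forces PD-MCI exactly", {
  spec <- cohort_spec(400, seed = 8, mode = "prevalence")
  co <- generate_cohort(spec)
  expect_identical(diagnose_pdmci(co)$diagnosis, co$mci_latent)
})

test_that("count fixtures hit the requested positives exactly", {
  fx <- make_count_fixture(c(NTD = 48), c(NTD = 26), "pdmci", seed = 1)
  expect_equal(sum(diagnose_pdmci(fx)$diagnosis), 26L)

  fx0 <- make_count_fixture(c(TD = 24), c(TD = 0), "pdmci", seed = 1)
  expect_equal(sum(diagnose_pdmci(fx0)$diagnosis), 0L)

  sizes <- c(YO = 93, TD = 24, NTD = 48, RDP = 44)
  fx2 <- make_count_fixture(sizes, c(YO = 5, TD = 2, NTD = 7, RDP = 3), "ess", seed = 2)
  expect_equal(nrow(fx2), 209L)
  expect_equal(as.vector(table(factor(fx2$latent_cluster, names(sizes)))),
               unname(sizes))
  flags <- classify_symptoms(fx2)
  expect_equal(as.vector(tapply(flags$ess, factor(fx2$latent_cluster, names(sizes)), sum)),
               c(5, 2, 7, 3))

  expect_error(make_count_fixture(c(TD = 5), c(TD = 6), "fog"), "between 0")
})

test_that("cohort CSV round-trips losslessly with schema validation", {
  co <- generate_cohort(cohort_spec(40, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_cohort_csv(path)
  expect_equal(back, as.data.frame(co), ignore_attr = TRUE, tolerance = 1e-12)

  broken <- co
  names(broken)[names(broken) == "bdi_total"] <- "bdi"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "bdi_total")

  oor <- co
  oor$mmse[3] <- 35
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(oor, path3, row.names = FALSE)
  expect_error(read_cohort_csv(path3), "mmse.*row 3")
})
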