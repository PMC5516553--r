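test_that("rating-scale cutoffs are inclusive at the first abnormal value", {
  expect_equal(classify_depression(c(13, 14, 0)), c(FALSE, TRUE, FALSE))
  expect_equal(classify_ess(c(9, 10, 24)), c(FALSE, TRUE, TRUE))
  expect_equal(classify_scopa_sleep(c(5, 4, 0), c(6, 7, 0)),
               data.frame(ds_flag = c(TRUE, FALSE, FALSE),
                          ns_flag = c(FALSE, TRUE, FALSE)))
  expect_equal(classify_rbd(c(4, 5, 13)), c(FALSE, TRUE, TRUE))
  expect_equal(classify_fog(c(0, 1, 4)), c(FALSE, TRUE, TRUE))
  expect_equal(classify_hallucination(c(1, 2, 0), c(1, 0, 3)),
               c(TRUE, FALSE, FALSE))

  expect_error(classify_depression(64), "BDI")
  expect_error(classify_ess(-1), "ESS")
  expect_error(classify_rbd(14), "RBDSQ")
  expect_error(classify_fog(5), "FOG")
  expect_error(classify_hallucination(4, 0), "SCOPA-PC")
})

test_that("Level-1 PD-MCI requires two impaired tests plus subjective complaint", {
  co <- tiny_cohort(3)
  co$updrs_1_1 <- 1L
  # patient 1: two tests 1.6 SD below premorbid; patient 2: one test; patient 3: none
  co$tmta_z <- c(-1.6, -2.0, 0)
  co$lm1_z <- c(-1.6, 0, 0)
  st <- diagnose_pdmci(co)
  expect_equal(st$diagnosis, c(TRUE, FALSE, FALSE))
  expect_equal(st$impaired_test_count, c(2, 1, 0))
  expect_equal(st$impaired_tests[1], "tmta_z,lm1_z")

  # three impaired tests but no subjective complaint -> no diagnosis
  co2 <- tiny_cohort(1)
  co2$updrs_1_1 <- 0L
  co2$tmta_z <- co2$lm1_z <- co2$fas_z <- -2
  expect_false(diagnose_pdmci(co2)$diagnosis)

  # impairment is relative to the NART-R premorbid level, not to zero
  co3 <- tiny_cohort(1)
  co3$updrs_1_1 <- 1L
  co3$nart_iq <- 130            # premorbid z = +2; z = 0.4 is already impaired
  co3$tmta_z <- co3$lm1_z <- 0.4
  expect_true(diagnose_pdmci(co3)$diagnosis)

  expect_error(diagnose_pdmci(tiny_cohort(2), battery = c("tmta_z", "nope_z")),
               "nope_z")
})

test_that("the diagnosis is invariant to adding unimpaired tests", {
  co <- tiny_cohort(2)
  co$updrs_1_1 <- 1L
  co$tmta_z <- c(-2, 0); co$lm1_z <- c(-2, 0)
  small <- diagnose_pdmci(co, battery = c("tmta_z", "lm1_z"))
  full <- diagnose_pdmci(co)
  expect_equal(small$diagnosis, full$diagnosis)
})

test_that("cutoff classifiers are monotone in their raw scores", {
  set.seed(33)
  for (i in 1:50) {
    b <- runif(1, 0, 60); expect_false(classify_depression(b) && !classify_depression(min(b + runif(1, 0, 3), 63)))
    e <- runif(1, 0, 20); expect_false(classify_ess(e) && !classify_ess(min(e + runif(1, 0, 4), 24)))
    r <- runif(1, 0, 12); expect_false(classify_rbd(r) && !classify_rbd(min(r + 1, 13)))
  }
})

test_that("frequency tables reproduce printed percentages from counts", {
  sizes <- c(YO = 93, TD = 24, NTD = 48, RDP = 44)
  pos <- c(YO = 22, TD = 10, NTD = 26, RDP = 11)
  fx <- make_count_fixture(sizes, pos, "pdmci", seed = 7)
  flags <- classify_symptoms(fx)
  tab <- frequency_table(flags, factor(fx$latent_cluster, names(sizes)))
  expect_equal(tab["pdmci", ], c(YO = 24L, TD = 42L, NTD = 54L, RDP = 25L))

  # reproducible by recount, all within [0, 100]
  recount <- vapply(names(sizes), function(g)
    pdsubtype:::percent_round(100 * sum(flags$pdmci[fx$latent_cluster == g]) / sizes[[g]]),
    numeric(1))
  expect_equal(tab["pdmci", ], vapply(recount, as.integer, integer(1)))
  expect_true(all(tab >= 0 & tab <= 100))

  # zero positives give 0; empty clusters give NA
  fx0 <- make_count_fixture(c(TD = 10), c(TD = 0), "fog", seed = 1)
  f0 <- classify_symptoms(fx0)
  tab0 <- frequency_table(f0, factor(fx0$latent_cluster, c("TD", "NTD")))
  expect_equal(tab0["fog", "TD"], 0L)
  expect_true(is.na(tab0["fog", "NTD"]))
})

test_that("cluster proportions reproduce the printed cohort percentages", {
  expect_equal(cluster_proportions(c(YO = 93, TD = 24, NTD = 48, RDP = 44)),
               c(YO = 45L, TD = 12L, NTD = 23L, RDP = 21L))
})
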