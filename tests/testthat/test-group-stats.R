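test_that("the normality gate accepts normal and rejects uniform samples", {
  set.seed(41)
  nrm <- ks_normality(rnorm(500), "x")
  expect_equal(nrm$test, "KS")
  expect_gt(nrm$p_value, 0.05)

  unif <- ks_normality(runif(500), "x")
  expect_lt(unif$p_value, 0.05)

  const <- ks_normality(rep(2, 10), "x")
  expect_equal(const$p_value, 0)
  expect_true(const$significant)

  expect_error(ks_normality(1:4), "n >= 5")
})

test_that("omnibus tests route to ANOVA or Kruskal-Wallis", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  kw <- omnibus_test(g, parametric = FALSE)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  expect_equal(kw$test, "Kruskal-Wallis")

  # two-group ANOVA F equals the squared pooled t statistic
  set.seed(42)
  x <- rnorm(15); y <- rnorm(12, 1)
  f <- omnibus_test(list(x = x, y = y), parametric = TRUE)
  t2 <- pairwise_test(x, y, parametric = TRUE)
  expect_equal(f$statistic, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(f$p_value, t2$p_value, tolerance = 1e-10)

  expect_error(omnibus_test(list(1:3), FALSE), ">= 2 groups")
  expect_error(omnibus_test(list(1:3, 2), FALSE), "n >= 2")
})

test_that("exact Mann-Whitney p agrees with the enumeration oracle", {
  r <- pairwise_test(c(1, 2), c(3, 4), parametric = FALSE)
  expect_equal(r$statistic, 0)            # U reported as min(U1, U2)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(43)
  for (i in 1:30) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    repeat {
      x <- round(rnorm(nx, 0, 5), 3); y <- round(rnorm(ny, 0.5, 5), 3)
      if (!any(duplicated(c(x, y)))) break
    }
    got <- pairwise_test(x, y, parametric = FALSE)
    expect_equal(got$p_value, enum_mw_p(x, y), tolerance = 1e-12)
    expect_lte(got$statistic, nx * ny / 2)
  }
})

test_that("degenerate and parametric pairwise cases behave", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  tt <- pairwise_test(x, x, parametric = TRUE)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p_value, 1)
  expect_error(pairwise_test(1, 1:3, TRUE), "n >= 2")
})

test_that("two-sample Kruskal-Wallis matches the uncorrected U normal approximation", {
  set.seed(44)
  x <- rnorm(18); y <- rnorm(15, 0.3)     # continuous, no ties
  kw <- omnibus_test(list(x = x, y = y), parametric = FALSE)
  mw <- pairwise_test(x, y, parametric = FALSE, correct = FALSE)
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-6)
})

test_that("cluster validation reports omnibus and conditional pairwise rows", {
  co <- generate_cohort(cohort_spec(300, seed = 15))
  v <- validate_solution(co, co$latent_cluster)
  expect_equal(attr(v, "correction"), "none (uncorrected alpha)")
  omni <- v[v$comparison == "omnibus", ]
  expect_equal(omni$variable, c("age", "disease_duration", "hy_stage", "pdq39_cog"))
  expect_true(all(omni$significant))
  # significant omnibus rows are followed by all 6 pairwise comparisons
  for (vr in omni$variable[omni$significant])
    expect_equal(sum(v$variable == vr & v$comparison != "omnibus"), 6L)
  expect_true(all(v$p_value >= 0 & v$p_value <= 1))

  expect_error(validate_solution(co, rep("A", nrow(co))), ">= 2 groups")
})
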