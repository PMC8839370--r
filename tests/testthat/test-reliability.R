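test_that("ICC(2,1) handles perfect agreement and rejects tiny samples", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc21(m)$icc, 1)
  expect_error(icc21(matrix(c(1, 2, 2, 1), 2, 2)),
               class = "gaitreliab_reliability_error")
  z <- icc21(matrix(5, 4, 2))
  expect_true(is.na(z$icc))
  expect_identical(z$flag, "zero_variance")
})

test_that("ICC(2,1) agrees with a variance-components oracle to 1e-10", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:30, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n, 0, runif(1, 0, 3))
    expect_lt(abs(icc21(m)$icc - icc21_oracle(m)), 1e-10)
  }
})

test_that("ICC confidence intervals bracket the point estimate", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    m <- matrix(rnorm(n * 2, 0, 1), n, 2) + rnorm(n, 0, runif(1, 0.2, 3))
    r <- icc21(m)
    expect_lte(r$ci95[1], r$icc + 1e-12)
    expect_gte(r$ci95[2], r$icc - 1e-12)
  }
})

test_that("ICC is invariant to affine transforms applied to both sessions", {
  set.seed(7)
  m <- matrix(rnorm(40, 5, 1), 20, 2) + rnorm(20)
  expect_equal(icc21(m)$icc, icc21(3.7 * m + 11)$icc, tolerance = 1e-12)
})

test_that("the ICC estimate converges to the analytic cohort value", {
  est <- vapply(1:20, function(s) {
    m <- generate_cohort(cohort_spec(200, between_subject_sd = 1,
                                     within_subject_sd = 0.5,
                                     rng_seed = 900 + s))
    icc21(m)$icc
  }, 0)
  expect_lt(abs(mean(est) - 0.8), 0.02)
})

test_that("SEM, MDC and rMDC satisfy their closed forms", {
  r <- sem_mdc_rmdc(1, c(1, 2, 3, 4))
  expect_equal(c(r$sem, r$mdc, r$rmdc), c(0, 0, 0))

  # with icc = 0.5 and sd = 2: sem = 1.4142, mdc = 3.9199, rmdc = 1.9600
  set.seed(1); vals <- rnorm(100)
  vals <- (vals - mean(vals)) / sd(vals) * 2
  r2 <- sem_mdc_rmdc(0.5, vals)
  expect_equal(r2$sem, 1.4142, tolerance = 1e-4)
  expect_equal(r2$mdc, 3.9199, tolerance = 1e-4)
  expect_equal(r2$rmdc, 1.9600, tolerance = 1e-4)

  r3 <- sem_mdc_rmdc(0, vals)
  expect_equal(r3$rmdc, 1.96 * sqrt(2), tolerance = 1e-12)

  r4 <- sem_mdc_rmdc(-0.2, vals)
  expect_true(is.na(r4$sem))
  expect_identical(r4$flag, "sem_suppressed")

  r5 <- sem_mdc_rmdc(0.5, rep(3, 10))
  expect_true(is.na(r5$rmdc))
  expect_identical(sem_mdc_rmdc(0.5, NULL)$flag, "insufficient_observations")
})

test_that("ICC classification bands are lower-inclusive", {
  expect_identical(classify_icc(c(0.49, 0.5, 0.74, 0.75, 0.8, 0.89, 0.9,
                                  0.95, -0.3)),
                   c("poor", "moderate", "moderate", "good", "good", "good",
                     "excellent", "excellent", "poor"))
})

test_that("the reliability table summarises a cohort feature-wise", {
  set.seed(3)
  n <- 20
  s1 <- data.frame(subject_id = sprintf("S%02d", 1:n))
  s2 <- s1
  subj <- rnorm(n, 10, 2)
  s1$noisefree <- subj; s2$noisefree <- subj
  s1$noisy <- subj + rnorm(n, 0, 2); s2$noisy <- subj + rnorm(n, 0, 2)
  s1$half <- c(subj[1:8], rep(NA, n - 8))
  s2$half <- s1$half
  tab <- reliability_table(s1, s2, catalogue = NULL)
  expect_identical(tab$icc[tab$feature == "noisefree"], 1)
  expect_identical(tab$icc_class[tab$feature == "noisefree"], "excellent")
  expect_lt(tab$icc[tab$feature == "noisy"], 1)
  expect_identical(tab$flag[tab$feature == "half"], "insufficient_data")
  expect_identical(attr(tab, "summary")$n_features, 3L)

  expect_error(reliability_table(s1[0, ], s2, catalogue = NULL),
               class = "gaitreliab_reliability_error")
  s3 <- s2; s3$subject_id <- paste0("X", s3$subject_id)
  expect_error(reliability_table(s1, s3, catalogue = NULL),
               "no paired subjects",
               class = "gaitreliab_reliability_error")
})
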