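test_that("duplicate columns give perfect agreement", {
  m <- cbind(c(0.1, 0.2, 0.3, 0.25, 0.18, 0.31),
             c(0.1, 0.2, 0.3, 0.25, 0.18, 0.31))
  fit <- icc_two_way_random_single(m)
  expect_equal(fit$icc, 1)
  expect_equal(sem_from_anova(fit), 0)
  expect_equal(minimal_difference(sem_from_anova(fit)), 0)
})

test_that("independent noise columns give ICC near zero", {
  m <- with(list(), {
    set.seed(14)
    matrix(rnorm(400), 200, 2)
  })
  fit <- icc_two_way_random_single(m)
  expect_lt(abs(fit$icc), 0.15)
})

test_that("ANOVA and ICC match the brute-force oracle to 1e-10", {
  set.seed(55)
  for (dims in list(c(6, 2), c(7, 2), c(8, 3), c(10, 3))) {
    for (rep in 1:3) {
      m <- matrix(sample.int(40, prod(dims), replace = TRUE), dims[1], dims[2])
      fit <- icc_two_way_random_single(m)
      oracle <- anova_oracle(m)
      expect_equal(fit$anova$ms_subjects, oracle$ms_subjects, tolerance = 1e-10)
      expect_equal(fit$anova$ms_raters, oracle$ms_raters, tolerance = 1e-10)
      expect_equal(fit$anova$ms_error, oracle$ms_error, tolerance = 1e-10)
      expect_equal(fit$icc, oracle$icc_a1, tolerance = 1e-10)
    }
  }
})

test_that("ICC and CI match an independent reference implementation", {
  ## expected values frozen from an external ICC implementation
  ## (two-way random effects, single measures) on these matrices
  m1 <- matrix(c(0.2548, 0.2608, 0.27, 0.249, 0.2145, 0.2462, 0.1195, 0.1561,
                 0.142, 0.1704, 0.0955, 0.1537, 0.2074, 0.2636, 0.3653, 0.365,
                 0.1202, 0.1895, 0.1827, 0.1976), ncol = 2, byrow = TRUE)
  a <- icc_two_way_random_single(m1)
  expect_equal(a$icc, 0.8726222385, tolerance = 1e-9)
  expect_equal(round(unname(a$ci95), 2), c(0.30, 0.97))
  cc <- icc_two_way_random_single(m1, type = "consistency")
  expect_equal(cc$icc, 0.9271924245, tolerance = 1e-9)
  expect_equal(round(unname(cc$ci95), 2), c(0.74, 0.98))

  m2 <- matrix(c(6.473, 7.35, 6.728, 9.096, 8.564, 8.805, 9.13, 7.305, 8.43,
                 8.478, 8.369, 9.683, 12.732, 11.662, 11.881, 8.846, 8.734,
                 8.631, 9.882, 10.969, 10.786, 11.228, 12.431, 11.098),
               ncol = 3, byrow = TRUE)
  b <- icc_two_way_random_single(m2)
  expect_equal(b$icc, 0.8941394182, tolerance = 1e-9)
  expect_equal(round(unname(b$ci95), 2), c(0.69, 0.98))
})

test_that("constant matrices yield a defined 'undefined' result", {
  m <- matrix(0.24, 5, 2)
  fit <- icc_two_way_random_single(m)
  expect_true(fit$undefined)
  expect_true(is.na(fit$icc))
})

test_that("ICC is affine invariant; SEM scales with the data", {
  set.seed(77)
  m <- matrix(rnorm(24, 10, 2), 12, 2)
  m[, 2] <- m[, 2] + 0.4   # rater offset
  a <- icc_two_way_random_single(m)
  b <- icc_two_way_random_single(3 + 2.5 * m)
  expect_equal(b$icc, a$icc, tolerance = 1e-12)
  expect_equal(sem_from_anova(b), 2.5 * sem_from_anova(a), tolerance = 1e-12)
  expect_equal(minimal_difference(2), 2 * 1.96 * sqrt(2))
})

test_that("SEM round-trips the printed reliability arithmetic", {
  ## pooled SD 0.09 with SEM 0.024 implies ICC = 1 - (0.024/0.09)^2 = 0.93
  icc_implied <- 1 - (0.024 / 0.09)^2
  expect_equal(round(icc_implied, 2), 0.93)
  sem <- sem_from_anova(list(pooled_sd = 0.09), method = "sd_icc",
                        icc = icc_implied)
  expect_equal(sem, 0.024, tolerance = 1e-12)
  expect_error(sem_from_anova(list(pooled_sd = 0.09), method = "sd_icc"),
               "icc")
})

test_that("estimated SEM recovers the generating error SD", {
  mod <- observer_model(between_subject_sd = 0.09, error_sd = 0.02)
  sems <- vapply(1:500, function(i) {
    m <- generate_observation_matrix(mod, 30, 2, seed = 40000 + i)
    sem_from_anova(icc_two_way_random_single(m))
  }, 1)
  expect_equal(mean(sems), 0.02, tolerance = 0.05)   # bias < 5%
})

test_that("qualitative categories follow the published bands", {
  expect_equal(categorize_icc(c(0.55, 0.78, 0.90, 0.93)),
               c("fair", "moderate", "substantial", "substantial"))
  ## inclusive upper edges and the below-slight region
  expect_equal(categorize_icc(c(0.40, 0.60, 0.80, 1.00)),
               c("slight", "fair", "moderate", "substantial"))
  expect_equal(categorize_icc(c(0.05, -0.3, 0.11)),
               c("below-slight", "below-slight", "slight"))
  expect_error(categorize_icc(1.2))
})

test_that("the 95% CI covers the population ICC at nominal rate", {
  mod <- observer_model(0.0867, 0.024)
  pop <- population_icc(mod)
  cover <- vapply(1:600, function(i) {
    m <- generate_observation_matrix(mod, 30, 2, seed = 60000 + i)
    ci <- icc_two_way_random_single(m)$ci95
    ci[1] <= pop && pop <= ci[2]
  }, TRUE)
  ## nominal 95%, allowing Monte-Carlo error (SE ~ 0.9% at 600 reps) and
  ## the interval's slight conservatism
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.985)
})

test_that("repeatability report assembles pairings, stats and plots", {
  set.seed(10)
  subj <- rnorm(12, 0.24, 0.09)
  readings <- list(
    msi = cbind(AxB = subj + rnorm(12, 0, 0.02),
                DT1 = subj + rnorm(12, 0, 0.02),
                DT2 = subj + rnorm(12, 0, 0.02)),
    msv = cbind(AxB = rnorm(12, 0.07, 0.03), DT1 = rnorm(12, 0.07, 0.03),
                DT2 = rnorm(12, 0.07, 0.03)))
  rownames(readings$msi) <- rownames(readings$msv) <- sprintf("S%02d", 1:12)
  outdir <- withr::local_tempdir()
  rep <- repeatability_report(readings, outdir = outdir)
  expect_s3_class(rep, "repeatability_report")
  expect_equal(nrow(rep$group_stats), 6L)        # 2 biomarkers x 3 readers
  expect_equal(nrow(rep$table), 4L)              # 2 biomarkers x 2 pairings
  expect_true(all(file.exists(rep$plots)))
  ## SEM as percent of the group mean: 0.024 on a mean of 0.24 is 10%
  r <- rep$results$msi$intra
  expect_equal(r$sem_pct, 100 * r$sem / r$grand_mean)
  expect_equal(round(100 * 0.024 / 0.24), 10)

  ## identical reading sets: perfect agreement
  same <- list(msi = readings$msi[, c(1, 1)])
  colnames(same$msi) <- c("DT1", "DT2")
  perfect <- repeatability_report(same, pairings = list(intra = c("DT1", "DT2")))
  expect_equal(perfect$results$msi$intra$icc, 1)
  expect_equal(perfect$results$msi$intra$sem, 0)

  ## mismatched subject sets across raters error
  long <- data.frame(subject = c("a", "b", "a"), rater = c("R1", "R1", "R2"),
                     biomarker = "msi", value = c(1, 2, 1.1))
  expect_error(repeatability_report(long, pairings = list(x = c("R1", "R2"))),
               "differ")

  ## unknown rater in a pairing
  expect_error(repeatability_report(readings,
                                    pairings = list(p = c("AxB", "ZZ"))),
               "ZZ")
})
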