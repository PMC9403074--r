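test_that("perfect duplicate columns give ICC exactly 1", {
  m <- cbind(c(3.1, 3.5, 4.0, 4.4, 5.2), c(3.1, 3.5, 4.0, 4.4, 5.2))
  for (form in c("ICC_2_1_agreement", "ICC_1_1", "ICC_3_1_consistency")) {
    res <- icc(repeatability_table(m), form)
    expect_identical(res$estimate, 1)
  }
})

test_that("ICC formulas reproduce brute-force ANOVA mean squares on a hand table", {
  m <- cbind(c(3.2, 4.1, 2.8, 5.0, 3.6),
             c(3.4, 4.0, 3.1, 5.3, 3.5))
  n <- nrow(m); k <- ncol(m)
  ms <- aov_mean_squares(m)
  res <- icc(repeatability_table(m), "ICC_2_1_agreement")
  expect_equal(res$ms$msr, ms$msr, tolerance = 1e-10)
  expect_equal(res$ms$msc, ms$msc, tolerance = 1e-10)
  expect_equal(res$ms$mse, ms$mse, tolerance = 1e-10)
  oracle_21 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  expect_equal(res$estimate, oracle_21, tolerance = 1e-10)

  res11 <- icc(repeatability_table(m), "ICC_1_1")
  oracle_11 <- (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw)
  expect_equal(res11$estimate, oracle_11, tolerance = 1e-10)

  res31 <- icc(repeatability_table(m), "ICC_3_1_consistency")
  oracle_31 <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  expect_equal(res31$estimate, oracle_31, tolerance = 1e-10)
})

test_that("a constant rater offset hurts agreement but not consistency", {
  base <- c(3.2, 4.1, 2.8, 5.0, 3.6, 4.4, 2.9, 3.8)
  prev <- 1
  for (delta in c(0.1, 0.3, 0.6)) {
    m <- cbind(base, base + delta)
    agree <- icc(repeatability_table(m), "ICC_2_1_agreement")$estimate
    consist <- icc(repeatability_table(m), "ICC_3_1_consistency")$estimate
    expect_lt(agree, prev)
    expect_identical(consist, 1)
    prev <- agree
  }
})

test_that("ICC is invariant to shift and positive scaling, and stays in range", {
  set.seed(314)
  m <- matrix(rnorm(40, 4, 0.5), 20, 2) + rnorm(20, 0, 0.3)
  base <- icc(repeatability_table(m), "ICC_2_1_agreement")$estimate
  expect_equal(icc(repeatability_table(m + 7))$estimate, base, tolerance = 1e-12)
  expect_equal(icc(repeatability_table(m * 3.5))$estimate, base, tolerance = 1e-12)
  for (i in 1:25) {
    mm <- matrix(rnorm(30, 0, runif(1, 0.1, 2)), 10, 3) +
      rnorm(10, 0, runif(1, 0, 2))
    for (form in c("ICC_2_1_agreement", "ICC_1_1", "ICC_3_1_consistency")) {
      est <- icc(repeatability_table(mm), form)$estimate
      expect_gte(est, -1 / (3 - 1))
      expect_lte(est, 1)
    }
  }
})

test_that("ICC(1,1) recovers the variance-component ratio", {
  # subject SD 0.3, error SD 0.1: true ICC = 0.09 / 0.10 = 0.9
  set.seed(271)
  est20 <- replicate(200, {
    s <- rnorm(20, 5, 0.3)
    m <- cbind(s + rnorm(20, 0, 0.1), s + rnorm(20, 0, 0.1))
    res <- icc(repeatability_table(m), "ICC_1_1")
    res$ci[1] <= 0.9 && 0.9 <= res$ci[2]
  })
  expect_gte(mean(est20), 0.90)   # CI coverage near nominal

  est200 <- replicate(500, {
    s <- rnorm(200, 5, 0.3)
    m <- cbind(s + rnorm(200, 0, 0.1), s + rnorm(200, 0, 0.1))
    icc(repeatability_table(m), "ICC_1_1")$estimate
  })
  expect_lt(abs(mean(est200) - 0.9), 0.01)
})

test_that("degenerate tables are rejected with typed errors", {
  expect_error(repeatability_table(matrix(1:4, 4, 1)),
               class = "aortaz_degenerate_table")
  expect_error(repeatability_table(matrix(1:6, 3, 2)),
               class = "aortaz_insufficient_data")
  m <- matrix(1:10, 5, 2); m[2, 1] <- NA
  expect_error(repeatability_table(m), class = "aortaz_degenerate_table")
  expect_error(icc(matrix(5, 6, 2)), class = "aortaz_degenerate_table")
})

test_that("the repeatability report covers all cells and survives bad ones", {
  dup <- matrix(rep(c(3.1, 3.5, 4.0, 4.4, 5.2), 2), 5, 2)
  tables <- list(
    intra_dmax = repeatability_table(dup, "intraobserver"),
    inter_dmax = repeatability_table(dup, "interobserver"),
    broken = matrix(1:5, 5, 1)
  )
  rep <- repeatability_report(tables)
  expect_identical(nrow(rep), 3L)
  expect_equal(rep$estimate[1:2], c(1, 1))
  expect_identical(rep$form[1:2], c("ICC_1_1", "ICC_2_1_agreement"))
  expect_true(is.na(rep$estimate[3]) && !is.na(rep$error[3]))
})

test_that("study-like synthetic repeatability lands in the published ICC range", {
  labels <- expand.grid(design = c("intraobserver", "interobserver"),
                        parameter = c("dmax", "dmin", "dd"),
                        stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(labels)), function(i) {
    simulate_repeatability(n_subjects = 20, k = 2,
                           design = labels$design[i],
                           parameter = labels$parameter[i],
                           seed = 400 + i)
  })
  names(tables) <- paste(labels$design, labels$parameter, sep = ".")
  rep <- repeatability_report(tables)
  expect_true(all(is.na(rep$error)))
  expect_true(all(rep$estimate >= 0.85 & rep$estimate <= 1))
})
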