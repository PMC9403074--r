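test_that("noiseless polynomial data are recovered exactly", {
  x <- seq(18, 40, length.out = 60)
  y <- 1 + 2 * x - 0.5 * x^2
  fit <- fit_mean_model(x, y, c(1, 2))
  expect_equal(fit$terms$coefficient, c(1, 2, -0.5), tolerance = 1e-9)
  expect_equal(fit$fit_stats$R, 1, tolerance = 1e-9)

  yc <- rep(3.7, 60)
  fitc <- fit_mean_model(x, yc, c(1, 2))
  expect_equal(fitc$terms$coefficient[1], 3.7, tolerance = 1e-9)
  expect_equal(fitc$terms$coefficient[-1], c(0, 0), tolerance = 1e-9)
})

test_that("fitting guards reject unusable designs", {
  expect_error(fit_mean_model(1:3, 1:3, c(1, 2, 3)),
               class = "aortaz_insufficient_data")
  expect_error(fit_mean_model(rep(2, 30), rnorm(30), 1),
               class = "aortaz_singular_fit")
  expect_error(fit_mean_model(1:10, 1:9, 1), class = "aortaz_insufficient_data")
})

test_that("model selection breaks exact ties toward fewer terms and lower degree", {
  x <- seq(18, 40, length.out = 80)
  y <- 2 + 0.3 * x                     # exactly linear, zero noise
  cfg <- fit_config(candidate_term_sets = list(1, c(1, 2, 3)))
  best <- select_best_model(x, y, cfg)
  expect_identical(best$terms$power, c(0, 1))

  # candidate too large for n is skipped, not fatal
  x5 <- c(18, 22, 26, 30, 34)
  y5 <- 1 + 0.1 * x5
  cfg2 <- fit_config(candidate_term_sets = list(1, c(1, 2, 3)))
  best2 <- select_best_model(x5, y5, cfg2)
  expect_identical(best2$terms$power, c(0, 1))
  expect_error(select_best_model(rep(1, 20), rnorm(20)), class = "aortaz_no_model")
})

test_that("selection detects a quadratic truth and usually rejects a spurious cubic", {
  # symmetric predictor range keeps even and odd powers near-orthogonal, so
  # the quadratic support is identifiable
  set.seed(731)
  res <- t(replicate(60, {
    x <- runif(300, -2, 2)
    y <- 1 + 0.1 * x + 0.5 * x^2 + rnorm(300, 0, 0.2)
    best <- select_best_model(x, y)
    c(has2 = 2 %in% best$terms$power, no3 = !(3 %in% best$terms$power))
  }))
  # curvature is always detected; a pure-noise cubic term sneaks into an
  # adjusted-R2 winner whenever its |t| exceeds 1 (~1/3 of samples), so its
  # exclusion rate sits near the theoretical ~68%
  expect_gte(mean(res[, "has2"]), 0.95)
  expect_gte(mean(res[, "no3"]), 0.5)
})

test_that("selected model's adjusted R2 dominates every candidate's", {
  co <- simulate_cohort(490, seed = 31)
  cfg <- fit_config()
  best <- select_best_model(co$ga, co$dmax, cfg)
  for (set in cfg$candidate_term_sets) {
    f <- fit_mean_model(co$ga, co$dmax, set)
    expect_gte(best$fit_stats$adj_r2, f$fit_stats$adj_r2 - 1e-10)
  }
})

test_that("binned SD regression recovers homoscedastic and heteroscedastic truth", {
  set.seed(11)
  x <- runif(2000, 18, 40)
  fs <- fit_sd_model(x, rnorm(2000, 0, 0.4))
  expect_lt(abs(fs$terms$coefficient[2]), 0.01)       # slope ~ 0
  expect_lt(abs(fs$terms$coefficient[1] - 0.4), 0.05) # intercept ~ 0.4

  set.seed(12)
  x <- runif(2000, 18, 40)
  fs2 <- fit_sd_model(x, rnorm(2000, 0, 0.026 * x - 0.227))
  rel <- (fs2$terms$coefficient - c(-0.227, 0.026)) / c(-0.227, 0.026)
  expect_lt(max(abs(rel)), 0.10)
})

test_that("the absolute-residual SD method agrees with binning", {
  co <- simulate_cohort(5000, seed = 77)
  fm <- fit_mean_model(co$ga, co$dmax, c(1, 2))
  res <- co$dmax - evaluate_poly(fm, co$ga)
  b <- fit_sd_model(co$ga, res, fit_config(sd_method = "binned"))
  a <- fit_sd_model(co$ga, res, fit_config(sd_method = "absolute_residual"))
  rel <- abs(a$terms$coefficient - b$terms$coefficient) /
    abs(b$terms$coefficient)
  expect_lt(max(rel), 0.15)
})

test_that("degenerate residual structures raise typed SD-fit errors", {
  x <- runif(200, 18, 40)
  expect_error(fit_sd_model(x, rep(0, 200)), class = "aortaz_non_positive_sd")
  expect_error(fit_sd_model(x[1:20], rnorm(20), fit_config(min_bin_count = 50)),
               class = "aortaz_insufficient_bins")
  expect_error(fit_sd_model(1:3, rnorm(3)), class = "aortaz_insufficient_data")
})

test_that("the full pipeline self-standardises its training cohort", {
  co <- simulate_cohort(490, seed = 19)
  fit <- build_reference_chart(co, "Dmax", "GA")
  expect_lt(abs(mean(fit$zscores$z)), 0.1)
  expect_lt(abs(sd(fit$zscores$z) - 1), 0.1)

  big <- simulate_cohort(5000, seed = 20)
  fitb <- build_reference_chart(big, "Dmax", "GA")
  expect_lt(abs(mean(fitb$zscores$z)), 0.05)
  expect_lt(abs(sd(fitb$zscores$z) - 1), 0.05)
})

test_that("chart construction is deterministic and duplication-invariant", {
  co <- simulate_cohort(300, seed = 4)
  f1 <- build_reference_chart(co, "DD", "GA")
  f2 <- build_reference_chart(co, "DD", "GA")
  expect_identical(f1$chart, f2$chart)

  # OLS mean fit is exactly invariant to duplicating the full design; the
  # per-bin SD estimator is not (its n-1 denominator sees doubled bins), so
  # the SD coefficients agree only closely
  doubled <- rbind(co, co)
  fd <- build_reference_chart(doubled, "DD", "GA")
  expect_equal(fd$chart$mean_model$terms, f1$chart$mean_model$terms,
               tolerance = 1e-9)
  expect_equal(fd$chart$sd_model$terms$coefficient,
               f1$chart$sd_model$terms$coefficient, tolerance = 0.05)
})

test_that("cohorts too small or too degenerate are refused", {
  co <- simulate_cohort(10, seed = 1)
  expect_error(build_reference_chart(co, "Dmax", "GA"),
               class = "aortaz_insufficient_data")
})

test_that("fit configuration is validated", {
  expect_error(fit_config(min_bin_count = 1), class = "aortaz_config_error")
  cfg <- fit_config(candidate_term_sets = list(c(2, 1)))
  expect_identical(cfg$candidate_term_sets[[1]], c(0L, 1L, 2L))
})
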