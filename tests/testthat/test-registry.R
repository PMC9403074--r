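test_that("the registry holds all nine response-predictor charts", {
  for (variant in c("sanitized", "as_printed")) {
    reg <- published_registry(variant)
    keys <- as.vector(outer(c("Dmax", "Dmin", "DD"), c("GA", "BPD", "FL"),
                            paste, sep = "~"))
    expect_setequal(names(reg), keys)
    expect_true(all(vapply(reg, inherits, logical(1), "aortaz_chart")))
  }
})

test_that("as-printed coefficients match the published equations", {
  reg <- published_registry("as_printed")
  dmax_ga <- reg[["Dmax~GA"]]
  expect_equal(dmax_ga$mean_model$terms,
               data.frame(power = c(0, 1, 2),
                          coefficient = c(-2.99, 0.32, -2.14e-3)))
  expect_equal(dmax_ga$sd_model$terms,
               data.frame(power = c(0, 1), coefficient = c(-0.227, 0.026)))
  expect_equal(predict_mean(dmax_ga, 24), 3.45736, tolerance = 1e-12)
  expect_equal(predict_sd(dmax_ga, 24), 0.397, tolerance = 1e-12)
  # DD SD against GA, as printed, gives ~0.134 at 24 weeks
  expect_equal(evaluate_poly(reg[["DD~GA"]]$sd_model, 24), 0.13388,
               tolerance = 1e-12)
  expect_identical(dmax_ga$mean_model$provenance, "published_as_printed")
})

test_that("corrupt printed equations carry sanitized variants; intact ones do not", {
  san <- published_registry("sanitized")
  ap <- published_registry("as_printed")

  sanitized_keys_mean <- names(san)[vapply(san, function(ch)
    ch$mean_model$provenance == "published_sanitized", logical(1))]
  sanitized_keys_sd <- names(san)[vapply(san, function(ch)
    ch$sd_model$provenance == "published_sanitized", logical(1))]
  expect_identical(sanitized_keys_mean, "Dmin~GA")
  expect_setequal(sanitized_keys_sd, c("DD~GA", "DD~BPD"))

  # the corrupt printed forms are retained verbatim on the sanitized models
  expect_match(san[["Dmin~GA"]]$mean_model$printed, "-2.41\\*GA")
  # sanitized DD SD slopes are single decimal-shift corrections
  expect_equal(san[["DD~GA"]]$sd_model$terms$coefficient, c(0.140, -2.55e-3))
  expect_equal(san[["DD~BPD"]]$sd_model$terms$coefficient, c(0.131, -8.040e-4))
  # ... and restore the worked example's effective SD ~0.08 at 24 weeks
  expect_equal(evaluate_poly(san[["DD~GA"]]$sd_model, 24), 0.0788,
               tolerance = 1e-12)

  # everything untouched is identical across variants
  for (key in setdiff(names(san), c("Dmin~GA", "DD~GA", "DD~BPD"))) {
    expect_identical(san[[key]]$mean_model$terms, ap[[key]]$mean_model$terms)
    expect_identical(san[[key]]$sd_model$terms, ap[[key]]$sd_model$terms)
  }
})

test_that("the as-printed Dmin~GA mean and DD~BPD SD are unusable, as published", {
  ap <- published_registry("as_printed")
  ga <- seq(18, 40, by = 0.5)
  expect_true(all(evaluate_poly(ap[["Dmin~GA"]]$mean_model, ga) < 0))
  expect_error(predict_sd(ap[["DD~BPD"]], 60), class = "aortaz_chart_domain")
})

test_that("sanitized Dmin~GA mean tracks Dmax/(1 + DD) from the intact equations", {
  san <- published_registry("sanitized")
  ga <- seq(18, 40, by = 0.25)
  ratio <- evaluate_poly(san[["Dmax~GA"]]$mean_model, ga) /
    (1 + evaluate_poly(san[["DD~GA"]]$mean_model, ga))
  expect_lt(max(abs(evaluate_poly(san[["Dmin~GA"]]$mean_model, ga) - ratio)),
            0.01)
})

test_that("sanitized SD models are strictly positive over their supported ranges", {
  san <- published_registry("sanitized")
  for (key in names(san)) {
    ch <- san[[key]]
    grid <- seq(ch$range[1], ch$range[2], length.out = 301)
    expect_true(all(evaluate_poly(ch$sd_model, grid) > 0), label = key)
  }
})

test_that("sanitized diameters grow and distensibility falls across gestation", {
  san <- published_registry("sanitized")
  for (key in names(san)) {
    ch <- san[[key]]
    grid <- seq(ch$range[1], ch$range[2], length.out = 301)
    d <- diff(evaluate_poly(ch$mean_model, grid))
    if (ch$response == "DD") {
      expect_true(all(d < 0), label = paste(key, "decreasing"))
    } else {
      expect_true(all(d > 0), label = paste(key, "increasing"))
    }
  }
})

test_that("charts round-trip through JSON exactly", {
  san <- published_registry("sanitized")
  path <- withr::local_tempfile(fileext = ".json")
  for (key in c("Dmax~GA", "Dmin~GA", "DD~BPD")) {
    write_chart_json(san[[key]], path)
    back <- read_chart_json(path)
    expect_identical(back$mean_model$terms, san[[key]]$mean_model$terms,
                     label = key)
    expect_identical(back$sd_model$terms, san[[key]]$sd_model$terms)
    expect_identical(back$range, san[[key]]$range)
    expect_identical(back$mean_model$provenance, san[[key]]$mean_model$provenance)
  }
  # fitted charts keep their fit statistics through the round trip
  co <- simulate_cohort(200, seed = 5)
  fit <- build_reference_chart(co, "Dmax", "GA")
  write_chart_json(fit$chart, path)
  back <- read_chart_json(path)
  expect_identical(back$mean_model$terms, fit$chart$mean_model$terms)
  expect_equal(back$mean_model$fit_stats$R, fit$chart$mean_model$fit_stats$R)
})
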