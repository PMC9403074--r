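# Independent oracles and small fixture builders used across test files.

# ANOVA mean squares computed through stats::aov, independently of the
# package's own sums-of-squares arithmetic.  Row order in the aov table is
# subject, rater, residuals.
aov_mean_squares <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  two_way <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  one_way <- summary(stats::aov(y ~ subject, data = df))[[1]]
  list(
    msr = two_way[1, "Mean Sq"],
    msc = two_way[2, "Mean Sq"],
    mse = two_way[3, "Mean Sq"],
    msw = one_way[2, "Mean Sq"]
  )
}

# A chart with constant mean and SD (intercept-only models), handy for
# scoring tests where mean and SD at the predictor value are given.
constant_chart <- function(mean, sd, response = "DD", predictor = "GA",
                           range = c(18, 40)) {
  reference_chart(
    response,
    poly_model(predictor, 0, mean, provenance = "published_sanitized"),
    poly_model(predictor, 0, sd, provenance = "published_sanitized"),
    range = range
  )
}

# Rescale a chart's response units by a positive factor (fraction <-> percent).
scale_chart <- function(chart, factor) {
  scale_poly <- function(m) {
    poly_model(m$predictor, m$terms$power, m$terms$coefficient * factor,
               provenance = m$provenance, fit_stats = m$fit_stats)
  }
  reference_chart(chart$response, scale_poly(chart$mean_model),
                  scale_poly(chart$sd_model), range = chart$range)
}
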