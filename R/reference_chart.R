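#' Reference chart: paired mean and SD models
#'
#' A reference chart couples a mean model and an SD model for one response
#' (`Dmax`, `Dmin` or `DD`) against one predictor, together with the
#' predictor range over which the chart is supported.  Z-scores and
#' percentile curves are derived from the pair under the Gaussian
#' assumption: `response | x ~ N(mean(x), sd(x))`.
#'
#' @param response One of `"Dmax"`, `"Dmin"`, `"DD"`.
#' @param mean_model,sd_model [poly_model()] objects sharing the same
#'   predictor.
#' @param range Length-2 numeric `(lo, hi)` in predictor units.
#' @param validate If `TRUE` (default) the SD model is checked to be strictly
#'   positive on a dense grid over `range`; construction fails with a
#'   chart-domain error otherwise.  Set `FALSE` only to hold a published
#'   equation known to be typographically corrupt for inspection.
#'
#' @return An object of class `aortaz_chart`.
#' @export
reference_chart <- function(response, mean_model, sd_model, range,
                            validate = TRUE) {
  response <- match.arg(response, c("Dmax", "Dmin", "DD"))
  stopifnot(inherits(mean_model, "aortaz_poly"), inherits(sd_model, "aortaz_poly"))
  if (mean_model$predictor != sd_model$predictor) {
    stop_typed("malformed_model",
               "mean and SD models must share one predictor")
  }
  range <- as.numeric(range)
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    stop_typed("malformed_model", "range must be finite (lo, hi) with lo < hi")
  }
  chart <- structure(
    list(response = response, mean_model = mean_model, sd_model = sd_model,
         range = range),
    class = "aortaz_chart"
  )
  if (validate) {
    grid <- seq(range[1], range[2], length.out = 201L)
    if (any(evaluate_poly(sd_model, grid) <= 0)) {
      stop_typed("chart_domain",
                 sprintf("SD model for %s~%s is not strictly positive over [%g, %g]",
                         response, sd_model$predictor, range[1], range[2]))
    }
  }
  chart
}

#' @export
print.aortaz_chart <- function(x, ...) {
  cat(sprintf("<reference_chart> %s ~ %s on [%g, %g]\n",
              x$response, x$mean_model$predictor, x$range[1], x$range[2]))
  cat("  mean: Y =", poly_formula(x$mean_model), "\n")
  cat("  sd:   Y =", poly_formula(x$sd_model), "\n")
  invisible(x)
}

#' Predicted mean and SD at a predictor value
#'
#' `predict_mean()` evaluates the chart's mean model; `predict_sd()` its SD
#' model.  Values outside the supported range raise an extrapolation warning
#' but still return a number (a clinical calculator must not refuse to
#' answer); a non-positive predicted SD raises a chart-domain error, since a
#' Z-score is undefined there.
#'
#' @param chart A [reference_chart()].
#' @param x Predictor values.
#' @return Numeric vector in response units.
#' @export
predict_mean <- function(chart, x) {
  check_chart_range(chart, x)
  evaluate_poly(chart$mean_model, x)
}

#' @rdname predict_mean
#' @export
predict_sd <- function(chart, x) {
  check_chart_range(chart, x)
  sd <- evaluate_poly(chart$sd_model, x)
  if (any(sd <= 0)) {
    stop_typed("chart_domain",
               sprintf("predicted SD <= 0 for %s~%s: predictor outside the validated range or corrupt coefficients",
                       chart$response, chart$sd_model$predictor))
  }
  sd
}

check_chart_range <- function(chart, x) {
  x <- as.numeric(x)
  out <- is.finite(x) & (x < chart$range[1] | x > chart$range[2])
  if (any(out)) {
    warn_typed("extrapolation",
               sprintf("%d predictor value(s) outside the supported %s range [%g, %g]; extrapolating",
                       sum(out), chart$mean_model$predictor,
                       chart$range[1], chart$range[2]))
  }
  invisible(any(out))
}

# 90% reference band threshold as printed in the source charts (the exact
# 95th standard-normal quantile, 1.6449, is used for percentile curves; the
# rounded 1.65 defines the clinical band).
BAND_Z <- 1.65

#' Z-score of an observation against predicted mean and SD
#'
#' `z = (observed - predicted_mean)/predicted_sd`.  `|z| > 1.65` (strict)
#' flags the observation outside the central 90% reference band.
#'
#' @param observed,predicted_mean,predicted_sd Numeric vectors in response
#'   units (recycled to common length); `predicted_sd` must be positive.
#' @return A data.frame of class `aortaz_zscore` with columns `observed`,
#'   `predicted_mean`, `predicted_sd`, `z`, `band_flag`
#'   (`"within_90"`/`"outside_90"`).
#' @examples
#' zscore(0.105, 0.344, 0.0816)  # z = -2.93, outside_90
#' @export
zscore <- function(observed, predicted_mean, predicted_sd) {
  n <- max(length(observed), length(predicted_mean), length(predicted_sd))
  observed <- rep_len(as.numeric(observed), n)
  predicted_mean <- rep_len(as.numeric(predicted_mean), n)
  predicted_sd <- rep_len(as.numeric(predicted_sd), n)
  if (any(!is.finite(predicted_sd)) || any(predicted_sd <= 0)) {
    stop_typed("invalid_sd", "predicted_sd must be positive and finite")
  }
  z <- (observed - predicted_mean) / predicted_sd
  structure(
    data.frame(
      observed = observed,
      predicted_mean = predicted_mean,
      predicted_sd = predicted_sd,
      z = z,
      band_flag = ifelse(abs(z) > BAND_Z, "outside_90", "within_90"),
      stringsAsFactors = FALSE
    ),
    class = c("aortaz_zscore", "data.frame")
  )
}

#' Score one biometry record against a registry chart
#'
#' Looks up the `(response, predictor)` chart, evaluates predicted mean and
#' SD at the record's predictor value, and standardises the observed
#' response.  The observed `DD` is taken from the record's `dd` column if
#' present, otherwise derived from `dmax`/`dmin`.
#'
#' @param record A one-row data.frame or named list with (lowercase) fields
#'   `ga`, `bpd`, `fl`, `dmax`, `dmin`, `dd` as available.
#' @param response,predictor Chart selection.
#' @param registry A chart registry as returned by [published_registry()],
#'   or any named list of charts keyed `"<response>~<predictor>"`.
#' @return A one-row `aortaz_zscore` data.frame with additional columns
#'   `response`, `predictor`, `x` and `extrapolated`.
#' @export
score_record <- function(record, response, predictor,
                         registry = published_registry()) {
  response <- match.arg(response, c("Dmax", "Dmin", "DD"))
  predictor <- match.arg(predictor, c("GA", "BPD", "FL"))
  key <- paste0(response, "~", predictor)
  chart <- registry[[key]]
  if (is.null(chart)) {
    stop_typed("unknown_chart", sprintf("no chart '%s' in the registry", key))
  }
  x <- record[[tolower(predictor)]]
  if (is.null(x) || length(x) != 1L || !is.finite(x)) {
    stop_typed("incomplete_record",
               sprintf("record carries no usable %s value", predictor))
  }
  obs <- observed_response(record, response)
  extrapolated <- withCallingHandlers(
    check_chart_range(chart, x),
    aortaz_extrapolation = function(w) invokeRestart("muffleWarning")
  )
  if (extrapolated) {
    warn_typed("extrapolation",
               sprintf("%s = %g outside the supported range [%g, %g] of chart %s",
                       predictor, x, chart$range[1], chart$range[2], key))
  }
  res <- zscore(obs, evaluate_poly(chart$mean_model, x), predict_sd_quiet(chart, x))
  res$response <- response
  res$predictor <- predictor
  res$x <- x
  res$extrapolated <- extrapolated
  res
}

# predict_sd without a second extrapolation warning (already emitted)
predict_sd_quiet <- function(chart, x) {
  sd <- evaluate_poly(chart$sd_model, x)
  if (any(sd <= 0)) {
    stop_typed("chart_domain",
               sprintf("predicted SD <= 0 for chart %s~%s at x = %g",
                       chart$response, chart$sd_model$predictor, x[sd <= 0][1]))
  }
  sd
}

observed_response <- function(record, response) {
  col <- c(Dmax = "dmax", Dmin = "dmin", DD = "dd")[[response]]
  obs <- record[[col]]
  if ((is.null(obs) || !is.finite(obs)) && response == "DD") {
    if (!is.null(record$dmax) && !is.null(record$dmin)) {
      obs <- distensibility(record$dmax, record$dmin)
    }
  }
  if (is.null(obs) || length(obs) != 1L || !is.finite(obs)) {
    stop_typed("incomplete_record",
               sprintf("record carries no usable %s value", response))
  }
  obs
}

#' Percentile curves of a reference chart
#'
#' Evaluates `mean(x) + qnorm(p/100) * sd(x)` over a predictor grid for each
#' requested percentile, as used for the 5th/50th/95th reference lines
#' superimposed on a cohort scatter.  The 50th percentile curve is the mean
#' model itself.
#'
#' @param chart A [reference_chart()].
#' @param grid Predictor values (non-empty, within the supported range).
#' @param percentiles Percentiles in (0, 100); default `c(5, 50, 95)`.
#' @return A list of `aortaz_percentile_curve` objects (fields `percentile`,
#'   `grid`, `values`); `as.data.frame()` gives the long form.
#' @export
percentile_curves <- function(chart, grid, percentiles = c(5, 50, 95)) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) {
    stop_typed("empty_input", "percentile curves need a non-empty grid")
  }
  percentiles <- as.numeric(percentiles)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop_typed("empty_input", "percentiles must lie strictly in (0, 100)")
  }
  m <- predict_mean(chart, grid)
  s <- predict_sd_quiet(chart, grid)
  curves <- lapply(percentiles, function(p) {
    structure(
      list(percentile = p, grid = grid,
           values = m + stats::qnorm(p / 100) * s),
      class = "aortaz_percentile_curve"
    )
  })
  structure(curves, class = "aortaz_percentile_curves")
}

#' @export
as.data.frame.aortaz_percentile_curves <- function(x, ...) {
  do.call(rbind, lapply(x, function(cv) {
    data.frame(percentile = cv$percentile, x = cv$grid, value = cv$values)
  }))
}

#' @export
plot.aortaz_percentile_curves <- function(x, ylab = "response", xlab = "predictor", ...) {
  df <- as.data.frame(x)
  graphics::plot(range(df$x), range(df$value), type = "n",
                 xlab = xlab, ylab = ylab, ...)
  for (cv in x) {
    graphics::lines(cv$grid, cv$values, lty = if (cv$percentile == 50) 1 else 2)
  }
  invisible(x)
}
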