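#' Configuration for reference-chart fitting
#'
#' @param candidate_term_sets List of integer vectors of polynomial powers to
#'   try for the mean model; the intercept (power 0) is added to every set.
#'   Default: all non-empty subsets of powers 1-3, matching the heterogeneous
#'   published forms (linear, quadratic, cubic and mixed).
#' @param selection_criterion `"adjusted_R2"` (default) or `"AIC"`.
#' @param sd_method `"binned"` (default): group residuals by predictor bin,
#'   regress the per-bin SD on the bin centre, weighted by bin count.
#'   `"absolute_residual"`: regress `|residual|` on the predictor and scale
#'   by `sqrt(pi/2)` (the half-normal correction).
#' @param min_bin_count Bins with fewer residuals are dropped (default 5).
#' @param bin_width Width of predictor bins for the binned SD method;
#'   `NULL` (default) means 1 week for `GA` and 5 mm for `BPD`/`FL`.
#' @return A list of class `aortaz_fit_config`.
#' @export
fit_config <- function(candidate_term_sets = default_term_sets(),
                       selection_criterion = c("adjusted_R2", "AIC"),
                       sd_method = c("binned", "absolute_residual"),
                       min_bin_count = 5L,
                       bin_width = NULL) {
  selection_criterion <- match.arg(selection_criterion)
  sd_method <- match.arg(sd_method)
  if (min_bin_count < 2L) {
    stop_typed("config_error", "min_bin_count must be at least 2")
  }
  candidate_term_sets <- lapply(candidate_term_sets, function(s) {
    sort(unique(c(0L, as.integer(s))))
  })
  structure(
    list(candidate_term_sets = candidate_term_sets,
         selection_criterion = selection_criterion,
         sd_method = sd_method,
         min_bin_count = as.integer(min_bin_count),
         bin_width = bin_width),
    class = "aortaz_fit_config"
  )
}

#' @rdname fit_config
#' @export
default_term_sets <- function() {
  list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L))
}

#' Fit a polynomial mean model by ordinary least squares
#'
#' Step 1 of the chart construction: regress the response on the specified
#' powers of the predictor.  `fit_stats` on the returned model carries the
#' multiple correlation `R`, the overall-F `p` value, the per-power
#' coefficient standard errors `se`, adjusted R-squared and AIC.
#'
#' @param x,y Predictor and response vectors of equal length.
#' @param powers Integer powers to include; 0 (intercept) is always added.
#' @param predictor Predictor label for the resulting model.
#' @return A fitted [poly_model()].
#' @export
fit_mean_model <- function(x, y, powers, predictor = c("GA", "BPD", "FL")) {
  predictor <- match.arg(predictor)
  x <- as.numeric(x); y <- as.numeric(y)
  powers <- sort(unique(c(0L, as.integer(powers))))
  if (length(x) != length(y)) {
    stop_typed("insufficient_data", "x and y must have equal length")
  }
  if (length(x) < length(powers) + 2L) {
    stop_typed("insufficient_data",
               sprintf("need at least %d observations to fit %d terms",
                       length(powers) + 2L, length(powers)))
  }
  if (length(unique(x)) < 2L) {
    stop_typed("singular_fit", "predictor must take at least 2 distinct values")
  }
  X <- outer(x, powers, `^`)
  colnames(X) <- paste0("p", powers)
  fit <- stats::lm(y ~ X - 1)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop_typed("singular_fit", "rank-deficient polynomial design")
  }
  # noiseless fixtures fit exactly; the perfect-fit warning is not useful here
  sm <- suppressWarnings(summary(fit))
  # R and p in the role of the published tables' R and P columns: multiple
  # correlation of the fit and the overall-F p-value against intercept-only
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  k <- length(powers) - 1L            # non-intercept terms
  n <- length(y)
  p_val <- if (k > 0 && r2 < 1) {
    f <- (r2 / k) / ((1 - r2) / (n - k - 1L))
    stats::pf(f, k, n - k - 1L, lower.tail = FALSE)
  } else if (k > 0) 0 else NA_real_
  adj_r2 <- if (n - k - 1L > 0) 1 - (1 - r2) * (n - 1L) / (n - k - 1L) else -Inf
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- paste0("p", powers)
  poly_model(predictor, powers, unname(beta), provenance = "fitted",
             fit_stats = list(R = sqrt(max(r2, 0)), p = p_val, se = se,
                              adj_r2 = adj_r2, aic = stats::AIC(fit), n = n))
}

#' Select the best-fitting mean model among candidate term sets
#'
#' Fits every candidate set in the configuration and returns the winner by
#' the configured criterion (adjusted R-squared by default).  Ties are broken
#' toward fewer terms, then lower maximum power.  Candidates that cannot be
#' fitted (too few observations, rank deficiency) are skipped; if none can,
#' a no-model error is raised.
#'
#' @inheritParams fit_mean_model
#' @param config A [fit_config()].
#' @return The winning fitted [poly_model()].
#' @export
select_best_model <- function(x, y, config = fit_config(),
                              predictor = c("GA", "BPD", "FL")) {
  predictor <- match.arg(predictor)
  fits <- list()
  for (set in config$candidate_term_sets) {
    f <- tryCatch(fit_mean_model(x, y, set, predictor), aortaz_error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) {
    stop_typed("no_model", "no candidate term set could be fitted")
  }
  crit <- vapply(fits, function(f) {
    if (config$selection_criterion == "adjusted_R2") f$fit_stats$adj_r2
    else -f$fit_stats$aic
  }, numeric(1))
  best <- max(crit)
  tied <- which(crit >= best - 1e-10)
  nt <- vapply(fits[tied], poly_nterms, numeric(1))
  tied <- tied[nt == min(nt)]
  dg <- vapply(fits[tied], poly_degree, numeric(1))
  fits[[tied[which.min(dg)]]]
}

#' Fit the SD-on-predictor model from mean-model residuals
#'
#' Step 2 of the chart construction: model the response SD as a linear
#' function of the predictor.  The default `"binned"` method treats the SD
#' as an observable — residuals are grouped into predictor bins (1 week for
#' GA, 5 mm for BPD/FL), the per-bin SD computed, and a linear model of bin
#' SD on bin centre fitted by two-pass generalised least squares: a
#' count-weighted first pass (late-gestation bins are sparse), then a second
#' pass weighted by the known Gaussian sampling variance of a bin SD,
#' `sd^2/(2 n_b)`, which also yields exact GLS coefficient standard
#' errors.  The `"absolute_residual"` method regresses `|residual|` on the
#' predictor and rescales by `sqrt(pi/2)`, the factor relating the mean
#' absolute deviation of a centred Gaussian to its SD.
#'
#' @param x Predictor values.
#' @param residuals Residuals from the fitted mean model, same length.
#' @param config A [fit_config()].
#' @param predictor Predictor label.
#' @return A fitted linear [poly_model()] for the SD.
#' @export
fit_sd_model <- function(x, residuals, config = fit_config(),
                         predictor = c("GA", "BPD", "FL")) {
  predictor <- match.arg(predictor)
  x <- as.numeric(x); r <- as.numeric(residuals)
  if (length(x) != length(r) || length(x) < 4L) {
    stop_typed("insufficient_data", "need matching x and residuals, n >= 4")
  }

  if (config$sd_method == "binned") {
    width <- config$bin_width %||% (if (predictor == "GA") 1 else 5)
    centre <- round(x / width) * width
    groups <- split(r, centre)
    counts <- lengths(groups)
    keep <- counts >= config$min_bin_count
    if (sum(keep) < 2L) {
      stop_typed("insufficient_bins",
                 sprintf("fewer than 2 predictor bins hold >= %d residuals",
                         config$min_bin_count))
    }
    bin_sd <- vapply(groups[keep], stats::sd, numeric(1))
    bin_x <- as.numeric(names(groups)[keep])
    bin_n <- counts[keep]
    # Two-pass GLS: a Gaussian bin SD has sampling variance sd^2/(2 n_b), so
    # a count-weighted first pass supplies fitted SDs, and the second pass
    # uses the implied known variances as weights.  Coefficient SEs then
    # come from the exact GLS covariance (X' W X)^-1 rather than the
    # few-degrees-of-freedom residual estimate.
    fit0 <- stats::lm(bin_sd ~ bin_x, weights = bin_n)
    sd0 <- stats::fitted(fit0)
    if (any(sd0 <= 0)) {
      stop_typed("non_positive_sd",
                 "first-pass SD model is non-positive at a bin centre")
    }
    w <- 2 * bin_n / sd0^2
    fit <- stats::lm(bin_sd ~ bin_x, weights = w)
    X <- cbind(1, bin_x)
    beta <- unname(stats::coef(fit))
    se <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
    r2 <- summary(fit)$r.squared
    p_val <- stats::anova(fit)[["Pr(>F)"]][1]
  } else {
    a <- abs(r)
    fit <- stats::lm(a ~ x)
    hn <- sqrt(pi / 2)                 # half-normal mean-to-SD correction
    beta <- unname(stats::coef(fit)) * hn
    se <- summary(fit)$coefficients[, "Std. Error"] * hn
    r2 <- summary(fit)$r.squared
    p_val <- stats::anova(fit)[["Pr(>F)"]][1]
  }
  fitted_sd <- beta[1] + beta[2] * x
  if (any(fitted_sd <= 0)) {
    stop_typed("non_positive_sd",
               "fitted SD model is non-positive somewhere over the data range")
  }
  names(se) <- c("p0", "p1")
  if (is.na(r2) || r2 < 0) r2 <- 0
  poly_model(predictor, c(0L, 1L), beta, provenance = "fitted",
             fit_stats = list(R = sqrt(r2), p = p_val,
                              se = se, method = config$sd_method,
                              n = length(x)))
}

#' Build a reference chart from a cohort (the full three-step pipeline)
#'
#' Step 1 selects the best polynomial mean model, step 2 fits the SD model
#' on the mean-model residuals, step 3 standardises every training record
#' against the pair.  The training Z-scores are returned alongside the chart
#' for calibration diagnostics (see [diagnostics_report()]); on a correctly
#' specified cohort they have mean near 0, SD near 1, and about 10% of
#' values outside the 1.65 band.
#'
#' @param records A cohort data.frame with lowercase columns `ga`, `bpd`,
#'   `fl`, `dmax`, `dmin`, `dd` (as produced by [simulate_cohort()] or
#'   [read_cohort()]).
#' @param response,predictor Chart selection.
#' @param config A [fit_config()].
#' @param min_records,min_distinct Guards: the pipeline refuses cohorts with
#'   fewer records or fewer distinct predictor values than these (defaults
#'   50 and 10).
#' @return A list of class `aortaz_fit` with elements `chart`
#'   (the fitted [reference_chart()]) and `zscores` (training
#'   [zscore()] results, one row per record, with `x` attached).
#' @export
build_reference_chart <- function(records, response, predictor,
                                  config = fit_config(),
                                  min_records = 50L, min_distinct = 10L) {
  response <- match.arg(response, c("Dmax", "Dmin", "DD"))
  predictor <- match.arg(predictor, c("GA", "BPD", "FL"))
  x <- as.numeric(records[[tolower(predictor)]])
  col <- c(Dmax = "dmax", Dmin = "dmin", DD = "dd")[[response]]
  y <- records[[col]]
  if (is.null(y) && response == "DD") y <- distensibility(records$dmax, records$dmin)
  y <- as.numeric(y)
  if (length(x) < min_records) {
    stop_typed("insufficient_data",
               sprintf("chart construction needs >= %d records, got %d",
                       min_records, length(x)))
  }
  if (length(unique(x)) < min_distinct) {
    stop_typed("insufficient_data",
               sprintf("chart construction needs >= %d distinct %s values",
                       min_distinct, predictor))
  }
  mean_model <- select_best_model(x, y, config, predictor)
  resid <- y - evaluate_poly(mean_model, x)
  sd_model <- fit_sd_model(x, resid, config, predictor)
  chart <- reference_chart(response, mean_model, sd_model, range = range(x))
  zs <- zscore(y, evaluate_poly(mean_model, x), evaluate_poly(sd_model, x))
  zs$x <- x
  structure(list(chart = chart, zscores = zs), class = "aortaz_fit")
}

#' @export
print.aortaz_fit <- function(x, ...) {
  print(x$chart)
  cat(sprintf("  training: n = %d, mean z = %.3f, sd z = %.3f, outside 90%% band = %.1f%%\n",
              nrow(x$zscores), mean(x$zscores$z), stats::sd(x$zscores$z),
              100 * mean(abs(x$zscores$z) > BAND_Z)))
  invisible(x)
}
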