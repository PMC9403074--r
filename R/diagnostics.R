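#' P-P plot data for a sample against a normal reference
#'
#' Probability-probability plot coordinates: the empirical CDF at each sorted
#' value (Hazen plotting position `(i - 0.5)/n` by default) against the
#' reference normal CDF evaluated at the value.  Points on the diagonal
#' indicate distributional agreement; `max_abs_deviation` summarises the
#' largest vertical gap.
#'
#' @param values Numeric sample, `n >= 3`.
#' @param reference `"standard_normal"` (N(0,1), appropriate for Z-scores) or
#'   `"fitted_normal"` (normal with the sample's mean and SD, appropriate for
#'   raw residuals).
#' @param plotting_position `"hazen"` (`(i - 0.5)/n`, default) or
#'   `"weibull"` (`i/(n + 1)`); the two differ by O(1/n).
#' @return An object of class `aortaz_pp`: list with `points` (data.frame
#'   `empirical`, `theoretical`, sorted by `theoretical`) and
#'   `max_abs_deviation`.
#' @export
pp_plot_data <- function(values,
                         reference = c("standard_normal", "fitted_normal"),
                         plotting_position = c("hazen", "weibull")) {
  reference <- match.arg(reference)
  plotting_position <- match.arg(plotting_position)
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) {
    stop_typed("insufficient_data", "P-P plot needs at least 3 finite values")
  }
  s <- sort(values)
  emp <- if (plotting_position == "hazen") (seq_len(n) - 0.5) / n
         else seq_len(n) / (n + 1)
  theo <- if (reference == "standard_normal") stats::pnorm(s)
          else stats::pnorm(s, mean = mean(s), sd = stats::sd(s))
  structure(
    list(points = data.frame(empirical = emp, theoretical = theo),
         max_abs_deviation = max(abs(emp - theo)),
         reference = reference, n = n),
    class = "aortaz_pp"
  )
}

#' @export
print.aortaz_pp <- function(x, ...) {
  cat(sprintf("<P-P plot data> n = %d vs %s; max |empirical - theoretical| = %.4f\n",
              x$n, x$reference, x$max_abs_deviation))
  invisible(x)
}

#' @export
plot.aortaz_pp <- function(x, ...) {
  graphics::plot(x$points$theoretical, x$points$empirical,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 20, cex = 0.5,
                 xlab = "theoretical CDF", ylab = "empirical CDF", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Formal companion to the graphical P-P check.
#'
#' @param z_values Numeric sample, `3 <= n <= 5000`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
normality_test <- function(z_values) {
  z <- as.numeric(z_values)
  z <- z[is.finite(z)]
  if (length(z) < 3L || length(z) > 5000L) {
    stop_typed("insufficient_data",
               "Shapiro-Wilk requires between 3 and 5000 values")
  }
  if (diff(range(z)) == 0) {
    stop_typed("degenerate_input", "all values identical: normality undefined")
  }
  sw <- stats::shapiro.test(z)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Fraction of Z-scores outside a symmetric reference band
#'
#' For a calibrated chart the training Z-scores are standard normal, so the
#' expected fraction outside `|z| > 1.6449` is 10% and outside `|z| > 1.96`
#' is 5%.
#'
#' @param z_values Z-scores, `n >= 1`.
#' @param band Positive half-width; strict inequality.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_check <- function(z_values, band) {
  z <- as.numeric(z_values)
  if (length(z) < 1L) stop_typed("insufficient_data", "need at least one z value")
  if (!is.finite(band) || band <= 0) {
    stop_typed("config_error", "band must be a positive number")
  }
  mean(abs(z) > band)
}

#' Balance of Z-scores across the predictor range
#'
#' OLS slope of z on the predictor with its two-sided p-value.  A calibrated
#' chart leaves no trend: Z-scores are equally distributed above and below
#' zero across the whole range.
#'
#' @param z_values,x_values Equal-length vectors, `n >= 10`.
#' @return List with `slope` and `p_value`.
#' @export
balance_check <- function(z_values, x_values) {
  z <- as.numeric(z_values); x <- as.numeric(x_values)
  if (length(z) != length(x) || length(z) < 10L) {
    stop_typed("insufficient_data",
               "balance check needs matching z and x with n >= 10")
  }
  if (diff(range(x)) == 0) {
    stop_typed("degenerate_input", "constant predictor: slope undefined")
  }
  fit <- stats::lm(z ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       p_value = unname(cf["x", "Pr(>|t|)"]))
}

#' Combined calibration report for a scored cohort
#'
#' Bundles the four diagnostics into the flat structure written by the
#' `diagnose` workflow: P-P maximum deviation, Shapiro-Wilk p, coverage at
#' the 1.6449 (90%) and 1.96 (95%) bands, and the balance slope/p.
#'
#' @param z_values Z-scores of a scored cohort.
#' @param x_values Matching predictor values.
#' @return Named list `pp_max_deviation`, `shapiro_p`, `coverage_1645`,
#'   `coverage_196`, `balance_slope`, `balance_p`.
#' @export
diagnostics_report <- function(z_values, x_values) {
  bal <- balance_check(z_values, x_values)
  list(
    pp_max_deviation = pp_plot_data(z_values)$max_abs_deviation,
    shapiro_p = normality_test(z_values)$p_value,
    coverage_1645 = coverage_check(z_values, 1.6449),
    coverage_196 = coverage_check(z_values, 1.96),
    balance_slope = bal$slope,
    balance_p = bal$p_value
  )
}
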