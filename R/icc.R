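#' Repeatability table: subjects by repeated measurements
#'
#' Holds the raw data of an observer-agreement study: one row per subject,
#' one column per measurement (two raters for an interobserver design, or
#' repeated readings by one rater for an intraobserver design).
#'
#' @param matrix Numeric matrix (or data.frame), subjects in rows,
#'   measurements in columns; at least 5 subjects, 2 columns, no missing
#'   cells.
#' @param design `"intraobserver"` or `"interobserver"`.
#' @return An object of class `aortaz_repeat_table`.
#' @export
repeatability_table <- function(matrix, design = c("intraobserver", "interobserver")) {
  design <- match.arg(design)
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) {
    stop_typed("degenerate_table", "repeatability needs at least 2 measurement columns")
  }
  if (nrow(m) < 5L) {
    stop_typed("insufficient_data", "repeatability needs at least 5 subjects")
  }
  if (anyNA(m)) {
    stop_typed("degenerate_table", "missing cells are not supported")
  }
  structure(list(matrix = m, design = design), class = "aortaz_repeat_table")
}

#' Intraclass correlation coefficient from ANOVA mean squares
#'
#' Single-measure ICC in three classical forms.  With `n` subjects, `k`
#' measurements, between-subject mean square `MSR`, between-measurement
#' mean square `MSC`, two-way residual `MSE` and one-way within-subject
#' `MSW`:
#' \itemize{
#'   \item `ICC_2_1_agreement` (two-way random effects, absolute agreement):
#'     `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.  Systematic
#'     rater offsets count against agreement.  Default for interobserver
#'     designs.
#'   \item `ICC_1_1` (one-way random effects):
#'     `(MSR - MSW) / (MSR + (k-1) MSW)`.  Appropriate when replicates are
#'     exchangeable, as in an intraobserver design.
#'   \item `ICC_3_1_consistency` (two-way mixed, consistency):
#'     `(MSR - MSE) / (MSR + (k-1) MSE)`.  Ignores constant offsets.
#' }
#' Confidence intervals are the exact F-based bounds (Shrout-Fleiss /
#' McGraw-Wong); the agreement form uses the Satterthwaite degrees of
#' freedom.
#'
#' @param table A [repeatability_table()] (or bare matrix, coerced with an
#'   intraobserver design).
#' @param form ICC variant; default `"ICC_2_1_agreement"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `aortaz_icc`: `estimate`, `ci` (lower, upper),
#'   `form`, `n`, `k` and the mean squares `ms`.
#' @export
icc <- function(table,
                form = c("ICC_2_1_agreement", "ICC_1_1", "ICC_3_1_consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  if (!inherits(table, "aortaz_repeat_table")) {
    table <- repeatability_table(table)
  }
  m <- table$matrix
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) {
    stop_typed("degenerate_table", "zero total variance: ICC undefined")
  }
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- (sst - ssr) / (n * (k - 1))
  alpha <- 1 - conf_level

  if (form == "ICC_1_1") {
    est <- (msr - msw) / (msr + (k - 1) * msw)
    if (msw == 0) {
      est <- 1; ci <- c(1, 1)
    } else {
      fo <- msr / msw
      fl <- fo / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
      fu <- fo * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else if (form == "ICC_3_1_consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      est <- 1; ci <- c(1, 1)
    } else {
      fo <- msr / mse
      df2 <- (n - 1) * (k - 1)
      fl <- fo / stats::qf(1 - alpha / 2, n - 1, df2)
      fu <- fo * stats::qf(1 - alpha / 2, df2, n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (abs(1 - est) < 1e-12 || (mse == 0 && msc == 0)) {
      ci <- c(if (mse == 0 && msc == 0) 1 else NA_real_, 1)
    } else {
      # McGraw & Wong: Satterthwaite df for the denominator of the F bound
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(lower, upper)
    }
  }
  # rounding in the sums of squares can push a perfect-agreement estimate a
  # few ulp past 1; the estimand is bounded above by 1
  if (est > 1) est <- 1
  ci <- pmin(ci, 1)
  structure(
    list(estimate = est, ci = ci, form = form, n = n, k = k,
         conf_level = conf_level,
         ms = list(msr = msr, msc = msc, mse = mse, msw = msw)),
    class = "aortaz_icc"
  )
}

#' @export
print.aortaz_icc <- function(x, ...) {
  cat(sprintf("<icc> %s = %.4f  %g%% CI [%.4f, %.4f]  (n = %d subjects, k = %d)\n",
              x$form, x$estimate, 100 * x$conf_level, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Repeatability report across parameters and designs
#'
#' Computes one ICC per supplied table, following the layout of an
#' intra/interobserver agreement table over the three measured parameters.
#' Intraobserver tables get the one-way `ICC_1_1` by default, interobserver
#' tables the absolute-agreement `ICC_2_1_agreement`.  A table that fails
#' (wrong shape, degenerate) surfaces its error message in the report
#' without aborting the other cells.
#'
#' @param tables Named list; each element a [repeatability_table()] or a
#'   bare matrix (then treated as intraobserver).
#' @param conf_level Confidence level passed to [icc()].
#' @return data.frame with columns `label`, `design`, `form`, `estimate`,
#'   `ci_lower`, `ci_upper`, `error`.
#' @export
repeatability_report <- function(tables, conf_level = 0.95) {
  stopifnot(is.list(tables), length(tables) > 0)
  labels <- names(tables) %||% as.character(seq_along(tables))
  rows <- lapply(seq_along(tables), function(i) {
    out <- data.frame(label = labels[i], design = NA_character_,
                      form = NA_character_, estimate = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      tb <- tables[[i]]
      if (!inherits(tb, "aortaz_repeat_table")) tb <- repeatability_table(tb)
      form <- if (tb$design == "interobserver") "ICC_2_1_agreement" else "ICC_1_1"
      res <- icc(tb, form = form, conf_level = conf_level)
      out$design <- tb$design
      out$form <- res$form
      out$estimate <- res$estimate
      out$ci_lower <- res$ci[1]
      out$ci_upper <- res$ci[2]
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  do.call(rbind, rows)
}
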