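#' Simulate a fetal biometry cohort
#'
#' Generates a cohort with the statistical structure the chart pipeline
#' assumes: gestational age drawn over 18-40 weeks; BPD and FL as linear
#' functions of GA plus Gaussian noise (anchored at standard biometry
#' values: BPD ~47 mm at 20 weeks and ~95 mm at term, FL ~33 mm and ~76
#' mm); distensibility and Dmax drawn from Gaussians whose mean and SD
#' follow the truth charts at each fetus's GA; and Dmin derived exactly as
#' `Dmax/(1 + DD)`, so the three responses are internally consistent and
#' `distensibility(dmax, dmin)` returns the DD draw to machine precision.
#'
#' Draws are floored at physical minima (DD at 0.01, Dmax at 0.5 mm) by
#' rejection sampling; the fraction of redrawn values is recorded in the
#' `truncation_fraction` attribute.  Near term the DD truth models put a few
#' percent of mass below the floor, so DD truncation is not negligible there
#' (see the package vignette).
#'
#' @param n Cohort size (default 490, the reference-study size).
#' @param ga_range Gestational-age range in weeks, default `c(18, 40)`.
#' @param ga_distribution `"uniform"` (default) or `"empirical_skewed"`,
#'   which thins the under-20 and over-38 week tails to a quarter of the
#'   central density, mimicking the sparse extremes of a clinical cohort.
#' @param truth Registry of truth charts (default the sanitized
#'   [published_registry()]); must contain `DD~GA` and `Dmax~GA`.
#' @param biometry_noise_sd SD of the BPD/FL noise, mm (default 2.0).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return data.frame of class `aortaz_cohort` with columns `ga`, `bpd`,
#'   `fl`, `dmax`, `dmin`, `dd`, and attribute `truncation_fraction`.
#' @export
simulate_cohort <- function(n = 490L,
                            ga_range = c(18, 40),
                            ga_distribution = c("uniform", "empirical_skewed"),
                            truth = published_registry("sanitized"),
                            biometry_noise_sd = 2.0,
                            seed = NULL) {
  ga_distribution <- match.arg(ga_distribution)
  if (n < 1L) stop_typed("config_error", "cohort size must be >= 1")
  if (ga_range[1] < 10 || ga_range[2] > 45 || ga_range[1] >= ga_range[2]) {
    stop_typed("config_error", "ga_range must lie within (10, 45)")
  }
  if (biometry_noise_sd < 0) stop_typed("config_error", "noise SDs must be >= 0")
  dd_chart <- truth[["DD~GA"]]
  dmax_chart <- truth[["Dmax~GA"]]
  if (is.null(dd_chart) || is.null(dmax_chart)) {
    stop_typed("config_error", "truth registry must contain DD~GA and Dmax~GA charts")
  }
  grid <- seq(ga_range[1], ga_range[2], length.out = 101L)
  for (ch in list(dd_chart, dmax_chart)) {
    if (any(evaluate_poly(ch$sd_model, grid) <= 0)) {
      stop_typed("config_error",
                 sprintf("truth SD model for %s~GA non-positive over the GA range",
                         ch$response))
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  ga <- draw_ga(n, ga_range, ga_distribution)
  bpd <- 2.4 * ga - 1 + stats::rnorm(n, 0, biometry_noise_sd)
  fl <- 2.15 * ga - 10 + stats::rnorm(n, 0, biometry_noise_sd)

  dd <- rnorm_floor(evaluate_poly(dd_chart$mean_model, ga),
                    evaluate_poly(dd_chart$sd_model, ga), floor = 0.01)
  dmax <- rnorm_floor(evaluate_poly(dmax_chart$mean_model, ga),
                      evaluate_poly(dmax_chart$sd_model, ga), floor = 0.5)
  dmin <- dmax$values / (1 + dd$values)

  out <- data.frame(ga = ga, bpd = bpd, fl = fl,
                    dmax = dmax$values, dmin = dmin, dd = dd$values)
  class(out) <- c("aortaz_cohort", "data.frame")
  attr(out, "truncation_fraction") <- c(dd = dd$truncated, dmax = dmax$truncated)
  out
}

draw_ga <- function(n, ga_range, distribution) {
  if (distribution == "uniform") {
    return(stats::runif(n, ga_range[1], ga_range[2]))
  }
  # piecewise-constant density, tails at a quarter of the central weight
  lo <- ga_range[1]; hi <- ga_range[2]
  edges <- c(lo, max(lo, 20), min(hi, 38), hi)
  dens <- c(0.25, 1, 0.25)
  mass <- dens * pmax(diff(edges), 0)
  seg <- sample.int(3L, n, replace = TRUE, prob = mass / sum(mass))
  stats::runif(n, edges[seg], edges[seg + 1L])
}

# Gaussian draws floored by rejection; no point mass at the floor.  Returns
# the fraction of initial draws that fell below and had to be redrawn.
rnorm_floor <- function(mean, sd, floor, max_iter = 100L) {
  n <- length(mean)
  v <- stats::rnorm(n, mean, sd)
  truncated <- mean(v < floor)
  it <- 0L
  while (any(v < floor) && it < max_iter) {
    idx <- which(v < floor)
    v[idx] <- stats::rnorm(length(idx), mean[idx], sd[idx])
    it <- it + 1L
  }
  v[v < floor] <- floor  # unreachable in practice; hard guard
  list(values = v, truncated = truncated)
}

#' Simulate a repeatability (observer-agreement) table
#'
#' Draws `n_subjects` fetuses from the cohort model, takes their true
#' parameter values, and adds independent per-measurement Gaussian noise to
#' build a subjects-by-measurements table.  An interobserver design may add
#' a constant rater offset to all but the first column, emulating a
#' systematic between-observer bias.
#'
#' @param n_subjects Number of subjects (default 20, the usual size of a
#'   repeatability sub-study); at least 5.
#' @param k Measurements per subject (default 2); at least 2.
#' @param design `"intraobserver"` or `"interobserver"`.
#' @param parameter `"dmax"`, `"dmin"` or `"dd"`.
#' @param measurement_noise_sd Per-measurement noise SD in the parameter's
#'   units.  `NULL` (default) uses 0.05 mm for the diameters and 0.02 for
#'   distensibility; both imply ICCs in the >= 0.93 range reported for this
#'   kind of study.
#' @param rater_offset Constant added to columns 2..k under the
#'   interobserver design (default 0).
#' @param truth,ga_range,seed As in [simulate_cohort()].
#' @return A [repeatability_table()].
#' @export
simulate_repeatability <- function(n_subjects = 20L, k = 2L,
                                   design = c("intraobserver", "interobserver"),
                                   parameter = c("dmax", "dmin", "dd"),
                                   measurement_noise_sd = NULL,
                                   rater_offset = 0,
                                   truth = published_registry("sanitized"),
                                   ga_range = c(18, 40),
                                   seed = NULL) {
  design <- match.arg(design)
  parameter <- match.arg(parameter)
  if (n_subjects < 5L) stop_typed("config_error", "need at least 5 subjects")
  if (k < 2L) stop_typed("config_error", "need at least 2 measurements per subject")
  noise <- measurement_noise_sd %||% (if (parameter == "dd") 0.02 else 0.05)
  if (noise < 0) stop_typed("config_error", "noise SDs must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cohort <- simulate_cohort(n_subjects, ga_range = ga_range, truth = truth)
  truth_vals <- cohort[[parameter]]
  m <- truth_vals + matrix(stats::rnorm(n_subjects * k, 0, noise), n_subjects, k)
  if (design == "interobserver" && rater_offset != 0) {
    m[, -1L] <- m[, -1L] + rater_offset
  }
  colnames(m) <- paste0("m", seq_len(k))
  repeatability_table(m, design)
}
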