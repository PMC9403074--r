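#' Read a cohort CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `ga_weeks`, `dmax_mm`,
#' `dmin_mm` (required) and `bpd_mm`, `fl_mm` (optional).  Distensibility is
#' always computed from the diameters, never read.  Rows violating the
#' measurement invariants (unparseable numbers, non-positive diameters,
#' `dmin > dmax`) are collected into a rejects table attached as the
#' `"rejects"` attribute — reported, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @return Cohort data.frame (`ga`, `bpd`, `fl`, `dmax`, `dmin`, `dd`) of
#'   class `aortaz_cohort`, with attribute `rejects` (data.frame `row`,
#'   `reason`).  See [cohort_rejects()].
#' @export
read_cohort <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_typed("schema", paste("cannot read cohort CSV:",
                                                   conditionMessage(e)))
  )
  required <- c("ga_weeks", "dmax_mm", "dmin_mm")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_typed("schema", paste("missing required column(s):",
                               paste(missing, collapse = ", ")))
  }
  num <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, nrow(raw))
  }
  ga <- num("ga_weeks"); bpd <- num("bpd_mm"); fl <- num("fl_mm")
  dmax <- num("dmax_mm"); dmin <- num("dmin_mm")

  reason <- rep(NA_character_, nrow(raw))
  bad_num <- !is.finite(ga) | !is.finite(dmax) | !is.finite(dmin)
  reason[bad_num] <- "unparseable-numeric"
  bad_meas <- !bad_num & (dmax <= 0 | dmin <= 0)
  reason[bad_meas] <- "invalid-measurement"
  bad_frames <- !bad_num & !bad_meas & (dmax < dmin)
  reason[bad_frames] <- "inconsistent-frames"

  keep <- is.na(reason)
  out <- data.frame(ga = ga[keep], bpd = bpd[keep], fl = fl[keep],
                    dmax = dmax[keep], dmin = dmin[keep],
                    dd = if (any(keep)) distensibility(dmax[keep], dmin[keep]) else numeric(0))
  class(out) <- c("aortaz_cohort", "data.frame")
  attr(out, "rejects") <- data.frame(row = which(!keep),
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' @rdname read_cohort
#' @param cohort A cohort read by [read_cohort()].
#' @export
cohort_rejects <- function(cohort) {
  attr(cohort, "rejects") %||% data.frame(row = integer(0), reason = character(0))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: unit-suffixed column names, numbers at 6
#' significant digits.  Distensibility is derived data and is not
#' persisted.
#'
#' @param cohort Cohort data.frame with `ga`, `dmax`, `dmin` (and optionally
#'   `bpd`, `fl`) columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(
    ga_weeks = signif(cohort$ga, 6),
    bpd_mm = signif(cohort$bpd %||% rep(NA_real_, nrow(cohort)), 6),
    fl_mm = signif(cohort$fl %||% rep(NA_real_, nrow(cohort)), 6),
    dmax_mm = signif(cohort$dmax, 6),
    dmin_mm = signif(cohort$dmin, 6)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a reference chart to JSON
#'
#' Charts round-trip through JSON with full double precision: `response`,
#' `predictor`, mean `terms` and `sd_terms` as `[power, coefficient]`
#' arrays, the supported `range`, provenance and any printed source form.
#'
#' @param chart A [reference_chart()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chart_json <- function(chart, path) {
  obj <- list(
    response = chart$response,
    predictor = chart$mean_model$predictor,
    terms = unname(apply(chart$mean_model$terms, 1, as.numeric, simplify = FALSE)),
    sd_terms = unname(apply(chart$sd_model$terms, 1, as.numeric, simplify = FALSE)),
    range = chart$range,
    provenance = list(mean = chart$mean_model$provenance,
                      sd = chart$sd_model$provenance),
    printed = list(mean = chart$mean_model$printed, sd = chart$sd_model$printed),
    fit_stats = list(mean = fit_stats_json(chart$mean_model),
                     sd = fit_stats_json(chart$sd_model))
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

# R, p and se survive serialisation; other fit metadata does not
fit_stats_json <- function(model) {
  fs <- model$fit_stats
  if (is.null(fs)) return(NULL)
  list(R = fs$R, p = fs$p, se = as.numeric(fs$se))
}

#' @rdname write_chart_json
#' @export
read_chart_json <- function(path) {
  obj <- jsonlite::read_json(path)
  term_matrix <- function(terms) {
    do.call(rbind, lapply(terms, function(t) as.numeric(unlist(t))))
  }
  tm <- term_matrix(obj$terms)
  ts <- term_matrix(obj$sd_terms)
  restore_stats <- function(fs) {
    if (is.null(fs)) NULL else lapply(fs, function(v) as.numeric(unlist(v)))
  }
  mean_model <- poly_model(obj$predictor, tm[, 1], tm[, 2],
                           provenance = obj$provenance$mean,
                           fit_stats = restore_stats(obj$fit_stats$mean),
                           printed = obj$printed$mean)
  sd_model <- poly_model(obj$predictor, ts[, 1], ts[, 2],
                         provenance = obj$provenance$sd,
                         fit_stats = restore_stats(obj$fit_stats$sd),
                         printed = obj$printed$sd)
  reference_chart(obj$response, mean_model, sd_model,
                  range = as.numeric(unlist(obj$range)), validate = FALSE)
}

#' Score a cohort file against a reference chart
#'
#' Reads a cohort CSV, scores every record for the requested
#' `(response, predictor)` chart, and writes the input back out with
#' appended `z_<response>_<predictor>` and `band_<response>_<predictor>`
#' columns.  Nothing is written unless the whole computation succeeds.
#'
#' @param input,output CSV paths; `output` may equal `input` conceptually
#'   but writing happens only after scoring completes.
#' @param response,predictor Chart selection.
#' @param registry Chart registry (default sanitized [published_registry()]).
#' @return Invisibly, a summary list: `n`, `n_rejected`, `mean_z`, `sd_z`,
#'   `coverage_165` (fraction with `|z| > 1.65`).
#' @export
score_file <- function(input, output, response, predictor,
                       registry = published_registry()) {
  response <- match.arg(response, c("Dmax", "Dmin", "DD"))
  predictor <- match.arg(predictor, c("GA", "BPD", "FL"))
  cohort <- read_cohort(input)
  key <- paste0(response, "~", predictor)
  chart <- registry[[key]]
  if (is.null(chart)) {
    stop_typed("unknown_chart", sprintf("no chart '%s' in the registry", key))
  }
  x <- cohort[[tolower(predictor)]]
  if (all(!is.finite(x))) {
    stop_typed("incomplete_record",
               sprintf("cohort has no usable %s values", predictor))
  }
  col <- c(Dmax = "dmax", Dmin = "dmin", DD = "dd")[[response]]
  zs <- zscore(cohort[[col]],
               evaluate_poly(chart$mean_model, x),
               predict_sd_quiet(chart, x))

  out_df <- utils::read.csv(input, check.names = FALSE, stringsAsFactors = FALSE)
  zcol <- paste0("z_", tolower(response), "_", tolower(predictor))
  bcol <- paste0("band_", tolower(response), "_", tolower(predictor))
  out_df[[zcol]] <- NA_real_
  out_df[[bcol]] <- NA_character_
  kept <- setdiff(seq_len(nrow(out_df)), cohort_rejects(cohort)$row)
  out_df[[zcol]][kept] <- signif(zs$z, 6)
  out_df[[bcol]][kept] <- zs$band_flag
  utils::write.csv(out_df, output, row.names = FALSE, quote = FALSE)

  invisible(list(
    n = nrow(cohort),
    n_rejected = nrow(cohort_rejects(cohort)),
    mean_z = mean(zs$z),
    sd_z = stats::sd(zs$z),
    coverage_165 = coverage_check(zs$z, BAND_Z)
  ))
}
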