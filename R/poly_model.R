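#' Polynomial model in a single biometric predictor
#'
#' A `poly_model` is an explicit term list \eqn{y = \sum_j c_j x^{p_j}} in one
#' predictor (gestational age `GA` in weeks, biparietal diameter `BPD` in mm,
#' or femur length `FL` in mm).  The same representation is used for the mean
#' and for the SD of a reference chart, mirroring how fetal biometry reference
#' equations are published.
#'
#' @param predictor One of `"GA"`, `"BPD"`, `"FL"`.
#' @param powers Integer vector of non-negative, unique powers.
#' @param coefficients Numeric vector, one coefficient per power.
#' @param provenance One of `"published_as_printed"`, `"published_sanitized"`,
#'   `"fitted"`.  `fit_stats` must be present if and only if the model was
#'   fitted by this package.
#' @param fit_stats For fitted models, a list with at least `R` (multiple
#'   correlation of the fit) and `p` (overall-F p-value); may carry `se`
#'   (coefficient standard errors) and other fit metadata.
#' @param printed Optional character string holding a published equation
#'   verbatim, kept for provenance when the printed form cannot be represented
#'   exactly as a term list (e.g. a typographically corrupt equation).
#'
#' @return An object of class `aortaz_poly`.
#' @seealso [evaluate_poly()], [published_registry()]
#' @examples
#' m <- poly_model("GA", c(0, 1, 2), c(-2.99, 0.32, -2.14e-3),
#'                 provenance = "published_as_printed")
#' evaluate_poly(m, 24) # 3.45736
#' @export
poly_model <- function(predictor,
                       powers,
                       coefficients,
                       provenance = c("fitted", "published_as_printed",
                                      "published_sanitized"),
                       fit_stats = NULL,
                       printed = NULL) {
  predictor <- match.arg(predictor, c("GA", "BPD", "FL"))
  provenance <- match.arg(provenance)
  powers <- as.numeric(powers)
  coefficients <- as.numeric(coefficients)
  if (length(powers) == 0L || length(powers) != length(coefficients)) {
    stop_typed("malformed_model",
               "a polynomial model needs matching, non-empty powers and coefficients")
  }
  if (any(powers < 0) || any(powers != round(powers)) || anyDuplicated(powers)) {
    stop_typed("malformed_model",
               "polynomial powers must be unique non-negative integers")
  }
  if (provenance == "fitted" && is.null(fit_stats)) {
    stop_typed("malformed_model", "fitted models must carry fit_stats")
  }
  if (provenance != "fitted" && !is.null(fit_stats)) {
    stop_typed("malformed_model", "only fitted models may carry fit_stats")
  }
  ord <- order(powers)
  structure(
    list(
      predictor = predictor,
      terms = data.frame(power = powers[ord], coefficient = coefficients[ord]),
      provenance = provenance,
      fit_stats = fit_stats,
      printed = printed
    ),
    class = "aortaz_poly"
  )
}

#' Evaluate a polynomial model
#'
#' Exact term-sum evaluation of the stored `(power, coefficient)` list at
#' `x`.  No range checking happens here: supported-range warnings are the
#' responsibility of the reference chart carrying the model (see
#' [predict_mean()]).
#'
#' @param model A [poly_model()].
#' @param x Numeric vector of predictor values (finite).
#' @return Numeric vector of model values.
#' @export
evaluate_poly <- function(model, x) {
  if (!inherits(model, "aortaz_poly")) {
    stop_typed("malformed_model", "`model` must be an aortaz_poly object")
  }
  if (nrow(model$terms) == 0L) {
    stop_typed("malformed_model", "model has an empty term list")
  }
  x <- as.numeric(x)
  if (length(x) && any(!is.finite(x))) {
    stop_typed("malformed_model", "predictor values must be finite")
  }
  out <- numeric(length(x))
  for (j in seq_len(nrow(model$terms))) {
    out <- out + model$terms$coefficient[j] * x^model$terms$power[j]
  }
  out
}

#' @export
print.aortaz_poly <- function(x, ...) {
  cat("<poly_model> Y =", poly_formula(x), " [", x$predictor, ",",
      x$provenance, "]\n")
  if (!is.null(x$fit_stats)) {
    cat("  fit: R =", format(x$fit_stats$R, digits = 4),
        " p =", format.pval(x$fit_stats$p, digits = 3), "\n")
  }
  if (!is.null(x$printed)) cat("  printed form:", x$printed, "\n")
  invisible(x)
}

# human-readable formula, highest power last
poly_formula <- function(model) {
  tt <- model$terms
  parts <- vapply(seq_len(nrow(tt)), function(j) {
    c_j <- format(tt$coefficient[j], digits = 6)
    p_j <- tt$power[j]
    if (p_j == 0) c_j
    else if (p_j == 1) paste0(c_j, "*", model$predictor)
    else paste0(c_j, "*", model$predictor, "^", p_j)
  }, character(1))
  paste(parts, collapse = " + ")
}

# degree and term count, used for model-selection tie-breaks
poly_degree <- function(model) max(model$terms$power)
poly_nterms <- function(model) nrow(model$terms)
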