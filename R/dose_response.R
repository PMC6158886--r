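# Linear expression-fitness dose-response model across galactose
# concentrations: w = b0 + (b1 + b2 * ln g) * E, fitted by ordinary least
# squares on strain means from the pure-galactose training environments.

#' Fit the expression-fitness dose-response model
#'
#' Default model: fitness is linear in expression with a slope that is
#' itself linear in log galactose concentration,
#' `w = b0 + b1 * E + b2 * E * ln(g)`, fitted by OLS. Alternatives:
#' `"per_concentration"` fits a separate expression slope per galactose
#' level, `"linear"` makes the slope linear in g rather than ln g.
#'
#' @param data data.frame with columns `expression`, `fitness`,
#'   `galactose` (> 0, percent w/v); at least 4 points spanning at least
#'   2 galactose levels. An optional `environment` column labels the
#'   training environments.
#' @param model Model form (see above).
#' @param weights Optional OLS weights (e.g. inverse s.e.m.^2).
#' @return Object of class `dose_response`: list with `fit` (the `lm`),
#'   `coefficients`, `sigma` (residual s.d.), `n`, `galactose_levels`,
#'   `training_environments`, `model`.
#' @export
fit_dose_response <- function(data, model = c("log_interaction",
                                              "per_concentration", "linear"),
                              weights = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("expression", "fitness", "galactose") %in% names(data)))
  if (nrow(data) < 4L) stop("need at least 4 points")
  if (any(data$galactose <= 0)) stop("galactose concentrations must be > 0")
  if (length(unique(data$galactose)) < 2L)
    stop("need at least 2 distinct galactose levels")
  fm <- switch(model,
    log_interaction = fitness ~ expression + expression:log(galactose),
    linear = fitness ~ expression + expression:galactose,
    per_concentration = fitness ~ expression:factor(galactose))
  fit <- stats::lm(fm, data = data, weights = weights)
  if (anyNA(stats::coef(fit)))
    stop("unidentifiable model: rank-deficient design")
  structure(list(
    fit = fit, model = model,
    coefficients = stats::coef(fit),
    sigma = sqrt(sum(if (is.null(weights)) stats::resid(fit)^2
                     else weights * stats::resid(fit)^2) / fit$df.residual),
    n = nrow(data),
    galactose_levels = sort(unique(data$galactose)),
    training_environments = if ("environment" %in% names(data))
      sort(unique(data$environment)) else NULL
  ), class = "dose_response")
}

#' Predict fitness from expression at a galactose concentration
#'
#' @param object A fitted [fit_dose_response()] model.
#' @param expression Expression level(s).
#' @param galactose Concentration(s), > 0.
#' @param ... Unused.
#' @return Predicted fitness values.
#' @export
predict.dose_response <- function(object, expression, galactose, ...) {
  if (!inherits(object, "dose_response") || is.null(object$fit))
    stop("model has not been fitted")
  if (any(galactose <= 0)) stop("galactose must be > 0")
  nd <- data.frame(expression = expression, galactose = galactose)
  if (object$model == "per_concentration" &&
      !all(galactose %in% object$galactose_levels))
    stop("per-concentration model only predicts at its training levels")
  unname(stats::predict(object$fit, newdata = nd))
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose-response model> ", x$model, ", n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 5))
  cat("residual s.d.:", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Mean signed residual of held-out points (saturation diagnostic)
#'
#' Mean of (observed - predicted) fitness for points sharing one held-out
#' galactose concentration; a negative gap at a high concentration that
#' shrinks when the prediction is evaluated at a lower substitute
#' concentration indicates saturation of the dose response.
#'
#' @param object A fitted [fit_dose_response()] model.
#' @param data Held-out points (`expression`, `fitness`, `galactose` with
#'   a single common value).
#' @param substitute_galactose Optional concentration at which to
#'   re-evaluate the prediction (e.g. 1 in place of 2).
#' @return List of class `saturation_gap`: `galactose`, `gap`,
#'   `substitute_galactose`, `gap_substitute` (NA when no substitute).
#' @export
saturation_gap <- function(object, data, substitute_galactose = NULL) {
  if (nrow(data) == 0L) stop("no held-out points supplied")
  g <- unique(data$galactose)
  if (length(g) != 1L) stop("held-out points must share one concentration")
  gap <- mean(data$fitness - predict(object, data$expression, g))
  gap_sub <- if (is.null(substitute_galactose)) NA_real_ else
    mean(data$fitness - predict(object, data$expression, substitute_galactose))
  structure(list(galactose = g, gap = gap,
                 substitute_galactose = if (is.null(substitute_galactose))
                   NA_real_ else substitute_galactose,
                 gap_substitute = gap_sub),
            class = "saturation_gap")
}

#' @export
print.saturation_gap <- function(x, ...) {
  cat(sprintf("<saturation gap> at %g%% galactose: %.4f", x$galactose, x$gap))
  if (!is.na(x$gap_substitute))
    cat(sprintf(" (substitute %g%%: %.4f)", x$substitute_galactose,
                x$gap_substitute))
  cat("\n")
  invisible(x)
}
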