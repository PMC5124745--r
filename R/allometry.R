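#' Fit the cross-species allometric clearance relationship
#'
#' Ordinary least squares of log10 clearance on log10 bodyweight, i.e. the
#' power law `CL = a * BW^exponent` fitted on the double-log scale. The
#' evaluation point (here, the zebrafish larva) must be excluded by the
#' caller — the relationship is estimated from the higher vertebrates only —
#' and then compared against the fit with [classify_point()].
#'
#' @param records Data frame with columns `species`, `life_stage` (`"mature"`
#'   or `"immature"`), `bodyweight_kg` (> 0), `clearance_l_per_h` (> 0).
#' @param subset `"mature"` (mature individuals only, the primary analysis)
#'   or `"all"` (mature plus immature).
#' @return An `allometric_fit` object with elements `a` (clearance at 1 kg,
#'   natural scale), `exponent`, `r2`, `n`, `residual_sd` (log10 scale),
#'   `x_mean` and `sxx` (log10-bodyweight design statistics for the interval
#'   formulas), `subset`, and the underlying `lm` fit.
#' @examples
#' sp <- simulate_species_clearances(simulation_config(seed = 3))
#' fit_allometry(sp, subset = "mature")
#' @export
fit_allometry <- function(records, subset = c("mature", "all")) {
  subset <- match.arg(subset)
  records <- validate_species_table(records)
  if (subset == "mature")
    records <- records[records$life_stage == "mature", , drop = FALSE]
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records after filtering")
  x <- log10(records$bodyweight_kg)
  y <- log10(records$clearance_l_per_h)
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    stop("zero variance in bodyweight; exponent not identifiable")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(
    list(a = 10^unname(stats::coef(fit)[1]),
         exponent = unname(stats::coef(fit)[2]),
         r2 = s$r.squared,
         n = n,
         residual_sd = s$sigma,
         x_mean = mean(x),
         sxx = sum((x - mean(x))^2),
         subset = subset,
         lm = fit),
    class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> CL = %.4g * BW^%.4g  (subset: %s, n = %d)\n",
              x$a, x$exponent, x$subset, x$n))
  cat(sprintf("  r2 = %.4f, residual sd (log10) = %.4f\n", x$r2, x$residual_sd))
  invisible(x)
}

#' Predict clearance with confidence and prediction intervals
#'
#' Point prediction `a * BW^exponent` with the standard OLS t-intervals
#' formed on the log10 scale and back-transformed:
#' CI half-width `t * s * sqrt(1/n + (x0 - xbar)^2 / Sxx)`, PI half-width
#' `t * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)` with `t = t(level; n - 2)`.
#' The prediction interval always contains the confidence interval, which
#' always contains the point.
#'
#' @param fit An `allometric_fit`.
#' @param bodyweight Bodyweight(s) in kg.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `bodyweight_kg`, `cl_pred`, `ci_lower`,
#'   `ci_upper`, `pi_lower`, `pi_upper` (all L/h).
#' @export
predict_with_intervals <- function(fit, bodyweight, level = 0.95) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (fit$n < 3L) stop("interval computation requires n >= 3")
  if (any(bodyweight <= 0)) stop("'bodyweight' must be positive")
  nd <- data.frame(x = log10(bodyweight))
  ci <- stats::predict(fit$lm, nd, interval = "confidence", level = level)
  pi <- stats::predict(fit$lm, nd, interval = "prediction", level = level)
  data.frame(bodyweight_kg = bodyweight,
             cl_pred = 10^ci[, "fit"],
             ci_lower = 10^ci[, "lwr"], ci_upper = 10^ci[, "upr"],
             pi_lower = 10^pi[, "lwr"], pi_upper = 10^pi[, "upr"])
}

#' Classify an external clearance record against the allometric fit
#'
#' Compares a species' observed clearance (a record that was not used in the
#' fit, e.g. the zebrafish larva) with the prediction interval of the
#' allometric relationship at that bodyweight. `over_predicted` means the
#' line over-predicts the species' clearance, i.e. the observation lies below
#' the lower PI bound.
#'
#' @param fit An `allometric_fit`.
#' @param record A one-row species record (same columns as [fit_allometry()]
#'   input).
#' @param level Confidence level of the prediction interval.
#' @return A list: `classification` (`"inside_PI"`/`"outside_PI"`),
#'   `direction` (`"over_predicted"`, `"under_predicted"`, or `NA` when
#'   inside), `observed`, `predicted`, `pi_lower`, `pi_upper`.
#' @export
classify_point <- function(fit, record, level = 0.95) {
  record <- validate_species_table(record)
  if (nrow(record) != 1L) stop("'record' must be a single row")
  iv <- predict_with_intervals(fit, record$bodyweight_kg, level)
  obs <- record$clearance_l_per_h
  inside <- obs >= iv$pi_lower && obs <= iv$pi_upper
  list(classification = if (inside) "inside_PI" else "outside_PI",
       direction = if (inside) NA_character_
                   else if (obs < iv$pi_lower) "over_predicted"
                   else "under_predicted",
       observed = obs,
       predicted = iv$cl_pred,
       pi_lower = iv$pi_lower,
       pi_upper = iv$pi_upper)
}
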