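#' Estimate the average larval volume from pooled wet weights
#'
#' The per-larva mean wet weight is the slope of a least-squares regression
#' of total pool weight on larvae count. The regression runs through the
#' origin by default (zero larvae weigh zero); set `intercept = TRUE` to
#' estimate a free intercept instead. Volume follows by dividing by the
#' larval density, taken equal to that of water at 25 degrees C
#' (0.997 g/mL) — with weights in mg this gives microlitres directly
#' (mg / (g/mL) = uL).
#'
#' @param weights Data frame with columns `n_larvae` (>= 1) and
#'   `total_weight_mg` (> 0).
#' @param density Larval density in g/mL (default 0.997).
#' @param intercept Estimate an intercept? Default `FALSE` (through-origin).
#' @return A `larval_volume` object: `mean_weight` (mg/larva), `density`
#'   (g/mL), `volume` (uL/larva), `n` (pools used).
#' @examples
#' w <- data.frame(n_larvae = c(10, 100), total_weight_mg = c(2.91, 29.1))
#' estimate_larval_volume(w)
#' @export
estimate_larval_volume <- function(weights, density = 0.997,
                                   intercept = FALSE) {
  weights <- validate_weight_table(weights)
  if (density <= 0) stop("'density' must be positive")
  if (length(unique(weights$n_larvae)) < 2L) {
    warning("single pool size: slope taken as the weight/count ratio")
    slope <- mean(weights$total_weight_mg / weights$n_larvae)
  } else if (intercept) {
    slope <- unname(stats::coef(
      stats::lm(total_weight_mg ~ n_larvae, data = weights))["n_larvae"])
  } else {
    slope <- unname(stats::coef(
      stats::lm(total_weight_mg ~ 0 + n_larvae, data = weights))["n_larvae"])
  }
  if (slope <= 0) stop("estimated per-larva weight is not positive")
  structure(list(mean_weight = slope, density = density,
                 volume = slope / density, n = nrow(weights)),
            class = "larval_volume")
}

#' @export
print.larval_volume <- function(x, ...) {
  cat(sprintf("<larval_volume> mean wet weight %.4g mg/larva, density %.3f g/mL\n",
              x$mean_weight, x$density))
  cat(sprintf("  volume %.4g uL/larva (from %d pools)\n", x$volume, x$n))
  invisible(x)
}

#' Convert fractional clearance to absolute clearance
#'
#' The model estimates clearance as the fraction of the larval volume cleared
#' per minute (distribution volume fixed to one larva). Multiplying by the
#' larval volume gives uL/min; conversion to L/h is `ke * volume * 60 * 1e-6`.
#' The function is bilinear: doubling either input doubles the result.
#'
#' @param ke Fractional clearance (per min); positive.
#' @param volume Larval volume (uL); positive.
#' @return Absolute clearance in L/h.
#' @examples
#' absolute_clearance(ke = 0.017, volume = 0.290)  # 2.958e-7 L/h
#' @export
absolute_clearance <- function(ke, volume) {
  if (!is.numeric(ke) || any(ke <= 0)) stop("'ke' must be positive")
  if (!is.numeric(volume) || any(volume <= 0)) stop("'volume' must be positive")
  ke * volume * 60 * 1e-6
}
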