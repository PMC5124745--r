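#' Structural and residual-error parameters of the larval PK model
#'
#' Bundles the parameters of the compartmental uptake/washout model used for
#' drug amounts in zebrafish larvae: a zero-order uptake rate from the
#' incubation medium (active only while the larva is in drug-containing
#' medium), a first-order fractional clearance, and optionally a peripheral
#' compartment. The total distribution volume is fixed to one larva, so `ke`
#' equals CL/V and the state variable is an amount (pmole/larva), not a
#' concentration.
#'
#' @param k0 Zero-order uptake rate (pmole/min); drug enters the larva at this
#'   constant rate while it sits in drug-containing medium.
#' @param ke First-order fractional clearance (fraction of the larval volume
#'   cleared per minute; equals CL with V fixed to 1 larva). Must be positive.
#' @param f_central Fraction of the total volume in the central compartment.
#'   `1` (default) selects the one-compartment model; values in (0, 1) select
#'   the two-compartment model, whose compartment volumes are expressed as
#'   fractions of one larva and sum to 1.
#' @param q Inter-compartmental exchange rate (per min); ignored when
#'   `f_central == 1`.
#' @param error_model Residual-error model: `"additive"`, `"proportional"` or
#'   `"combined"`. The residual variance at prediction `f` is
#'   `sigma2_add + sigma2_prop * f^2`.
#' @param sigma2_add Additive residual variance (pmole^2).
#' @param sigma2_prop Proportional residual variance (dimensionless; a 10%
#'   CV corresponds to 0.01).
#'
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(k0 = 0.289, ke = 0.017)
#' amount_uptake(p, 60)
#' @export
pk_params <- function(k0 = 0.289, ke = 0.017, f_central = 1, q = 0,
                      error_model = c("proportional", "additive", "combined"),
                      sigma2_add = 0, sigma2_prop = 0.01) {
  error_model <- match.arg(error_model)
  p <- structure(
    list(k0 = as.numeric(k0), ke = as.numeric(ke),
         f_central = as.numeric(f_central), q = as.numeric(q),
         error_model = error_model,
         sigma2_add = as.numeric(sigma2_add),
         sigma2_prop = as.numeric(sigma2_prop)),
    class = "pk_params")
  validate_pk_params(p)
  p
}

validate_pk_params <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(p$k0) || p$k0 < 0) stop("'k0' must be a single nonnegative number")
  if (!num1(p$ke) || p$ke <= 0)
    stop("'ke' must be a single positive number (ke = 0 is degenerate)")
  if (!num1(p$f_central) || p$f_central <= 0 || p$f_central > 1)
    stop("'f_central' must lie in (0, 1]")
  if (!num1(p$q) || p$q < 0) stop("'q' must be a single nonnegative number")
  if (p$f_central < 1 && p$q <= 0)
    stop("two-compartment model (f_central < 1) requires q > 0")
  if (!num1(p$sigma2_add) || p$sigma2_add < 0) stop("'sigma2_add' must be >= 0")
  if (!num1(p$sigma2_prop) || p$sigma2_prop < 0) stop("'sigma2_prop' must be >= 0")
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cmt <- if (x$f_central < 1) "two-compartment" else "one-compartment"
  cat(sprintf("<pk_params> %s, %s error\n", cmt, x$error_model))
  cat(sprintf("  k0        = %g pmole/min (zero-order uptake)\n", x$k0))
  cat(sprintf("  ke        = %g /min (fractional clearance, V = 1 larva)\n", x$ke))
  if (x$f_central < 1)
    cat(sprintf("  f_central = %g, q = %g /min\n", x$f_central, x$q))
  cat(sprintf("  sigma2_add = %g pmole^2, sigma2_prop = %g\n",
              x$sigma2_add, x$sigma2_prop))
  invisible(x)
}

#' Dosing and sampling schedule for one pooled-larvae experiment
#'
#' Describes one experimental arm: larvae sit in drug-containing medium from
#' time 0 until `exposure_end` (use `Inf` for continuous exposure), after which
#' they are transferred to drug-free medium; pools of `pool_size` larvae are
#' destructively sampled at `sample_times`, `n_replicates` pools per time.
#'
#' @param medium_conc Drug concentration in the medium (mM). The medium is
#'   treated as an infinite source (2 mL of 1 mM holds far more drug than the
#'   larvae absorb), so it only labels the condition.
#' @param exposure_end Time of transfer to drug-free medium (min); `Inf` for
#'   continuous exposure.
#' @param sample_times Strictly increasing sampling times (min from start of
#'   exposure).
#' @param pool_size Larvae per pooled sample.
#' @param n_replicates Pools per time point.
#' @param loq Lower limit of quantification for the parent drug
#'   (pmole/larva); measurements below it are censored.
#' @return An object of class `exposure_design`.
#' @seealso [design_experiment1()], [design_experiment2()]
#' @export
exposure_design <- function(medium_conc = 1, exposure_end = Inf,
                            sample_times, pool_size = 5L, n_replicates = 3L,
                            loq = 0.02) {
  d <- structure(
    list(medium_conc = as.numeric(medium_conc),
         exposure_end = as.numeric(exposure_end),
         sample_times = as.numeric(sample_times),
         pool_size = as.integer(pool_size),
         n_replicates = as.integer(n_replicates),
         loq = as.numeric(loq)),
    class = "exposure_design")
  if (d$medium_conc <= 0) stop("'medium_conc' must be positive")
  if (length(d$sample_times) < 1L || any(d$sample_times < 0) ||
      is.unsorted(d$sample_times, strictly = TRUE))
    stop("'sample_times' must be strictly increasing and >= 0")
  if (d$pool_size < 1L) stop("'pool_size' must be >= 1")
  if (d$n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (d$exposure_end <= 0) stop("'exposure_end' must be positive")
  d
}

#' @export
print.exposure_design <- function(x, ...) {
  cat(sprintf("<exposure_design> %g mM medium, exposure to %s min\n",
              x$medium_conc,
              if (is.finite(x$exposure_end)) format(x$exposure_end) else "Inf"))
  cat(sprintf("  %d replicate pools of %d larvae at t = %s min; LOQ %g pmole/larva\n",
              x$n_replicates, x$pool_size,
              paste(x$sample_times, collapse = ", "), x$loq))
  invisible(x)
}

#' Default uptake experiment: continuous exposure
#'
#' Triplicate pools of five larvae in 1 mM medium, sampled after 10, 20, 30,
#' 40, 50, 60, 80, 100, 120 and 180 minutes of continuous exposure.
#' @return An [exposure_design()].
#' @export
design_experiment1 <- function() {
  exposure_design(medium_conc = 1, exposure_end = Inf,
                  sample_times = c(10, 20, 30, 40, 50, 60, 80, 100, 120, 180))
}

#' Default washout experiment: 1 h exposure then drug-free medium
#'
#' One hour in 1 mM medium, transfer to drug-free medium, triplicate pools
#' sampled 0-4 h after transfer (the extended grid of the repeated run).
#' @return An [exposure_design()].
#' @export
design_experiment2 <- function() {
  exposure_design(medium_conc = 1, exposure_end = 60,
                  sample_times = 60 + 60 * (0:4))
}

#' Convert sampling times from hours to minutes
#'
#' The package works in minutes internally; hour-scale schedules at the I/O
#' boundary are converted with this helper.
#' @param hours Numeric vector of times in hours.
#' @return Times in minutes.
#' @export
hours_to_minutes <- function(hours) 60 * as.numeric(hours)
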