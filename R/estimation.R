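#' Naive-pooled -2 log-likelihood of an observation table
#'
#' Objective function value (OFV) for the pooled analysis: all pools are
#' treated as draws around one shared prediction curve (destructive sampling
#' leaves no way to estimate inter-individual variability, so the likelihood
#' is the naive-pooled one). For observation `y_i` with model prediction
#' `f_i` and residual variance `g_i^2 = sigma2_add + sigma2_prop * f_i^2`,
#' `OFV = sum(log(g_i^2) + (y_i - f_i)^2 / g_i^2)`; the `n*log(2*pi)` constant
#' is omitted, so only OFV differences between models are meaningful.
#'
#' Only parent-drug rows enter the likelihood. Censored (below-LOQ) rows are
#' dropped by default; `censored_method = "M3"` instead adds their
#' `-2 log P(Y < LOQ)` contribution.
#'
#' @param params A [pk_params()] object (structural + error parameters).
#' @param obs An observation table; see [read_observations()] for columns.
#' @param designs Named list of [exposure_design()]s keyed by
#'   `experiment_id`.
#' @param censored_method `"drop"` (default) or `"M3"`.
#' @return The OFV (single number; `1e10` if any prediction or variance is
#'   non-finite, which keeps optimizers inside the valid region).
#' @export
objective_function <- function(params, obs, designs,
                               censored_method = c("drop", "M3")) {
  validate_pk_params(params)
  censored_method <- match.arg(censored_method)
  prep <- prep_obs_for_fit(obs, designs, censored_method)
  ofv_core(params, prep)
}

# Validate once and split by experiment so the likelihood can be evaluated
# thousands of times without touching the data frame again.
prep_obs_for_fit <- function(obs, designs, censored_method) {
  obs <- validate_observations(obs)
  obs <- obs[obs$analyte == "paracetamol", , drop = FALSE]
  if (nrow(obs) == 0L) stop("observation table has no parent-drug rows")
  cen <- as.logical(obs$censored)
  if (censored_method == "drop") {
    obs <- obs[!cen, , drop = FALSE]
    cen <- cen[!cen]
  }
  if (nrow(obs) == 0L) stop("all rows are censored; nothing to fit")
  ids <- unique(obs$experiment_id)
  lapply(ids, function(id) {
    if (is.null(designs[[id]]))
      stop("no exposure design supplied for experiment '", id, "'")
    sel <- obs$experiment_id == id
    list(design = designs[[id]], times = obs$time_min[sel],
         y = obs$amount[sel], cen = cen[sel], loq = obs$loq[sel])
  })
}

# prediction without per-call validation, for the optimizer's hot loop;
# exactly the same math as predict_profile()
predict_fast <- function(params, design, times) {
  tend <- design$exposure_end
  if (params$f_central >= 1) {
    sat <- params$k0 / params$ke
    out <- sat * (1 - exp(-params$ke * pmin(times, tend)))
    late <- times > tend
    if (any(late))
      out[late] <- out[late] * exp(-params$ke * (times[late] - tend))
    return(out)
  }
  two_cmt_analytic(params, design$exposure_end, times)
}

ofv_core <- function(params, prep) {
  ofv <- 0
  for (e in prep) {
    f <- tryCatch(predict_fast(params, e$design, e$times),
                  error = function(err) NULL)
    if (is.null(f) || any(!is.finite(f))) return(1e10)
    g2 <- params$sigma2_add + params$sigma2_prop * f^2
    if (any(!is.finite(g2)) || any(g2 <= 0)) return(1e10)
    nc <- !e$cen
    if (any(nc))
      ofv <- ofv + sum(log(g2[nc]) + (e$y[nc] - f[nc])^2 / g2[nc])
    if (any(e$cen)) {
      p_cen <- stats::pnorm((e$loq[e$cen] - f[e$cen]) / sqrt(g2[e$cen]))
      if (any(p_cen <= 0)) return(1e10)
      ofv <- ofv - 2 * sum(log(p_cen))
    }
  }
  if (!is.finite(ofv)) return(1e10)
  ofv
}

# Transform between the natural parameter list and the unconstrained
# optimization vector: log for positive parameters, logit for f_central.
fit_par_names <- function(model_label, error_model) {
  nm <- c("k0", "ke")
  if (model_label == "2cmt") nm <- c(nm, "f_central", "q")
  if (error_model %in% c("additive", "combined")) nm <- c(nm, "sigma2_add")
  if (error_model %in% c("proportional", "combined")) nm <- c(nm, "sigma2_prop")
  nm
}

par_to_vec <- function(p, names) {
  vapply(names, function(nm) {
    if (nm == "f_central") stats::qlogis(p[[nm]]) else log(p[[nm]])
  }, numeric(1))
}

vec_to_par <- function(v, names, error_model) {
  p <- list(k0 = NA_real_, ke = NA_real_, f_central = 1, q = 0,
            error_model = error_model, sigma2_add = 0, sigma2_prop = 0)
  for (i in seq_along(names)) {
    nm <- names[i]
    p[[nm]] <- if (nm == "f_central") stats::plogis(v[i]) else exp(v[i])
  }
  # floor the residual variances: on (near-)noise-free data the profiled
  # likelihood is unbounded as sigma2 -> 0, and the floor (sd 1e-5 pmole,
  # far below assay precision) keeps the objective finite without affecting
  # any realistic fit
  if ("sigma2_add" %in% names)
    p$sigma2_add <- max(p$sigma2_add, 1e-10)
  if ("sigma2_prop" %in% names)
    p$sigma2_prop <- max(p$sigma2_prop, 1e-10)
  class(p) <- "pk_params"
  p
}

default_init <- function(obs, model_label, error_model) {
  parent <- obs[obs$analyte == "paracetamol" & !obs$censored, , drop = FALSE]
  if (nrow(parent) == 0L)   # downstream validation reports the real problem
    return(list(k0 = 0.3, ke = 0.02, f_central = 0.8, q = 0.01,
                sigma2_add = 0.01, sigma2_prop = 0.04))
  y_bar <- tapply(parent$amount, parent$time_min, mean)
  tt <- as.numeric(names(y_bar))
  plateau <- max(y_bar)
  t1 <- min(tt[tt > 0])
  k0 <- max(unname(y_bar[as.character(t1)]) / t1, 1e-4)
  ke <- max(k0 / plateau, 1e-4)
  sd_guess <- max(0.1 * mean(parent$amount), 1e-3)
  list(k0 = k0, ke = ke, f_central = 0.8, q = ke / 2,
       sigma2_add = sd_guess^2, sigma2_prop = 0.04)
}

#' Fit the larval PK model by naive-pooled maximum likelihood
#'
#' Minimizes [objective_function()] over log-transformed parameters
#' (logit-transformed for the central volume fraction), so positivity and
#' range constraints hold by construction. The optimizer is quasi-Newton
#' (BFGS) with multi-start: the first start is `init`, the remaining
#' `n_starts - 1` are drawn log-uniformly within one decade of it under a
#' deterministic seed. Standard errors come from the inverse Hessian of
#' `OFV/2` at the optimum, mapped to the natural scale by the delta method.
#'
#' @param obs Observation table (see [read_observations()]); parent-drug rows
#'   are fitted, both experiments jointly with shared parameters.
#' @param designs Named list of [exposure_design()]s keyed by `experiment_id`.
#' @param model_label `"1cmt"` or `"2cmt"`.
#' @param error_model `"proportional"`, `"additive"` or `"combined"`.
#' @param init Optional named list of starting values (as in [pk_params()]);
#'   defaults to a heuristic from the data (initial slope for `k0`, plateau
#'   for `k0/ke`).
#' @param n_starts Number of optimization starts (default 5).
#' @param seed Seed for the multi-start draws (the global RNG state is left
#'   untouched).
#' @param censored_method Passed to [objective_function()].
#' @return A `pk_fit` object: `estimates` ([pk_params()]), `ofv`, `se`,
#'   `rse_percent`, `covariance` (natural scale), `converged`, `n_obs`,
#'   `model_label`, `error_model`.
#' @examples
#' cfg <- simulation_config(seed = 7)
#' obs <- rbind(simulate_experiment(cfg, "experiment1"),
#'              simulate_experiment(cfg, "experiment2"))
#' fit <- fit_pk_model(obs, cfg$designs)
#' fit
#' @export
fit_pk_model <- function(obs, designs, model_label = c("1cmt", "2cmt"),
                         error_model = c("proportional", "additive", "combined"),
                         init = NULL, n_starts = 5L, seed = 1L,
                         censored_method = c("drop", "M3")) {
  model_label <- match.arg(model_label)
  error_model <- match.arg(error_model)
  censored_method <- match.arg(censored_method)
  obs <- validate_observations(obs)
  nm <- fit_par_names(model_label, error_model)

  init_full <- default_init(obs, model_label, error_model)
  if (!is.null(init)) {
    init <- unclass(init)
    for (k in intersect(names(init), names(init_full)))
      if (is.numeric(init[[k]])) init_full[[k]] <- init[[k]]
  }
  n_parent <- sum(obs$analyte == "paracetamol" &
                    (censored_method == "M3" | !obs$censored))
  if (length(unique(obs$time_min[obs$analyte == "paracetamol"])) < 4L)
    warning("fewer than 4 distinct time points; (k0, ke) may not be identifiable")

  prep <- prep_obs_for_fit(obs, designs, censored_method)
  # the transforms keep every parameter in range by construction; overflow or
  # degenerate values surface as non-finite predictions, which ofv_core maps
  # to the 1e10 plateau
  fn <- function(v) {
    if (any(!is.finite(v))) return(1e10)
    ofv_core(vec_to_par(v, nm, error_model), prep)
  }

  # For a single-component error model without censored-likelihood terms the
  # ML residual variance has a closed form; profiling it out removes the
  # stiffest direction of the objective and is exact.
  any_cens <- any(vapply(prep, function(e) any(e$cen), logical(1)))
  profiled <- error_model %in% c("additive", "proportional") && !any_cens
  sig_nm <- if (error_model == "additive") "sigma2_add" else "sigma2_prop"
  nm_opt <- if (profiled) setdiff(nm, sig_nm) else nm
  profile_sigma2 <- function(p) {
    num <- 0; n_tot <- 0
    for (e in prep) {
      f <- tryCatch(predict_fast(p, e$design, e$times),
                    error = function(err) NULL)
      if (is.null(f) || any(!is.finite(f))) return(NA_real_)
      r <- e$y - f
      num <- num + if (error_model == "additive") sum(r^2) else {
        if (any(f <= 0)) return(NA_real_)
        sum((r / f)^2)
      }
      n_tot <- n_tot + length(r)
    }
    max(num / n_tot, 1e-10)
  }
  fn_opt <- if (!profiled) fn else function(v) {
    if (any(!is.finite(v))) return(1e10)
    p <- vec_to_par(v, nm_opt, error_model)
    s2 <- profile_sigma2(p)
    if (!is.finite(s2)) return(1e10)
    p[[sig_nm]] <- s2
    ofv_core(p, prep)
  }

  v0_opt <- par_to_vec(init_full, nm_opt)
  starts <- matrix(rep(v0_opt, n_starts), ncol = n_starts)
  if (n_starts > 1L) {
    pert <- with_preserved_seed(seed, {
      matrix(stats::runif(length(v0_opt) * (n_starts - 1L),
                          -log(10), log(10)),
             nrow = length(v0_opt))
    })
    starts[, -1L] <- starts[, -1L] + pert
  }
  if (model_label == "2cmt") {
    # extra start at the one-compartment limit so the richer model never
    # scores worse than the model it nests
    v_lim <- v0_opt
    v_lim[match("f_central", nm_opt)] <- stats::qlogis(0.999)
    v_lim[match("q", nm_opt)] <- log(init_full$ke)
    starts <- cbind(starts, v_lim)
  }

  best <- NULL
  for (j in seq_len(ncol(starts))) {
    res <- tryCatch(
      stats::optim(starts[, j], fn_opt, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")
  # polish the winning start with Nelder-Mead in case BFGS stalled on a kink
  res2 <- tryCatch(
    stats::optim(best$par, fn_opt, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-8)),
    error = function(e) best)
  conv <- (best$convergence == 0 || res2$convergence == 0) &&
    min(best$value, res2$value) < 1e9
  if (res2$value < best$value) best <- res2
  best$converged <- conv
  if (!conv) warning("optimization did not converge; results are the best attempt")

  if (profiled) {
    # reinstate the profiled variance in the full parameter vector
    p_opt <- vec_to_par(best$par, nm_opt, error_model)
    s2 <- profile_sigma2(p_opt)
    v_full <- numeric(length(nm))
    v_full[match(nm_opt, nm)] <- best$par
    v_full[match(sig_nm, nm)] <- log(s2)
    best$par <- v_full
  }
  est <- vec_to_par(best$par, nm, error_model)
  validate_pk_params(est)

  # SE from the inverse Hessian of OFV/2, delta method to natural scale
  se <- rep(NA_real_, length(nm)); names(se) <- nm
  cov_nat <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  H <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
  singular <- TRUE
  if (!is.null(H)) {
    cov_log <- tryCatch(solve(0.5 * H), error = function(e) NULL)
    if (!is.null(cov_log) && all(is.finite(cov_log)) &&
        all(diag(cov_log) > 0)) {
      theta <- vapply(nm, function(k) est[[k]], numeric(1))
      jac <- ifelse(nm == "f_central", theta * (1 - theta), theta)
      cov_nat <- diag(jac) %*% cov_log %*% diag(jac)
      dimnames(cov_nat) <- list(nm, nm)
      se <- sqrt(diag(cov_nat))
      singular <- FALSE
    }
  }

  theta <- vapply(nm, function(k) est[[k]], numeric(1))
  structure(
    list(estimates = est,
         ofv = best$value,
         se = se,
         rse_percent = 100 * se / theta,
         covariance = cov_nat,
         converged = isTRUE(best$converged),
         se_defined = !singular,
         n_obs = n_parent,
         model_label = model_label,
         error_model = error_model,
         par_names = nm,
         par_log = best$par,
         designs = designs,
         censored_method = censored_method),
    class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %s / %s error; OFV = %.3f; n = %d; converged: %s\n",
              x$model_label, x$error_model, x$ofv, x$n_obs, x$converged))
  est <- vapply(x$par_names, function(k) x$estimates[[k]], numeric(1))
  tab <- data.frame(estimate = signif(est, 4),
                    se = signif(x$se, 3),
                    rse_percent = round(x$rse_percent, 1))
  print(tab)
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  vapply(object$par_names, function(k) object$estimates[[k]], numeric(1))
}

#' Likelihood-ratio comparison of two nested pooled fits
#'
#' Decides between a reduced and a full model from the drop in objective
#' function value: the full model is preferred when
#' `OFV_reduced - OFV_full > qchisq(0.95, df)` — for one degree of freedom
#' the familiar 3.84-point criterion (p < 0.05).
#'
#' @param fit_reduced,fit_full `pk_fit` objects; `fit_reduced` must be nested
#'   in `fit_full` (one-compartment within two-compartment, or
#'   additive/proportional error within combined, all else equal).
#' @param df Degrees of freedom of the comparison (default 1, the criterion
#'   used for model selection here).
#' @return A list: `decision` (`"keep_reduced"` or `"prefer_full"`),
#'   `delta_ofv`, `threshold`, `p_value`, `df`.
#' @export
lrt_compare <- function(fit_reduced, fit_full, df = 1L) {
  stopifnot(inherits(fit_reduced, "pk_fit"), inherits(fit_full, "pk_fit"))
  if (df < 1L) stop("'df' must be >= 1")
  cmt_nested <- (fit_reduced$model_label == fit_full$model_label) ||
    (fit_reduced$model_label == "1cmt" && fit_full$model_label == "2cmt")
  err_nested <- (fit_reduced$error_model == fit_full$error_model) ||
    (fit_full$error_model == "combined")
  same <- fit_reduced$model_label == fit_full$model_label &&
    fit_reduced$error_model == fit_full$error_model
  if (!cmt_nested || !err_nested || same)
    stop("'fit_reduced' is not nested in 'fit_full'")
  delta <- fit_reduced$ofv - fit_full$ofv
  threshold <- stats::qchisq(0.95, df)
  list(decision = if (delta > threshold) "prefer_full" else "keep_reduced",
       delta_ofv = delta,
       threshold = threshold,
       p_value = stats::pchisq(max(delta, 0), df, lower.tail = FALSE),
       df = as.integer(df))
}

#' Weighted-residual diagnostics for a pooled fit
#'
#' Returns per-observation predictions and weighted residuals
#' `(y - f) / g`, with `g` the fitted residual standard deviation at each
#' prediction. With no random effects in the pooled model, conditional
#' weighted residuals reduce to exactly this quantity. The table supports the
#' usual goodness-of-fit plots: predicted vs observed, residuals vs time,
#' residuals vs predicted.
#'
#' @param fit A converged `pk_fit`.
#' @param obs The observation table the fit used.
#' @return A data frame with columns `experiment_id`, `replicate`, `time_min`,
#'   `observation`, `prediction`, `weighted_residual`.
#' @export
residual_diagnostics <- function(fit, obs) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!fit$converged) stop("residual diagnostics require a converged fit")
  obs <- validate_observations(obs)
  obs <- obs[obs$analyte == "paracetamol" & !obs$censored, , drop = FALSE]
  p <- fit$estimates
  f <- numeric(nrow(obs))
  for (id in unique(obs$experiment_id)) {
    sel <- obs$experiment_id == id
    f[sel] <- predict_profile(p, fit$designs[[id]], obs$time_min[sel])
  }
  g <- sqrt(p$sigma2_add + p$sigma2_prop * f^2)
  data.frame(experiment_id = obs$experiment_id,
             replicate = obs$replicate,
             time_min = obs$time_min,
             observation = obs$amount,
             prediction = f,
             weighted_residual = (obs$amount - f) / g)
}

# Run an expression with a fixed seed without disturbing the caller's RNG.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
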