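obs_columns <- c("experiment_id", "replicate", "time_min", "analyte",
                 "amount", "censored", "loq")

# full-precision CSV write so numeric tables round-trip exactly
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

validate_observations <- function(obs) {
  if (!is.data.frame(obs)) stop("observation table must be a data frame")
  missing_cols <- setdiff(obs_columns, names(obs))
  if (length(missing_cols))
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  obs$time_min <- as.numeric(obs$time_min)
  obs$amount <- as.numeric(obs$amount)
  obs$censored <- as.logical(obs$censored)
  obs$loq <- as.numeric(obs$loq)
  bad <- which(obs$time_min < 0 | !is.finite(obs$time_min))
  if (length(bad)) stop("negative or non-finite time_min in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!obs$censored & (is.na(obs$amount) | obs$amount < 0))
  if (length(bad)) stop("negative or missing amount in non-censored row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(obs$experiment_id, obs$replicate, obs$time_min, obs$analyte)
  if (anyDuplicated(key))
    stop("duplicate (experiment, replicate, time, analyte) row(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  obs
}

validate_weight_table <- function(w) {
  if (!is.data.frame(w) ||
      !all(c("n_larvae", "total_weight_mg") %in% names(w)))
    stop("weight table needs columns n_larvae, total_weight_mg")
  if (any(w$n_larvae < 1)) stop("n_larvae must be >= 1")
  if (any(w$total_weight_mg <= 0)) stop("total_weight_mg must be positive")
  w
}

validate_species_table <- function(sp) {
  need <- c("species", "life_stage", "bodyweight_kg", "clearance_l_per_h")
  if (!is.data.frame(sp) || !all(need %in% names(sp)))
    stop("species table needs columns ", paste(need, collapse = ", "))
  if (!all(sp$life_stage %in% c("mature", "immature")))
    stop("life_stage must be 'mature' or 'immature'")
  if (any(sp$bodyweight_kg <= 0)) stop("bodyweight_kg must be positive")
  if (any(sp$clearance_l_per_h <= 0)) stop("clearance_l_per_h must be positive")
  sp
}

#' Read or write observation tables as CSV
#'
#' The on-disk format has columns `experiment_id`, `replicate`, `time_min`,
#' `analyte`, `amount_pmole_per_larva`, `censored` (0/1),
#' `loq_pmole_per_larva`; in memory the amount/loq columns are called
#' `amount` and `loq`. Reading validates row-level constraints (nonnegative
#' times and amounts, unique keys) and reports offending rows.
#'
#' @param path CSV file path.
#' @param obs In-memory observation table.
#' @return `read_observations()` returns the validated data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(amount_pmole_per_larva = "amount", loq_pmole_per_larva = "loq")
  for (k in names(ren))
    if (k %in% names(raw)) names(raw)[names(raw) == k] <- ren[[k]]
  validate_observations(raw)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  out <- obs
  out$censored <- as.integer(out$censored)
  names(out)[names(out) == "amount"] <- "amount_pmole_per_larva"
  names(out)[names(out) == "loq"] <- "loq_pmole_per_larva"
  write_csv_exact(out, path)
  invisible(path)
}

#' Read or write pooled weight tables as CSV
#'
#' Columns `n_larvae`, `total_weight_mg`.
#' @param path CSV file path.
#' @param weights Weight table.
#' @return The validated data frame, or `path` invisibly for the writer.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_weight_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_weight_table
#' @export
write_weight_table <- function(weights, path) {
  weights <- validate_weight_table(weights)
  write_csv_exact(weights, path)
  invisible(path)
}

#' Read or write species clearance tables as CSV
#'
#' Columns `species`, `life_stage` (`mature`/`immature`), `bodyweight_kg`,
#' `clearance_l_per_h`.
#' @param path CSV file path.
#' @param species Species clearance table.
#' @return The validated data frame, or `path` invisibly for the writer.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_species_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_species_table
#' @export
write_species_table <- function(species, path) {
  species <- validate_species_table(species)
  write_csv_exact(species, path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic defaults
#'
#' End-to-end driver: simulate both experiments, fit the one- and
#' two-compartment models under all three residual-error models, apply the
#' likelihood-ratio model selection, compute residual diagnostics for the
#' selected model, estimate the larval volume from simulated pool weights,
#' convert the fitted fractional clearance to an absolute clearance, fit the
#' allometric relationship to a simulated species table and classify the
#' larval clearance against its prediction interval. All randomness derives
#' from `config$seed`, which is embedded in the returned report.
#'
#' @param config A [simulation_config()]; defaults to the study conditions.
#' @param out_dir Optional directory; when given, observation/weight/species
#'   CSVs and a JSON report (estimates, RSE%, OFV grid, LRT decisions,
#'   volume, absolute clearance, allometric fit, classification, seed) are
#'   written there.
#' @param models,error_models Model grid to fit.
#' @return A `pk_report` list (invisibly printed components; see details in
#'   the vignette).
#' @export
run_pipeline <- function(config = simulation_config(),
                         out_dir = NULL,
                         models = c("1cmt", "2cmt"),
                         error_models = c("additive", "proportional",
                                          "combined")) {
  stopifnot(inherits(config, "simulation_config"))
  obs <- do.call(rbind, lapply(names(config$designs), function(nm)
    simulate_experiment(config, nm)))

  fits <- list()
  for (ml in models) for (em in error_models) {
    key <- paste(ml, em, sep = "_")
    fits[[key]] <- fit_pk_model(obs, config$designs, model_label = ml,
                                error_model = em, seed = config$seed)
  }
  ofv_grid <- data.frame(
    model = vapply(fits, function(f) f$model_label, character(1)),
    error_model = vapply(fits, function(f) f$error_model, character(1)),
    ofv = vapply(fits, function(f) f$ofv, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    row.names = NULL)

  # structural selection at the 3.84-point criterion, per error model
  lrt <- list()
  if (all(c("1cmt", "2cmt") %in% models)) {
    lrt <- lapply(error_models, function(em) {
      lrt_compare(fits[[paste0("1cmt_", em)]], fits[[paste0("2cmt_", em)]],
                  df = 1L)
    })
    names(lrt) <- error_models
  }
  prop_fit <- fits[["1cmt_proportional"]]
  best_fit <- if (!is.null(prop_fit)) prop_fit else fits[[1L]]
  diag_tab <- residual_diagnostics(best_fit, obs)

  wt <- simulate_pool_weights(config)
  vol <- estimate_larval_volume(wt)
  abs_cl <- absolute_clearance(best_fit$estimates$ke, vol$volume)

  sp <- simulate_species_clearances(config)
  allo <- fit_allometry(sp, subset = "mature")
  larva <- data.frame(species = "zebrafish_larva", life_stage = "immature",
                      bodyweight_kg = vol$mean_weight * 1e-6,
                      clearance_l_per_h = abs_cl)
  cls <- classify_point(allo, larva)

  report <- structure(
    list(seed = config$seed, observations = obs, fits = fits,
         ofv_grid = ofv_grid, lrt = lrt, selected_fit = best_fit,
         diagnostics = diag_tab, weights = wt, volume = vol,
         absolute_clearance = abs_cl, species = sp, allometry = allo,
         larva_classification = cls),
    class = "pk_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_observations(obs, file.path(out_dir, "observations.csv"))
    write_weight_table(wt, file.path(out_dir, "pool_weights.csv"))
    write_species_table(sp, file.path(out_dir, "species_clearances.csv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      js <- list(seed = config$seed,
                 estimates = coef(best_fit),
                 rse_percent = best_fit$rse_percent,
                 ofv_grid = ofv_grid,
                 lrt = lapply(lrt, function(l)
                   l[c("decision", "delta_ofv", "threshold", "p_value")]),
                 volume_ul = vol$volume,
                 mean_weight_mg = vol$mean_weight,
                 absolute_clearance_l_per_h = abs_cl,
                 allometry = list(a = allo$a, exponent = allo$exponent,
                                  r2 = allo$r2, n = allo$n),
                 larva_classification = cls)
      jsonlite::write_json(js, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  report
}

#' @export
print.pk_report <- function(x, ...) {
  cat("== Larval PK pipeline report (seed", x$seed, ") ==\n\n")
  cat("OFV grid:\n"); print(x$ofv_grid)
  cat("\nLRT (1cmt vs 2cmt, 3.84-point criterion):\n")
  for (em in names(x$lrt))
    cat(sprintf("  %-12s dOFV = %6.2f -> %s\n", em,
                x$lrt[[em]]$delta_ofv, x$lrt[[em]]$decision))
  cat("\nSelected fit:\n"); print(x$selected_fit)
  cat(sprintf("\nLarval volume: %.4g uL (mean weight %.4g mg)\n",
              x$volume$volume, x$volume$mean_weight))
  cat(sprintf("Absolute clearance: %.4g L/h\n", x$absolute_clearance))
  cat(sprintf("Allometry (mature): CL = %.3g * BW^%.3f, r2 = %.3f\n",
              x$allometry$a, x$allometry$exponent, x$allometry$r2))
  cat(sprintf("Larval point: %s (%s)\n",
              x$larva_classification$classification,
              x$larva_classification$direction))
  invisible(x)
}

#' Plot observed and model-predicted amounts over time
#'
#' Observed pooled amounts (points) with the fitted model curve (lines), one
#' panel per experiment.
#'
#' @param fit A converged `pk_fit`.
#' @param obs The observation table used for the fit.
#' @return A ggplot object.
#' @export
plot_fit <- function(fit, obs) {
  stopifnot(inherits(fit, "pk_fit"))
  obs <- validate_observations(obs)
  obs <- obs[obs$analyte == "paracetamol" & !obs$censored, ]
  curves <- do.call(rbind, lapply(names(fit$designs), function(id) {
    d <- fit$designs[[id]]
    tt <- seq(0, max(d$sample_times), length.out = 200)
    data.frame(experiment_id = id, time_min = tt,
               amount = predict_profile(fit$estimates, d, tt))
  }))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_min, y = .data$amount)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~experiment_id, scales = "free_x") +
    ggplot2::labs(x = "Time (min)", y = "Amount (pmole/larva)") +
    ggplot2::theme_bw()
}

#' Double-log allometric plot with confidence and prediction bands
#'
#' Species clearances versus bodyweight on log10-log10 axes, with the fitted
#' power law, its confidence band (darker) and prediction band (lighter).
#'
#' @param fit An `allometric_fit`.
#' @param records The species table (all life stages; points are coloured by
#'   life stage).
#' @param extra Optional extra records (e.g. the larval point) drawn as open
#'   triangles.
#' @param level Band confidence level.
#' @return A ggplot object.
#' @export
plot_allometry <- function(fit, records, extra = NULL, level = 0.95) {
  records <- validate_species_table(records)
  bw_range <- range(records$bodyweight_kg)
  if (!is.null(extra)) bw_range <- range(bw_range, extra$bodyweight_kg)
  grid <- 10^seq(log10(bw_range[1]) - 0.5, log10(bw_range[2]) + 0.5,
                 length.out = 200)
  bands <- predict_with_intervals(fit, grid, level)
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$bodyweight_kg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lower,
                                      ymax = .data$pi_upper),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cl_pred), linetype = "dashed") +
    ggplot2::geom_point(data = records,
                        ggplot2::aes(y = .data$clearance_l_per_h,
                                     colour = .data$life_stage)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Bodyweight (kg)", y = "Clearance (L/h)",
                  colour = "Life stage") +
    ggplot2::theme_bw()
  if (!is.null(extra))
    p <- p + ggplot2::geom_point(data = extra,
                                 ggplot2::aes(y = .data$clearance_l_per_h),
                                 shape = 2, size = 3, colour = "red")
  p
}
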