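designs <- list(experiment1 = design_experiment1(),
                experiment2 = design_experiment2())

one_obs <- function(y, t = 60, id = "experiment1") {
  data.frame(experiment_id = id, replicate = 1L, time_min = t,
             analyte = "paracetamol", amount = y, censored = FALSE,
             loq = 0.02)
}

test_that("objective function reproduces hand-computed values", {
  # single obs, additive sigma2 = 1: OFV = log 1 + (y - f)^2
  p <- pk_params(k0 = 1, ke = 1, error_model = "additive",
                 sigma2_add = 1, sigma2_prop = 0)
  # at t = 60, f = k0/ke = 1 to 26 digits
  expect_equal(objective_function(p, one_obs(1), designs), 0,
               tolerance = 1e-12)
  expect_equal(objective_function(p, one_obs(2), designs), 1,
               tolerance = 1e-12)
  # proportional error: log(s2 f^2) + (y-f)^2/(s2 f^2)
  pp <- pk_params(k0 = 0.289, ke = 0.017, sigma2_prop = 0.01)
  f <- amount_uptake(pp, 60)
  y <- 1.1 * f
  expect_equal(objective_function(pp, one_obs(y), designs),
               log(0.01 * f^2) + (0.1 * f)^2 / (0.01 * f^2),
               tolerance = 1e-10)
  expect_error(objective_function(pp, one_obs(1)[0, ], designs), "no parent")
})

test_that("OFV is invariant to row order and consistent unit rescaling", {
  cfg <- simulation_config(seed = 11)
  obs <- make_obs(cfg)
  p <- cfg$true_params
  o1 <- objective_function(p, obs, designs)
  o2 <- objective_function(p, obs[sample(nrow(obs)), ], designs)
  expect_equal(o1, o2)
  # hours everywhere: times/60, rates*60 — identical predictions and OFV
  obs_h <- obs
  obs_h$time_min <- obs$time_min / 60
  designs_h <- lapply(designs, function(d) {
    d$sample_times <- d$sample_times / 60
    d$exposure_end <- d$exposure_end / 60
    d
  })
  p_h <- pk_params(k0 = p$k0 * 60, ke = p$ke * 60,
                   sigma2_prop = p$sigma2_prop)
  expect_equal(objective_function(p_h, obs_h, designs_h), o1,
               tolerance = 1e-10)
})

test_that("OFV at the truth beats perturbed parameters on average", {
  better <- 0
  n <- 40
  for (i in seq_len(n)) {
    cfg <- simulation_config(seed = 3000 + i)
    obs <- make_obs(cfg)
    truth <- cfg$true_params
    pert <- pk_params(k0 = truth$k0 * 1.3, ke = truth$ke * 0.7,
                      sigma2_prop = truth$sigma2_prop)
    if (objective_function(truth, obs, designs) <
        objective_function(pert, obs, designs)) better <- better + 1
  }
  expect_gt(better / n, 0.9)
})

test_that("noise-free data are recovered almost exactly", {
  cfg <- noise_free_config(seed = 5)
  obs <- make_obs(cfg)
  fit <- fit_pk_model(obs, cfg$designs, error_model = "additive",
                      init = list(k0 = 0.2, ke = 0.02, sigma2_add = 0.1))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$k0 / 0.289 - 1), 1e-3)
  expect_lt(abs(fit$estimates$ke / 0.017 - 1), 1e-3)
})

test_that("multi-start recovers the optimum from a far-off initial guess", {
  cfg <- simulation_config(seed = 21)
  obs <- make_obs(cfg)
  fit_near <- fit_pk_model(obs, cfg$designs, seed = 1)
  fit_far <- fit_pk_model(obs, cfg$designs, seed = 1,
                          init = list(k0 = 2.89, ke = 0.0017))
  expect_lt(abs(fit_far$ofv - fit_near$ofv), 1e-4)
  expect_lt(abs(fit_far$estimates$k0 - fit_near$estimates$k0), 1e-3)
})

test_that("adding parameters never increases the optimal OFV", {
  cfg <- simulation_config(seed = 31)
  obs <- make_obs(cfg)
  f_add <- fit_pk_model(obs, cfg$designs, error_model = "additive")
  f_prop <- fit_pk_model(obs, cfg$designs, error_model = "proportional")
  f_comb <- fit_pk_model(obs, cfg$designs, error_model = "combined")
  expect_lte(f_comb$ofv, f_add$ofv + 1e-6)
  expect_lte(f_comb$ofv, f_prop$ofv + 1e-6)
  f_2cmt <- suppressWarnings(
    fit_pk_model(obs, cfg$designs, model_label = "2cmt"))
  expect_lte(f_2cmt$ofv, f_prop$ofv + 1e-6)
})

test_that("estimator bias shrinks as replication grows", {
  bias_at <- function(nrep, seeds) {
    des <- list(
      experiment1 = exposure_design(
        sample_times = design_experiment1()$sample_times,
        n_replicates = nrep),
      experiment2 = exposure_design(
        exposure_end = 60, sample_times = design_experiment2()$sample_times,
        n_replicates = nrep))
    err <- vapply(seeds, function(s) {
      cfg <- simulation_config(seed = s, designs = des)
      fit <- fit_pk_model(make_obs(cfg), des, seed = s)
      abs(fit$estimates$ke / 0.017 - 1)
    }, numeric(1))
    mean(err)
  }
  seeds <- 4000 + 1:12
  e3 <- bias_at(3, seeds)
  e30 <- bias_at(30, seeds)
  expect_lt(e30, e3)
})

test_that("likelihood-ratio decisions follow the 3.84-point criterion", {
  fit1 <- structure(list(model_label = "1cmt", error_model = "proportional",
                         ofv = 100), class = "pk_fit")
  fit2 <- structure(list(model_label = "2cmt", error_model = "proportional",
                         ofv = 100 - 3.85), class = "pk_fit")
  res <- lrt_compare(fit1, fit2, df = 1)
  expect_identical(res$decision, "prefer_full")
  expect_lt(res$p_value, 0.05)
  fit2$ofv <- 100
  expect_identical(lrt_compare(fit1, fit2, df = 1)$decision, "keep_reduced")
  # non-nested pairs are rejected
  fit_add <- structure(list(model_label = "1cmt", error_model = "additive",
                            ofv = 99), class = "pk_fit")
  expect_error(lrt_compare(fit_add, fit2, df = 1), "nested")
  expect_error(lrt_compare(fit1, fit1, df = 1), "nested")
})

test_that("weighted residuals are (y - f)/g and well calibrated", {
  cfg <- simulation_config(seed = 41)
  obs <- make_obs(cfg)
  fit <- fit_pk_model(obs, cfg$designs)
  d <- residual_diagnostics(fit, obs)
  expect_identical(nrow(d), fit$n_obs)
  # hand check one row
  i <- 7
  g <- sqrt(fit$estimates$sigma2_prop * d$prediction[i]^2)
  expect_equal(d$weighted_residual[i],
               (d$observation[i] - d$prediction[i]) / g, tolerance = 1e-12)
  # calibration across several datasets (n = 45 * 7 > 300)
  wr <- unlist(lapply(1:7, function(s) {
    cfg <- simulation_config(seed = 600 + s)
    obs <- make_obs(cfg)
    fit <- fit_pk_model(obs, cfg$designs, seed = s)
    residual_diagnostics(fit, obs)$weighted_residual
  }))
  expect_lt(abs(mean(wr)), 0.1)
  expect_gt(stats::var(wr), 0.8)
  expect_lt(stats::var(wr), 1.2)
})

test_that("inverse-Hessian standard errors agree with a pool bootstrap", {
  cfg <- simulation_config(seed = 51)
  obs <- make_obs(cfg)
  fit <- fit_pk_model(obs, cfg$designs)
  # resample pools (time x replicate rows) within each experiment
  set.seed(99)
  B <- 200
  boots <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    res <- do.call(rbind, lapply(split(obs, obs$experiment_id), function(e) {
      e2 <- e[sample(nrow(e), replace = TRUE), ]
      e2$replicate <- seq_len(nrow(e2))  # restore key uniqueness
      e2
    }))
    # bootstrap refits start at the full-data MLE, as usual
    fb <- tryCatch(fit_pk_model(res, cfg$designs, n_starts = 1, seed = b,
                                init = fit$estimates),
                   error = function(err) NULL)
    if (!is.null(fb)) boots[b, ] <- c(fb$estimates$k0, fb$estimates$ke)
  }
  sd_boot <- apply(boots, 2, stats::sd, na.rm = TRUE)
  expect_lt(abs(fit$se[["k0"]] / sd_boot[1] - 1), 0.2)
  expect_lt(abs(fit$se[["ke"]] / sd_boot[2] - 1), 0.2)
})

test_that("all-censored tables and missing designs raise clean errors", {
  obs <- one_obs(0.01)
  obs$censored <- TRUE
  expect_error(objective_function(pk_params(), obs, designs), "censored")
  obs2 <- one_obs(5, id = "mystery")
  expect_error(objective_function(pk_params(), obs2, designs), "design")
})

test_that("M3 censored handling uses the censoring probability", {
  p <- pk_params(k0 = 0.289, ke = 0.017, error_model = "additive",
                 sigma2_add = 4, sigma2_prop = 0)
  obs <- one_obs(0.01, t = 10)
  obs$censored <- TRUE
  f <- amount_uptake(p, 10)
  expected <- -2 * log(stats::pnorm((0.02 - f) / 2))
  expect_equal(objective_function(p, obs, designs, censored_method = "M3"),
               expected, tolerance = 1e-10)
})
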