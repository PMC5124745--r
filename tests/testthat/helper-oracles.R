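# Independent numeric oracles used to check the closed-form model code.

# One-compartment ODE dA/dt = k0 * I(t <= tend) - ke * A, solved with lsoda.
ode_oracle_1cmt <- function(k0, ke, tend, times) {
  deriv <- function(t, y, parms) {
    input <- if (t <= parms$tend) parms$k0 else 0
    list(input - parms$ke * y)
  }
  grid <- sort(unique(c(0, times, if (is.finite(tend)) tend)))
  grid <- grid[grid <= max(times) | grid == 0]
  sol <- deSolve::lsoda(c(A = 0), grid, deriv,
                        parms = list(k0 = k0, ke = ke, tend = tend),
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[match(times, sol[, "time"]), "A"])
}

# Fine-grid explicit Euler for the two-compartment amounts; deliberately
# naive so it shares nothing with the package's analytic path.
euler_oracle_2cmt <- function(k0, ke, f_central, q, tend, t_out, dt = 0.001) {
  v1 <- f_central; v2 <- 1 - f_central
  a1 <- 0; a2 <- 0; t <- 0
  n <- ceiling(t_out / dt)
  for (i in seq_len(n)) {
    input <- if (t < tend) k0 else 0
    c1 <- a1 / v1; c2 <- a2 / v2
    da1 <- input - ke * c1 - q * (c1 - c2)
    da2 <- q * (c1 - c2)
    a1 <- a1 + dt * da1
    a2 <- a2 + dt * da2
    t <- t + dt
  }
  a1 + a2
}

random_valid_params <- function(n, seed = 424242) {
  set.seed(seed)
  data.frame(k0 = stats::runif(n, 0.05, 1),
             ke = stats::runif(n, 0.005, 0.05))
}

make_obs <- function(cfg) {
  rbind(simulate_experiment(cfg, "experiment1"),
        simulate_experiment(cfg, "experiment2"))
}

noise_free_config <- function(seed = 1, k0 = 0.289, ke = 0.017) {
  simulation_config(
    true_params = pk_params(k0 = k0, ke = ke, sigma2_prop = 0, sigma2_add = 0),
    seed = seed)
}
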