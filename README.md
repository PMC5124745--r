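# zfpk — compartmental pharmacokinetics of paracetamol in zebrafish larvae

Zebrafish larvae (3 days post-fertilization) are screened for drug effects
in pooled, destructive experiments: pools of five larvae are lysed and the
drug amount per larva is quantified once per pool. `zfpk` is for
pharmacologists analyzing such data. It implements, end to end:

* a **compartmental uptake/washout model** — zero-order uptake from an
  effectively infinite drug-containing medium at rate *k*₀ (pmole/min) and
  first-order elimination at fractional clearance *k*ₑ (per min; the
  distribution volume is fixed to one larva, so *k*ₑ = CL/V). Under
  continuous exposure, A(t) = (*k*₀/*k*ₑ)(1 − e^(−*k*ₑ·t)); after transfer
  to drug-free medium at *t*ₑₙₐ, A decays as A(*t*ₑₙₐ)·e^(−*k*ₑ·Δt). A
  two-compartment alternative (central volume fraction, inter-compartmental
  exchange) is solved exactly by matrix exponential;
* **naive-pooled maximum-likelihood estimation** with additive,
  proportional, or combined residual-error models, the NONMEM-style
  objective OFV = Σ[ln g² + (y − f)²/g²], likelihood-ratio model selection
  (ΔOFV > 3.84 at df = 1), inverse-Hessian standard errors (RSE%), and
  weighted-residual diagnostics;
* **larval volume estimation** — through-origin regression of pooled wet
  weights on larvae counts, divided by the density of water at 25 °C
  (0.997 g/mL) — and conversion of the fractional clearance into an
  **absolute clearance** (L/h);
* **cross-species allometric scaling** CL = a·BW^exp, fitted by OLS on the
  double-log scale, with 95% confidence and prediction intervals and
  classification of external points (is the larval clearance inside or
  below the prediction band of the mature-vertebrate relationship?);
* a **synthetic-data generator** reproducing the two experimental designs
  (continuous exposure sampled 10–180 min; 1-h exposure then washout
  sampled 0–4 h; triplicate pools of five; proportional error; LOQ
  censoring at 0.02 pmole/larva), pooled weighings, metabolite cascades,
  and power-law species tables — so the whole pipeline is testable without
  any external data.

## Worked example

Simulate both experiments under the default study conditions, fit the
one-compartment model, estimate the larval volume, and place the larva on
the allometric scale:

```r
library(zfpk)

cfg <- simulation_config(seed = 1)
obs <- rbind(simulate_experiment(cfg, "experiment1"),
             simulate_experiment(cfg, "experiment2"))

fit <- fit_pk_model(obs, cfg$designs, model_label = "1cmt",
                    error_model = "proportional")
fit
#> <pk_fit> 1cmt / proportional error; OFV = -39.242; n = 45; converged: TRUE
#>             estimate       se rse_percent
#> k0          0.299600 0.004670         1.6
#> ke          0.017260 0.000156         0.9
#> sigma2_prop 0.006322 0.001340        21.2
```

One synthetic dataset of 45 pools gives *k*₀ ≈ 0.30 pmole/min and
*k*ₑ ≈ 0.0173/min — i.e. about 1.7% of the larval volume cleared per minute
— with relative standard errors of a few percent; the residual-error
variance is, as usual, the least precisely estimated quantity.

```r
vol <- estimate_larval_volume(simulate_pool_weights(cfg))
vol
#> <larval_volume> mean wet weight 0.2955 mg/larva, density 0.997 g/mL
#>   volume 0.2964 uL/larva (from 6 pools)

absolute_clearance(fit$estimates$ke, vol$volume)
#> 3.069e-07   # L/h

allo <- fit_allometry(simulate_species_clearances(cfg), subset = "mature")
allo
#> <allometric_fit> CL = 0.7666 * BW^0.778  (subset: mature, n = 30)
#>   r2 = 0.8915, residual sd (log10) = 0.3810

larva <- data.frame(species = "zebrafish_larva", life_stage = "immature",
                    bodyweight_kg = 2.9e-7,
                    clearance_l_per_h = absolute_clearance(fit$estimates$ke,
                                                           vol$volume))
classify_point(allo, larva)$classification
#> "outside_PI"   # direction: "over_predicted"
```

The ~0.3 µL larva clears ~3×10⁻⁷ L/h of its volume equivalent; the
mature-vertebrate power law (exponent ≈ 0.78, r² ≈ 0.89 on this draw)
over-predicts that value — the larval point falls below the 95% prediction
band, as expected for an immature animal.

`run_pipeline(simulation_config(seed = 1))` chains all of the above (model
grid, LRT table, diagnostics, volume, allometry) into one report object and
can write CSV/JSON artifacts; `plot_fit()` and `plot_allometry()` draw the
observed-vs-predicted time courses and the double-log allometric plot with
its confidence/prediction bands.

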