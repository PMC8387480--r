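# feno2cm

Estimation of airway and alveolar nitric oxide parameters from
multiple-flow exhaled NO (FeNO) maneuvers, and of covariate effects on
those parameters, under the steady-state two-compartment model

```
FeNO(flow) = C_aw + (C_A − C_aw) · exp(−D_aw / flow)
```

with `C_A` the alveolar NO concentration (ppb), `C_aw` the airway-wall
concentration (ppb) and `D_aw` the airway diffusing capacity
(pL·s⁻¹·ppb⁻¹). FeNO is a non-invasive airway-inflammation biomarker;
measuring it at several expiratory flows lets airway and alveolar
inflammation be separated, and epidemiological interest centres on how a
covariate `X` (air-pollution exposure, asthma, …) relates to the three NO
parameters across a cohort.

The package is aimed at biostatisticians comparing estimation strategies
for such studies. It implements, behind one common effect-estimate layout:

* **Two-stage methods** — per-participant Stage-I estimators
  (`nls_fit()`: log-transform-both-sides nonlinear least squares;
  `hma_fit()`: the iterative third-order three-flow algorithm;
  `nlme_fit(unified = FALSE)`: population NLME with empirical-Bayes
  participant estimates) followed by per-parameter OLS of the estimates on
  `X` (`stage2_ols()`), deliberately ignoring Stage-I uncertainty as
  applied work does.
* **Unified methods** — `nlme_fit(unified = TRUE)` puts `X` in the NLME
  mean functions; `uhb_fit()` is a unified hierarchical Bayesian model
  (log-normal maneuver level, truncated-MVN subject level with
  `C_A ≥ 0`, diffuse priors) fitted by a vectorised
  Metropolis-within-Gibbs sampler with the Gelman–Rubin
  R̂ ≤ 1.1 / retained-sample re-check protocol.
* **A synthetic-data generator** (`simulate_dataset()`) reproducing the
  reference simulation design (standard-normal `X`, truncated-MVN NO
  parameters, two maneuvers at each of 30/50/100/300 mL/s), and
* **a simulation-study harness** (`run_replicate()`, `run_scenario()`,
  `aggregate_metrics()`) computing bias, relative bias, 95%-interval
  coverage and length, power and type-I error, with the
  all-methods-converged filter.

The methods vignette (`vignettes/feno-methods.Rmd`) documents the model,
the sampler, every tunable default and the package's design choices.

## Worked example

Simulate a 500-participant study in which `X` raises only the alveolar
concentration (`beta = (0.2, 0, 0)`), then estimate the effects two ways:

```r
library(feno2cm)
pop <- population_params(alpha = c(1, 3.5, 2.5), beta = c(0.2, 0, 0),
                         sigma_theta = default_population()$sigma_theta,
                         sigma_resid = 0.15)
sim <- simulate_dataset(pop, n = 500, seed = 42)

s1 <- fit_stage1(sim$maneuvers, method = "nls")
mean(!s1$converged)
#> [1] 0.268
cov <- sim$participants[, c("participant_id", "x")]
stage2_ols(s1, cov, method = "ts_nls")
#>   method parameter    estimate         se      ci_low    ci_high n_used
#> 1 ts_nls     c_alv  0.19599688 0.04611989  0.10530200 0.28669176    366
#> 2 ts_nls   log_caw -0.02589672 0.06168718 -0.14720473 0.09541128    366
#> 3 ts_nls   log_daw  0.04751291 0.05577980 -0.06217821 0.15720402    366

fit <- uhb_fit(sim$maneuvers, cov, seed = 1,
               control = uhb_control(warmup = 800, check_every = 400,
                                     retained_total = 1500, max_iter = 12000,
                                     monitor = "regression"))
fit$effects
#>   method parameter    estimate         se      ci_low   ci_high n_used
#> 1   u_hb     c_alv  0.19999713 0.02899284  0.14339512 0.2568895    500
#> 2   u_hb   log_caw -0.02676180 0.05855716 -0.14589269 0.0831209    500
#> 3   u_hb   log_daw  0.01723322 0.06080764 -0.09265403 0.1471444    500
posterior_jaw(fit)
#>   parameter     mean       sd     q2_5    q97_5
#> 1       jaw 428.9025 17.94658 392.7247 465.1046
```

Reading the output: per-participant NLS fails for 26.8% of participants
(8 noisy maneuvers, 3 free parameters), and the two-stage pipeline drops
them (`n_used = 366`), yet still recovers the alveolar effect (0.196,
95% CI 0.105–0.287). The unified Bayesian fit keeps all 500 participants,
estimates the alveolar effect as 0.200 with a noticeably tighter interval,
and correctly finds no airway effects. `posterior_jaw()` transforms the
airway-intercept draws into the posterior of the population airway flux
`J'_aw = C_aw · D_aw` (here centred on 429 pL/s, with
exp(3.5 + 2.5) ≈ 403 the generating value).

Column contracts for file-based work (`read_maneuvers()`,
`read_covariates()`, `write_simdata()`): maneuvers
`participant_id, flow_mls, feno_ppb`; covariates `participant_id, x, ...`;
Stage-I results `participant_id, method, converged, c_alv_hat,
log_caw_hat, log_daw_hat, diagnostics`; effects `method, parameter,
estimate, se, ci_low, ci_high, n_used`. A thin command-line front end with
`simulate`, `fit` and `study` subcommands lives in `inst/cli/feno2cm.R`.

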