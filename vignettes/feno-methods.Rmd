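---
title: "Estimating covariate effects on airway and alveolar nitric oxide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating covariate effects on airway and alveolar nitric oxide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feno2cm)
```

## The model

Exhaled nitric oxide (FeNO, in ppb) measured at the mouth falls as
expiratory flow rises, because NO produced in the airway wall has less time
to accumulate in fast-moving air while the alveolar contribution passes
through unchanged. The steady-state two-compartment model (2CM) captures
this with three parameters:

$$\mathrm{FeNO}(\dot V) \;=\; C_{aw} + (C_A - C_{aw})\,e^{-D_{aw}/\dot V},$$

where $C_A$ is the alveolar NO concentration (ppb), $C_{aw}$ the airway-wall
tissue concentration (ppb), $D_{aw}$ the airway-wall diffusing capacity
(pL·s⁻¹·ppb⁻¹) and $\dot V$ the expiratory flow (mL/s). The derived flux
$J'_{aw} = C_{aw} D_{aw}$ is provided as a view (`jaw_from()`), never as
stored state. Internally every estimator works on the scale
$\theta = (C_A, \log C_{aw}, \log D_{aw})$: the logs enforce positivity of
the airway parameters and make a multivariate-normal population assumption
reasonable; $C_A$ stays on its natural scale with a non-negativity
constraint where the model carries one.

The scientific question the package addresses is not the per-person
parameters themselves but how a covariate $X$ (an exposure, a disease
indicator) relates to them across a study population. Five estimators of
the per-unit-$X$ effects $\beta = (\beta_{C_A}, \beta_{\log C_{aw}},
\beta_{\log D_{aw}})$ are implemented.

## Two-stage estimators

**Stage I** produces per-participant estimates $\hat\theta_i$:

* `nls_fit()` — log-transform-both-sides nonlinear least squares on all of a
  participant's maneuvers, $\sum_j (\log \mathrm{FeNO}_{ij} -
  \log f(\theta, \dot V_{ij}))^2$, minimised by Gauss–Newton with step
  halving and the relative-offset stopping rule (tolerance $10^{-5}$,
  50 iterations, minimum step factor $1/1024$ — the classical NLS
  conventions). Starting values are data-driven: $C_A$ from the slope of
  $\mathrm{FeNO}\cdot\dot V$ against $\dot V$ over the two highest flow
  levels, $\log C_{aw}$ from the log mean FeNO at the lowest flow,
  $\log D_{aw} = 2.5$; one fallback restart from $(1, 3.5, 2.5)$. A fit
  that fails, or lands outside wide sanity bounds
  ($C_A \in [-50, 200]$, logs in $[-5, 10]$), counts as a Stage-I failure.
  With eight maneuvers and three free parameters such failures are common
  and are themselves part of the phenomenon under study.
* `hma_fit()` — the iterative third-order three-flow algorithm. $C_A$ and
  $J'_{aw}$ come from the high-flow linear relation
  $\mathrm{FeNO}\cdot\dot V = J'_{aw} + C_A \dot V$ over the medium and
  high flows; $D_{aw}$ is then iterated through the third-order truncation
  of the exponential at the low flow ($C_{aw}$ from the low-flow FeNO at
  the current $D_{aw}$, then $D_{aw} \leftarrow J'_{aw}/C_{aw}$) until
  successive iterates agree to 1% (relative, floored at 1 absolute), and
  the final iterate is returned. The estimator fails only when its output
  is undefined — a non-increasing high-flow pair ($J'_{aw} \le 0$) or a
  non-positive $C_{aw}$ or $D_{aw}$. Triples that the third-order model
  cannot fit drive the iteration toward a degenerate corner (tiny
  $D_{aw}$, huge $C_{aw}$); those estimates are kept, which is what gives
  this estimator its characteristic very wide airway-parameter intervals
  and large airway-parameter biases while it almost never drops a
  participant. The coarse stopping tolerance follows the original
  algorithm's reported convergence practice (a fixed handful of
  iterations); a tighter tolerance only pushes the degenerate fits deeper
  into the corner and inflates the airway biases further.

**Stage II** (`stage2_ols()`) regresses each $\hat\theta$ component on $X$
by ordinary least squares with t-based 95% intervals, dropping Stage-I
failures. Stage-I uncertainty is deliberately **not** propagated: that
omission is the characterised weakness of two-stage estimation and
reproducing it faithfully is the point of the comparison.

`nlme_fit()` covers the two mixed-model routes: with `unified = FALSE` a
single population fit with unstructured MVN random effects on $\theta$
(Stage I of the two-stage NLME pipeline; empirical-Bayes estimates feed
`stage2_ols()`), and with `unified = TRUE` the covariate enters the mean of
each NO parameter so the slopes come from one joint fit. Fitting goes
through the standard `nlme` linearisation machinery; population starts come
from medians of the per-participant NLS estimates. NLME fitting of this
model is fragile — non-convergence is reported, not raised, and is part of
the method comparison. $C_A$ is not constrained in the frequentist fits.

## The unified hierarchical Bayesian model

`uhb_fit()` implements the package's central method: a two-level model

* maneuver level: $\log \mathrm{FeNO}_{ij} \sim N(f(\theta_i, \dot V_{ij}), \sigma^2)$,
* subject level: $\theta_i \sim \mathrm{MVN}(\alpha + \beta X_i, \Sigma_\theta)$
  truncated to $C_{A,i} \ge 0$,

with priors $\alpha \sim N((2, 4.2, 2.5)', 10^3 I)$,
$\beta \sim N(0, 10^3 I)$, $\sigma^2 \sim$ Inv-Gamma$(10^{-3}, 10^{-3})$,
and $\Sigma_\theta \sim$ inverse-Wishart. The inverse-Wishart
hyperparameters are not pinned down by the model description; the package
default is the minimal weakly-informative choice df $= 4$, scale $= I_3$,
exposed in `default_priors()`.

### Sampler

$(\alpha, \beta)$, $\sigma^2$ and $\Sigma_\theta$ have exact conjugate
Gibbs updates (multivariate normal, inverse-gamma, inverse-Wishart). The
conjugate updates ignore the $X$-dependent truncation mass
$P(C_A \ge 0 \mid \mu_i, \Sigma_\theta)$; under the parameter ranges of
this model that mass is essentially 1 and the approximation is documented
rather than corrected.

The $\theta_i$ full conditionals are non-conjugate. Each sweep updates them
with a mixture of vectorised Metropolis stages, all built on the two-step
truncated-MVN construction (propose the airway pair, then draw $C_A$ from a
zero-truncated normal given the pair, with the truncated-normal proposal
densities — including their pair-dependent normalising masses — in the
acceptance ratio):

* random-walk stages along and across the flux axis
  $u = \log C_{aw} + \log D_{aw}$ (the per-participant likelihood is
  ridge-shaped: the flux is well determined by a handful of flows, its
  decomposition is not), with per-participant scales adapted during warmup
  toward acceptance ≈ 0.3–0.45 and frozen afterwards;
* independence stages proposing the pair from a fixed per-participant
  Gaussian built once from that participant's own NLS fit, sharpened by
  the current subject-level prior;
* group moves that shift an intercept or slope together with every
  participant's corresponding parameter (leaving the random-effects
  residuals untouched), and stretch/shear moves on the joint residual
  cloud with the appropriate Jacobians. These decorrelate the population
  location and scale from the individual parameters; without them the
  population airway parameters mix an order of magnitude more slowly.

Correctness of the whole kernel is established by a Geweke-style
joint-distribution test (forward simulation versus successive-conditional
simulation on a 20-participant toy) and by closed-form oracles for every
conjugate update; these run in the test suite.

### Protocol

Three chains with deterministic overdispersed starts ($C_A$ from Stage-I
estimates, airway pair at jittered population medians, chain-dependent
offsets). After warmup, the Gelman–Rubin $\hat R$ (classic non-split form)
of the monitored scalars is checked periodically; when all fall to ≤ 1.1
the protocol draws the retained sample (12,000 pooled across chains by
default — the published count is read as pooled, exposed in
`uhb_control()`) and re-checks $\hat R$ on exactly those draws, continuing
if the re-check fails until the iteration budget runs out, in which case
the fit is flagged non-converged and excluded by the study harness exactly
as a failed frequentist fit would be.

By default all top-level scalars are monitored, including the six
$\Sigma_\theta$ elements. The covariance of the airway pair is the
slowest-mixing part of the posterior by an order of magnitude — the same
bottleneck that made the original protocol a matter of hours per dataset —
so `uhb_control(monitor = "regression")` offers a criterion on
$(\alpha, \beta, \sigma^2)$ only, for work whose target is the covariate
effects. The package's own calibration tests use this option at desk
scale; its cost is that $\Sigma_\theta$ summaries (and, mildly, the width
of intervals that integrate over $\Sigma_\theta$) may rest on
under-resolved covariance draws, which is why it is not the default.

## Synthetic data

`simulate_dataset()` emulates a multiple-flow FeNO study: $X_i$ standard
normal; $\theta_i$ from the truncated MVN above (the whole 3-vector is
redrawn whenever $C_A < 0$); maneuvers at a configurable schedule (presets:
two at each of 30/50/100/300 mL/s, or the 9-maneuver cohort protocol with
three at 50); log-normal maneuver noise, iid across maneuvers. Defaults
mirror the reference study population: intercepts $(1, 3.5, 2.5)$,
covariance
$$\Sigma_\theta = \begin{pmatrix} 0.44 & 0.13 & -0.14\\ 0.13 & 0.62 &
-0.15\\ -0.14 & -0.15 & 0.36 \end{pmatrix}.$$
One master seed drives three derived sub-streams (covariates, parameters,
noise), so changing the maneuver schedule never perturbs the participant
draws.

The residual SD $\sigma$ is not published for the reference study; the
package default is 0.15 on the log-ppb scale, a plausible multiple-flow
FeNO residual SD under the log-both-sides model, and it is exposed
everywhere. Much of what the simulation study shows is sensitive to this
choice: Stage-I NLS failure rates rise steeply with $\sigma$ (from under 1%
at $\sigma = 0.01$ to about 29% at 0.15, which brackets the published
31.6%), and the leakage biases of the two-stage methods grow with it.
Notably, no single $\sigma$ reconciles every published headline number
under this package's reconstructions: at $\sigma = 0.15$ roughly a fifth
of noisy three-flow triples are arithmetically unfittable by *any* exact
three-flow 2CM solve (the required low-to-high drop ratio exceeds what the
model family can produce), so a published sub-1% three-flow failure rate is
only reachable by an algorithm that returns its final iterate regardless —
which is how the estimator here behaves, and which simultaneously explains
that method's published combination of tiny failure rate, very wide
airway intervals and large airway biases.

The generator does not simulate flow-rate measurement error, within-session
drift, or missing-maneuver mechanisms; passing tests therefore speak to the
statistical machinery under the stated generating process, not to the
robustness of any method against those real-data features.

## The simulation harness

`run_replicate()` runs any subset of the five methods on one generated
dataset and returns slope estimates with 95% intervals (or a
non-convergence flag) per NO parameter. `run_scenario()` sweeps an
effect-size grid (seven scenario masks over which parameters the covariate
touches, grid 0.02–0.2 in steps of 0.02) with deterministically derived
per-replicate seeds. `aggregate_metrics()` computes bias, relative bias
(only where the truth is non-zero), 95%-interval coverage and mean length,
and the rejection rate (power away from zero truth, type-I error at zero),
optionally under the conservative all-methods-converged filter; without
the filter each method still drops only its own failed replicates.
Average relative bias over a sweep averages per-setting means over
settings (settings first, then the average). The replicate archive is
sufficient to recompute every metric.

## Problem sizes and numerical choices

The full published design — 71 settings × 1000 replicates × five methods,
with the Bayesian fit alone taking hours per dataset — is cluster-scale.
The package's own checks run at desk scale, chosen once: 20 reference
datasets of 1000 participants for the Stage-I failure rates; the
scenario-1 sweep at 50 replicates per setting for the two-stage bias
structure; and a 100-participant, 5+5-replicate calibration run for the
Bayesian method with 1,500 retained draws under the regression-parameter
criterion. The full-scale power statement (power ≈ 1 at effect size 0.12
with 1000 participants) is a function of the published sample size and is
not reproduced at desk scale.

Numerical conventions worth knowing: exponent underflow in the 2CM mean is
clamped; the Gauss–Newton normal equations are solved in closed form per
participant with a relative-determinant singularity guard; the
inverse-Wishart draw jitters a numerically singular scale by $10^{-8} I$
with a warning; zero-truncated normal draws fall back to the boundary when
the truncation mass underflows; and every stochastic entry point takes an
integer seed from which all sub-streams derive.

## Known limitations

* The three-flow estimator is a reconstruction: the original's exact
  update order and stopping rule are not published. The reconstruction was
  validated against the published failure-rate and bias structure rather
  than against source code.
* The conjugate updates' neglect of the truncation mass is an
  approximation, excellent at the reference population but unquantified
  for populations with most mass near $C_A = 0$.
* Desk-scale Bayesian runs lean on the regression-parameter convergence
  criterion; covariance summaries from such runs should be treated as
  indicative.
* The generating $\sigma$ is a package choice (0.15), not a published
  value; quantitative agreement with published bias magnitudes inherits
  that uncertainty.
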