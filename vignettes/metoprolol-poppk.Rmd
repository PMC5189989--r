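---
title: "Methods: population PK modeling and sex-stratified dose equivalence for oral metoprolol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK modeling and sex-stratified dose equivalence for oral metoprolol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metopop)
```

## The problem

Metoprolol is cleared much more slowly by women than by men — the female
apparent clearance of the active S-enantiomer is roughly 40% of the male
value — so equal oral doses produce very unequal systemic exposures. This
package implements the full modeling-and-simulation chain needed to turn
that observation into a dosing statement: a structural PK model, a
population (mixed-effects) layer, a trial simulator, an estimator, a
simulation-based model check, and an exposure-matching dose search.

## Structural model

A one-compartment model with first-order absorption, absorption lag, and
first-order elimination:

$$C(t') = \frac{D\,K_a}{V\,(K_a - k_e)}\left(e^{-k_e t'} - e^{-K_a t'}\right),
\qquad t' = t - T_{lag}, \qquad k_e = CL/V,$$

with $C = 0$ for $t \le T_{lag}$. Parameters and units:

| parameter | meaning | unit |
|---|---|---|
| $V$ | apparent volume of distribution ($V/F$) | L |
| $CL$ | apparent clearance ($CL/F$) | L/h |
| $K_a$ | first-order absorption rate constant | 1/h |
| $T_{lag}$ | absorption lag time | h |

Assumptions: linear (dose-proportional) kinetics, instantaneous
distribution, no enterohepatic recirculation, constant bioavailability.
Because all data are oral, $F$ is not identifiable and is fixed at 1; every
reported $V$ and $CL$ is apparent. Doses are in mg, times in h, and
concentrations in ng/mL (= µg/L), i.e. the mg/L closed form × 1000.

Multiple doses are superposed: the model is linear, so the regimen curve is
the sum of time-shifted single-dose solutions. An independent ODE route
(`ode_profile`) integrates the two-state system gut → central with each
dose entering the gut as a bolus at (dose time + $T_{lag}$), which matches
the closed form's time shift exactly; `deSolve::lsoda` at rtol $10^{-10}$,
atol $10^{-12}$ makes the oracle two orders tighter than the $10^{-6}$
agreement contract it checks.

**Flip-flop kinetics.** For all four sex-by-enantiomer parameter sets,
$K_a < k_e$ (e.g. S/female: $K_a = 0.161$/h vs $k_e = 101/34.9 = 2.89$/h),
so the terminal slope reflects *absorption*: the terminal half-life
converges to $\ln 2 / K_a$, not $\ln 2 / k_e$. The tail-regression
half-life estimator is tested against both identities.

### Numerical choices

- **$K_a \approx k_e$ degeneracy**: when $|K_a - k_e| < 10^{-8}
  \max(K_a, k_e)$ the closed form switches to the limit
  $C(t') = (D/V) K_a t' e^{-K_a t'}$, avoiding catastrophic cancellation.
- **AUC**: linear trapezoid by default. On the 1000-point 0–24 h grid this
  reproduces the reference single-dose AUCs at integer precision, which is
  why the 0–24 h trapezoidal value (not the analytic $D/CL$, also exposed
  as `auc_infinity`) is the package's reporting default. A log-linear
  trapezoid is available as an option.
- **Terminal half-life**: least-squares line on log-concentration over the
  last 25% of positive-concentration grid points — safely inside the
  terminal phase for all reference parameter sets; a rising tail is an
  error, not a number.
- **Cmax ties** break toward the earliest time.

## Population layer

Individual parameters are lognormal around the typical values:
$\theta_i = \theta\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$,
independently per parameter (diagonal $\Omega$). Observation noise is
proportional: $y_{ij} = f_{ij}(1 + b\,\varepsilon_{ij})$,
$\varepsilon \sim N(0,1)$, floored at 0.

Two CV conventions coexist in practice and both are implemented
(`cv_to_variance`): the *exact* lognormal relation
$\omega^2 = \ln(1 + CV^2)$, used for simulation, and the *approximate*
$\omega^2 = CV^2$ (equivalently $CV = \sqrt{\omega^2}$), used for report
tables because that is the convention population-PK estimate tables print.

The packaged trial conditions (`cts_design`, `cts_population_model`): 50
subjects per sex, a single 100 mg oral dose, 17 nominal sampling times (0,
0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1, 2, 4, 6, 8, 12, 14, 16, 18, 24 h), CVs of
59/49% (CL, men/women), 44/34% (V), 40% ($K_a$, an assumed value), and
$b = 0.0281$. Design choices worth stating:

- the pre-dose $t = 0$ sample is simulated (it is exactly 0 under
  proportional error) and counted as an observation record, making the
  design's bookkeeping 2 × 50 × 17 = 1700 samples;
- $T_{lag}$ carries no interindividual variability: the reference variance
  estimate for it is effectively nil and no CV is available for it;
- the residual parameter 0.0281 is interpreted as the proportional SD
  fraction $b$ (2.81%) — a magnitude consistent with fitting near-noiseless
  mean profiles — and is used both as the generator default and as an
  estimation target within sampling error.

All randomness flows from R's global RNG: `set.seed()` before any
simulation or fit reproduces it exactly.

## Estimation

### Pooled least squares

`naive_pooled_fit` fits the structural model to pooled observations by
Levenberg–Marquardt on log-parameters, minimizing squared *log-scale*
residuals $\sum_j (\ln y_j - \ln f_j)^2$. Log residuals equal proportional
residuals $(y-f)/f$ to first order but remain bounded when individual
curves span orders of magnitude; with an observed-value denominator, a
single fast-eliminating subject's near-zero tail concentration can dominate
the objective and push the fit into a degenerate absorption-limited mode.
The search is box-constrained, with $T_{lag}$ capped just below the
earliest positive observation: past that point every prediction is zero and
the objective is flat, a plateau the optimizer must not enter. Non-positive
observations (pre-dose zeros) are excluded. On noise-free model-generated
profiles the fitter recovers the generating parameters to $<0.1$%.

### SAEM

`saem_fit` maximizes the mixed-effects likelihood by stochastic
approximation EM. Writing $\phi_i = \log\theta_i \sim N(\mu, \Omega)$:

1. **E-step (MCMC)**: per iteration and chain, one independence proposal
   from the current prior $N(\mu, \Omega)$ for all subjects jointly, then
   one component-wise random-walk pass; acceptance per subject. Random-walk
   steps adapt toward 40% acceptance during burn-in. Default 3 chains.
2. **Stochastic approximation**: sufficient statistics
   ($\sum_i \phi_i$, $\sum_i \phi_i^2$, the squared proportional residual
   sum) are smoothed with step size $\gamma_k = 1$ during burn-in (default
   300 iterations) and $\gamma_k = 1/(k - K_1)$ during smoothing (default
   100).
3. **M-step**: $\mu$, $\omega^2$ (floored at $10^{-6}$; floor hits are
   messaged) and $b$ from the smoothed statistics. During burn-in,
   variances may shrink by at most 5% per iteration (simulated annealing),
   preventing premature collapse.

$T_{lag}$ is estimated as a fixed effect: it is excluded from the reported
$\Omega$, and its *sampling* variance is annealed geometrically from 0.1 to
$10^{-4}$ across the burn-in and held there. The terminal value matters:
annealing it to the $10^{-6}$ floor freezes the $T_{lag}$ chain before the
fixed effect has finished moving, and the residual bias propagates into the
individual $V$ estimates. At $10^{-4}$ (≈1% wiggle on the log scale) the
estimate keeps tracking through smoothing, with a bias bound well below
the reporting precision.

Two likelihood details guard the pre-dose degeneracy: the observation SD is
$\sqrt{a^2 + (b f)^2}$ with a fixed additive floor $a = 10^{-8}$ ng/mL, so
records where both the prediction and the observation are exactly zero
contribute a finite constant; and predictions below $10^{-6}$ ng/mL are
excluded from the $b$ update.

Standard errors come from a stochastic approximation of the Fisher
information by Louis' principle (complete-data score and Hessian
accumulated over the smoothing phase); typical-value SEs are delta-method
transformed to the natural scale, and RSE% = 100·SE/estimate mirrors the
usual report layout. The SE printed for a fixed-effect-only parameter
($T_{lag}$) reflects the annealed-variance approximation and is
optimistic; it is reported for layout parity, not inference. Convergence is
declared when the final smoothing stretch of the log-likelihood trace shows
no material linear drift (the raw trace carries MCMC sampling noise, so a
range-based criterion would measure noise, not drift).

Subjects are processed in sorted-ID order and records in time order, so
estimates are bit-identical under row shuffles and order-preserving
relabelings; order-*changing* relabelings alter the positional mapping of
random draws to subjects and are therefore only stochastically invariant.

Empirical Bayes individual estimates (`individual_estimates`) are posterior
modes of $\phi_i$ given the population fit. Goodness-of-fit residuals are
computed against *individual* predictions, $(y - f_i)/f_i$: residuals
against the typical prediction are right-skewed under lognormal IIV even
when the model is correct, so only the individual-level residuals admit a
zero-mean check.

## PC-VPC

`vpc_compute` simulates replicate datasets at the original design from the
fitted model, prediction-corrects observed and simulated records
identically ($pcY_{ij} = Y_{ij}\,\mathrm{median}(PRED_{bin})/PRED_{ij}$,
the standard correction), and compares empirical 10/50/90th percentiles per
bin with their 95% simulation intervals. Conventions, fixed for
reproducibility: one bin per nominal design time (a break-point binner is
available for irregular data); linear-interpolation quantiles (R type 7);
500 replicates by default. Records with $PRED = 0$ — the pre-dose sample
and any nominal time at or before $T_{lag}$ — cannot be corrected (division
by zero); they pass through unchanged, are excluded from the bands, and
stay in the record counts. Consequently a stratum's band table has one row
per nominal time *after* its lag (13 of 17 bins for the female stratum,
11 for the male one). On self-simulated data the empirical percentile
excursion rate is consistent with the nominal 5% (checked by a binomial
band in the test suite); with all variability at zero, every band collapses
onto the typical curve.

## Dose equivalence

`equivalent_dose` selects, from a candidate set, the target-population dose
minimizing $|\ln(AUC_{cand}/AUC_{ref})|$, with ties broken toward the lower
dose — the log criterion makes the choice symmetric in reference and
target. The default candidates {25, 50, 100, 200} mg are the commercial
tablet strengths; because the discrete answer depends on what is on the
shelf, the continuous solution of $AUC_{target}(D) = AUC_{ref}$ is reported
alongside (40.7 mg for the female-vs-male S-enantiomer comparison, where
the discrete answer is 50 mg). The default metric is the 0–24 h trapezoidal
AUC on the 1000-point grid, consistent with the exposure surface above;
`auc_inf` ($D/CL$) is available, under which the continuous optimum reduces
to $D_{ref} \cdot CL_{target}/CL_{ref}$ exactly.

## What the synthetic-data generator does and does not emulate

`generate_digitized_profile` emulates the *mean* concentration–time input
the original model fit consumed: one mean "subject", nine 100 mg doses
every 12 h, samples across the ninth dosing interval plus a 24 h washout,
and optional proportional noise. The true sampling schedule of the source
dataset is unknown; the default (4-hourly through the steady-state
accumulation, dense after the ninth dose) is a documented stand-in chosen
to inform all four parameters, not a claim about the original digitization.
Likewise `simulate_trial` draws ideal lognormal individuals at exact
nominal times with purely proportional noise — no dropout, no BQL
censoring, no dosing-history errors, no model misspecification. Passing
recovery and calibration tests therefore demonstrates the estimator and the
check are correct *under the stated generating model*; they do not certify
performance on real clinical data.

## Problem sizes

The test suite runs the full trial bookkeeping at the design size (100
subjects, 1700 observations); parameter-recovery evidence uses 20 seeded
replicates of the 50-woman stratum with the default SAEM schedule
(300 + 100 iterations, 3 chains), and VPC calibration uses 5 seeded trials
× 200 replicates — sizes at which the Monte-Carlo error of each assertion
is well below its tolerance. The acceptance script's exposure surface is
deterministic and uses the 1000-point grid throughout.

## Known limitations

- One structural model only: no two-compartment, transit-absorption or
  saturable-clearance alternatives, and no covariates beyond the sex
  stratification (no weight, age, or CYP2D6 genotype).
- Diagonal $\Omega$: correlated random effects are not supported.
- The likelihood route is SAEM only (no FOCE/Laplace), and model-selection
  machinery (AIC/BIC across structural models) is out of scope.
- Equivalence matches AUC only; Cmax-matching and pharmacodynamic
  (blood-pressure/heart-rate) equivalence are not addressed.
- Fixed-effect-only SEs are approximations (see above).
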