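---
title: "Pediatric vancomycin population PK: model, simulations, estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pediatric vancomycin population PK: model, simulations, estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pedvanc` implements a two-compartment population pharmacokinetic (PK)
model of intravenous vancomycin in children aged 3 months to 18 years,
and the analysis layers that such a model exists for: Monte Carlo
simulation of target attainment, dose optimization, empirical-Bayes
individual estimation for precision dosing, a scaled-down population
estimator, and model diagnostics. This vignette explains the science,
the numerical choices, and what the synthetic-data experiments do and do
not demonstrate.

## The structural and covariate model

Drug amounts in a central (V1) and a peripheral (V2) compartment follow
linear kinetics with clearance CL, intercompartmental clearance Q, and
zero-order infusion input. Covariates act multiplicatively on the
typical values, all referenced to a 70 kg adult:

* **Size.** Allometric scaling with fixed exponents: CL and Q scale as
  `(WT/70)^0.75`, V1 and V2 as `WT/70`.
* **Maturation.** A sigmoidal Hill function of postmenstrual age (PMA,
  weeks): `PMA^H / (PMA^H + TM50^H)` with H = 3.4 and TM50 = 47.7 weeks
  held fixed (they are not identifiable from data in this age range and
  are taken from the neonatal renal-maturation literature). Maturation
  passes 90% of its maximum near a PMA of two years. An optional
  postnatal-age transition factor (`f_mat_pna()`) is implemented for
  completeness, but the final model does not use it and no published
  values for its two parameters exist, so none are shipped.
* **Renal function.** Serum creatinine (SCR, umol/L) enters as
  `exp(-theta * (SCR - SCR_std(age)))`, where `SCR_std` is a pediatric
  age-standard creatinine polynomial. A child with age-typical
  creatinine has factor 1. The polynomial is not monotone: it dips to a
  shallow minimum near 1.2 years before rising through adolescence,
  which is why the renal factor must pivot on the *age-specific*
  standard rather than a single cutoff. The sign convention of the
  intercept (-2.37330) follows the pediatric reference formula; the
  coefficients are exposed as arguments for sensitivity analyses.

Random effects are lognormal: interindividual variability (IIV) on CL
(22.1%) and V1 (32.9%), interoccasion variability (IOV) on CL (18.7%)
redrawn per treatment occasion, and proportional residual error
(23.3%). A new occasion begins when the gap between consecutive doses
exceeds 24 h (configurable); IOV across treatment episodes is otherwise
undefined for retrospective TDM data.

The packaged parameter file `table2_final.json` carries these values and
is the default everywhere (`vanco_params()`).

### Closed-form kinetics

Because the system is linear and time-invariant, the concentration under
any infusion sequence is a superposition of step responses with hybrid
rate constants alpha > beta > 0. Both the step response and its running
integral have closed forms, so windowed AUCs (the exposure metric) are
exact integrals, not quadrature. Numerical choices:

* beta is computed as `(k10 k21) / alpha` to avoid cancellation.
* If `(alpha - beta)/alpha < 1e-9` (possible only for extreme parameter
  combinations), a repeated-eigenvalue series expansion replaces the
  two-exponential form.
* With IOV, clearance is piecewise-constant across occasions. Each dose
  event is evaluated with its own occasion's clearance; carryover from a
  previous occasion keeps decaying with that occasion's constants. This
  is exact within one occasion — in particular for the 48-h dosing
  simulations, which contain a single occasion.

The closed form is verified against an independent stiff ODE integration
(`deSolve`) to a relative error below 1e-6 on randomized regimens, and
`AUC(0, Inf) = dose / CL` holds to 1e-9.

## What the synthetic cohorts emulate

The clinical datasets behind the model are confidential, so every input
here is synthetic. The virtual dosing cohorts reproduce the *printed
design*: nine age x creatinine subgroups (3 months-1, 1-4, 4-10, 10-16,
16-18 years crossed with laboratory creatinine bands), 1,000 subjects
each. Within a band, age and creatinine are uniform — the only structure
the published tables pin down — and weight is the median weight-for-age
times a lognormal deviate (log-SD 0.15). The median curve is anchored to
unisex growth-reference medians at 14 ages and interpolated with a
monotone Hermite spline; it reproduces the development cohort's median
weight (22.9 kg) at its median age (6.8 years) to within half a
kilogram, which is the only external calibration available. PMA is
derived from age assuming term gestation (40 weeks, configurable), since
the dosing tables stratify by postnatal age only.

What this stand-in does *not* reproduce: the joint distribution of age,
weight and creatinine in the real covariate database (real weights are
age-correlated with heavier tails; real creatinine is not uniform within
a band and correlates with age and illness), preterm birth, and any
time-varying renal function. Consequences are visible and documented in
the results: optimizer dose selections and pooled attainment match the
published table closely, while the standard-arm attainment in the
youngest subgroup — the quantity most sensitive to the infant covariate
joint — runs high by several percentage points. Passing the simulation
checks therefore demonstrates that the *model and decision rules* are
implemented correctly under the declared cohort model, not that the
synthetic cohort equals the confidential one.

Synthetic TDM datasets add trough-weighted sparse sampling (1-6 samples
per child, weights chosen so the median is 3, matching the development
dataset's sampling intensity), proportional residual error, and a lower
limit of quantification of 2 mg/L below which records are dropped (the
source datasets do not state their handling; dropping is the
conservative default and the count is reported).

## Dosing simulations and the optimizer

Exposure is summarized per subject as AUC over 0-24 h and 24-48 h and
the troughs at 24 h and 48 h, computed from the model state without
residual error (AUC is a state quantity; measurement error belongs to
observed concentrations only). The efficacy index AUC/MIC reduces to AUC
with MIC fixed at 1 mg/L, the susceptibility breakpoint for
*S. aureus*. The target window [400, 650] mg.h/L is closed: attainment
means the AUC lies inside it, and exposures above 650 are counted
separately as supratherapeutic.

Doses are mg/kg rounded to the nearest milligram; regimens are 1-h
infusions every 6 h with the ninth dose starting exactly at 48 h so that
the steady-state trough is read immediately before it. The
dose-escalation optimizer evaluates a 5-30 mg/kg grid (1 mg/kg steps) on
a common set of random-effect draws — common random numbers make the
95%-of-maximum rule stable against Monte Carlo noise — and selects the
lowest dose whose attainment is at least 95% of the grid maximum.
"Pooled" attainment is the unweighted mean over the nine subgroups
(weighting is not specified in the source tables; equal subgroup sizes
make this the natural choice). The loading-dose analysis replaces the
first optimized maintenance dose with 25 mg/kg, sharing cohorts and
draws between the loading and no-loading arms. Descriptive daily-dose
maxima are not enforced as constraints; an optional per-day cap exists
but is off by default.

## MAP estimation and precision dosing

With population parameters fixed, a subject's random-effect vector
(eta_CL, eta_V1, and one kappa per observed occasion) is estimated as
the posterior mode of

    sum_j [ (DV_j - f_j)^2 / (sigma f_j)^2 + log((sigma f_j)^2) ]
      + eta' Omega^-1 eta + sum_occ kappa_occ^2 / omega_IOV^2

— the conditional step of FOCE with interaction, so population and
individual estimation are mutually consistent. The optimizer is BFGS on
the at-most-4-dimensional space, multistarted from 0 and +/- one prior
SD; out-of-bounds proposals (|effect| > 10 on the log scale) receive a
dominating penalty so line searches cannot escape. Whether the kappas
are estimated or zeroed is a switch (`estimate_kappa`), defaulting to
estimation for observed occasions.

Dose adjustment converts the MAP clearance (interindividual part only —
future-occasion IOV is unpredictable by construction) into the daily
dose whose steady-state AUC is the window midpoint, 525 mg.h/L. On
synthetic cohorts with two troughs per child, MAP-forecast steady-state
AUC ranks subjects against their simulation truth with Spearman
correlation above 0.8, which is the property that matters for dose
correction.

## Scaled-down population estimation

The population objective is the Laplace approximation to -2 log marginal
likelihood, evaluated at each subject's conditional mode with the exact
(finite-difference) curvature of the joint, interaction term retained.
The additive constant includes `n log(2 pi)`, so with all random effects
switched off the objective is the exact -2 log likelihood of the typical
model. A first-order (FOCE-I) variant using the Gauss-Newton covariance
is available (`method = "focei"`); at four observations per subject its
clearance estimates run several percent high, which is why the exact
curvature is the default — with sparse data the per-subject joint is far
from the regime where the linearization is harmless.

Two implementation details matter at desk scale. First, conditional
modes are warm-started between outer iterations, which makes the
objective reproducible only to about 1e-9; the outer optimizer
(`nlminb`) therefore receives an explicit wide-step (5e-4)
finite-difference gradient rather than relying on machine-epsilon
internal steps that would read noise. Second, log-transformed parameters
keep every estimate positive without constraints.

The recovery experiment (analysis script 04, and the acceptance suite)
uses 200 children, two q6h treatment episodes, and one peak plus one
trough sample per episode — four observations per child, the sparse
reality of TDM. Design choices made once, on identifiability grounds:

* Creatinine spans 10-180 umol/L (within the development cohort's
  10-328 range); the wide contrast is what identifies the renal slope
  from 800 observations.
* The dataset is generated without quantification-limit censoring: the
  estimator does not model censoring, and dropping low records
  demonstrably biases the renal covariate slope upward, which would
  contaminate a pure recovery check.
* `omega_iov_cl` is fixed at its generating value during fitting, like
  the maturation parameters: with two short episodes per child the IOV
  magnitude is barely separable from IIV, and letting it float degrades
  the fixed-effect recovery that the experiment is designed to measure.
  The IOV *effects* (kappas) are still estimated per occasion.

At this scale the three structural targets (TVCL, TVV1, renal slope) are
recovered within 10%; the remaining deviation is the known sparse-data
bias of mode-based marginal approximations plus sampling noise, and it
shrinks visibly when sampling is enriched to eight observations per
child. The nonparametric bootstrap resamples subjects with replacement
and reports percentile intervals; 12 replicates in the analysis script
(300 at full scale) keep the run inside desk time, with the weakly
informed peripheral parameters held at the point fit during replicate
refits.

## Diagnostics

CWRES uses the FOCE linearization at the conditional mode: residuals
about the linearized marginal mean, decorrelated by the Cholesky factor
of the linearized covariance (ridged by 1e-10 if singular, with a
warning). On model-true data their mean is near 0 and variance near 1;
without random effects they reduce exactly to `(DV - f)/(sigma f)`.

The prediction-corrected VPC bins observations by time after the
previous dose (quantile edges, bins under 5 observations merged with a
neighbor), corrects each observation by `median PRED in bin / own PRED`,
and applies the same correction to every simulated replicate (1,000 by
default; 200 in the desk-scale scripts). Reported are observed
5th/50th/95th percentiles per bin with 95% confidence bands of the same
percentiles across replicates. Stratification by infusion mode follows a
`CONT` flag when the dataset carries one; no further stratification is
implemented.

## Problem sizes and limitations

The analysis scripts use 1,000 subjects per subgroup for dosing
simulations (the published design), 200 subjects for estimation
recovery, 150 for diagnostics, 300 for MAP calibration, 20 bootstrap
replicates, and 200 VPC replicates — sizes chosen so the full workflow
reruns in minutes on one core while keeping Monte Carlo error well
below the decision tolerances.

Known limitations: no saturable elimination, no ECMO/dialysis
populations, no time-varying covariates within a run, no parameter-
uncertainty propagation into the simulations, and the covariate
stand-ins described above. The estimator is a desk-scale reimplementation
of the named method, not a substitute for a production NLME engine on
real data.
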