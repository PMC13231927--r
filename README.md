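# pedvanc

Population pharmacokinetics of intravenous vancomycin in children
(3 months to 18 years), as an R package plus a scripted analysis
workflow: covariate-structured two-compartment kinetics, Monte Carlo
probability-of-target-attainment (PTA) simulation and dose
optimization, MAP Bayesian individual estimation for model-informed
precision dosing, a scaled-down FOCE-I/Laplace population estimator
with bootstrap, and model diagnostics (CWRES, goodness of fit,
prediction-corrected VPC).

## The problem and the model

Vancomycin has a narrow window: efficacy requires a 24-h area under the
concentration-time curve over the MIC (AUC/MIC) above 400, while kidney
injury risk rises above about 650 mg.h/L. Pediatric clearance varies
strongly with size, maturation and renal function, so one-size-fits-all
mg/kg dosing leaves many children outside 400-650. The package
implements a two-compartment model whose clearance is

    CL = TVCL * (WT/70)^0.75
              * PMA^H / (PMA^H + TM50^H)
              * exp(-theta_SCR * (SCR - SCR_std(age)))

with TVCL = 7.56 L/h/70 kg, H = 3.4, TM50 = 47.7 weeks (fixed),
theta_SCR = 0.0188 per umol/L, and `SCR_std(age)` a pediatric
age-standard creatinine polynomial; volumes scale linearly with weight
(V1 = 85.6, V2 = 286 L/70 kg; Q = 1.30 L/h/70 kg with exponent 0.75).
Lognormal interindividual variability acts on CL (22.1%) and V1
(32.9%), interoccasion variability on CL (18.7%), and residual error is
proportional (23.3%). These values ship as
`inst/extdata/table2_final.json` and load via `vanco_params()`.
Concentrations and windowed AUCs come from the closed-form superposition
of infusion step responses — no ODE solver, exact integrals.

## Worked example

Typical clearance for a 2-year-old, 12 kg, serum creatinine
20 umol/L, and the dose that centers steady-state AUC on the window:

```r
library(pedvanc)
pop <- vanco_params()
cov <- subject_covariates(age = 2, wt = 12, scr = 20)
typ <- typical_params(pop, cov)
round(typ$cl, 2)            # 2.06 L/h -- maturation is complete, so
                            # clearance per kg is near its childhood peak
reg <- q6h_regimen(round(15 * 12))     # 180 mg q6h, 1-h infusions
round(auc(typ, reg, 24, 48))           # 305 mg.h/L -> BELOW the 400-650 target
round(concentration(typ, reg, 48), 1)  # 8.4 mg/L steady-state trough
round(target_dose(typ$cl)$daily_mg)    # 1084 mg/day centers AUC on 525
```

At the standard 60 mg/kg/day this typical toddler is under-exposed
(AUC 305 mg.h/L); hitting the window midpoint takes about
1,084 mg/day, i.e. 22-23 mg/kg q6h — precisely the dose range the
subgroup optimizer selects for young children below.

The analysis workflow lives in `analysis/` as numbered scripts (run
from the repository root, outputs under `results/`):

```sh
Rscript analysis/01_cohorts.R        # nine virtual subgroups
Rscript analysis/02_dosing_table.R   # standard vs optimized q6h dosing
Rscript analysis/03_loading_dose.R   # 25 mg/kg loading-dose evaluation
Rscript analysis/04_fit_recovery.R   # estimation recovery + bootstrap
Rscript analysis/05_diagnostics.R    # CWRES, GoF, pcVPC
Rscript analysis/06_map_dosing.R     # MAP forecasts and dose proposals
```

Script 02 prints the dosing table; for the youngest subgroup
(3 months-1 year, SCR 10-30 umol/L) it reports the standard 15 mg/kg
q6h arm at about 19% attainment with a median trough near 9 mg/L, and
an optimized dose of 22 mg/kg reaching about 64%; pooled over the nine
subgroups the optimized strategy attains the window in roughly 68% of
children versus 43% under standard dosing. Script 03 shows a 25 mg/kg
loading dose raising first-day attainment from about 28% to 52% while
keeping first-day exposures above 650 mg.h/L below 2%.

## Layout

```
R/                  model, cohorts, simulation, dosing, MAP, fitting,
                    diagnostics, I/O
analysis/           numbered workflow scripts (thin drivers over R/)
scripts/acceptance.R
inst/extdata/       table2_final.json, weight_for_age_synthetic.csv
tests/testthat/     unit, property and acceptance suites
vignettes/methods.Rmd   model assumptions, numerical choices, limits
```

The clinical datasets behind the published model are confidential;
every input here is synthetic, and the vignette spells out which
features of real data the generators do and do not emulate.
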