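# txapk

Population pharmacokinetics of tranexamic acid (TXA) in cardiac surgery
with cardiopulmonary bypass (CPB).

Patients on CPB receive TXA to limit fibrinolytic bleeding, but bypass
alters the drug's disposition: clearance falls and distribution volume
rises relative to product-information values, so standard dosing can miss
the target exposure. `txapk` is a complete, tested R implementation of the
nonlinear mixed-effects analysis behind a double-bolus CPB regimen
(1000 mg at the start of surgery and 1000 mg when CPB is discontinued),
intended for pharmacometricians who want to refit, extend, or simulate
from this model.

## What is in the box

* **Structural model** — closed-form one-/two-compartment IV-bolus
  predictions with dose superposition:
  `C(t) = Σ_d (amt_d/V1)[A e^(−α(t−t_d)) + B e^(−β(t−t_d))]`,
  plus Cockcroft–Gault and DuBois–DuBois clinical formulas.
* **Statistical model** — log-normal inter-individual variability
  (`P_i = TV(P)·exp(η_i)`, diagonal Ω), combined residual error
  (`SD = sqrt(σ1² + (Cpred·σ2)²)`), and power-law covariate effects
  (`V1 = TV(V1)·(BW/61.4)^0.911`, `CL1 = TV(CL1)·(CLcr/61.0)^0.752`).
* **Estimation** — FOCE with interaction (`fit_population()`), written
  here with an Rcpp core and complex-step derivatives, validated against
  adaptive Gauss–Hermite quadrature in the test suite.
* **Model building** — likelihood-ratio tests (`lrt()`, ΔOFV > 6.635 at
  1 df, p < 0.01) and the exhaustive "shotgun" covariate search
  (`shotgun_covariate_search()`).
* **Qualification** — PRED/IPRED/CWRES diagnostics (`gof_diagnostics()`),
  visual predictive checks (`vpc()`), nonparametric bootstrap
  (`bootstrap_model()`).
* **Data** — NONMEM-style event-record CSV I/O (`read_dataset()`,
  `write_dataset()`) and a synthetic cohort generator
  (`cohort_design()`, `simulate_dataset()`) reproducing the study design:
  77 subjects, reported covariate medians/IQRs, CPB-timed second bolus,
  sampling 0.5/1/2/5 h and 1/6/16 h post-dose, late dose-1 draws dropped
  when re-dosing intervenes.

## Worked example

```r
library(txapk)

ds  <- simulate_dataset(cohort_design(), txa_truth(), seed = 1)
ds
#> Population PK dataset (simulated(seed=1))
#>   subjects:     77
#>   doses:        154
#>   observations: 454

fit <- fit_population(ds, txa_final_model(), control = fit_control(se = FALSE))
fit
#> Population PK fit (FOCE with interaction)
#>   OFV: 3204.743691   converged: TRUE
#>             Estimate RSE%
#> v1          13.01000   NA
#> v2           6.62000   NA
#> cl1          3.22800   NA
#> cl2          2.60900   NA
#> bw_on_v1     0.76530   NA
#> clcr_on_cl1  0.58690   NA
#> omega2_cl1   0.09062   NA
#> omega2_v1    0.08990   NA
#> sigma_add    0.89700   NA
#> sigma_prop   0.15570   NA
```

The cohort was simulated from typical values `v1 = 12.77` L and
`cl1 = 3.263` L/h with 30% CV between-subject variability; the fit recovers
them within 2% (13.01 L, 3.228 L/h) along with the variance components
(`omega2 ≈ 0.09`, `sigma ≈ (0.9 mg/L, 0.156)`). A typical patient with
creatinine clearance 60 mL/min has
`cl1 = 3.263·(60/61)^0.752 = 3.223` L/h:

```r
apply_covariates(txa_truth()$theta, txa_final_model()$effects,
                 list(bw = 61.4, clcr = 60))[["cl1"]]
#> [1] 3.222692
```

A pipeline runner (`txapk_run()`, with a thin Rscript wrapper in
`inst/cli/txapk.R`) drives `simulate` / `fit` / `covsearch` / `vpc` /
`bootstrap` / `report` stages from a YAML config and a single root seed;
all artifacts are byte-reproducible from config + seed.

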