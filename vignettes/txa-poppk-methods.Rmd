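---
title: "Methods: population PK of tranexamic acid under cardiopulmonary bypass"
author: "txapk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of tranexamic acid under cardiopulmonary bypass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txapk)
```

## The problem

Tranexamic acid (TXA) is an antifibrinolytic given during cardiac surgery to
reduce bleeding. Cardiopulmonary bypass (CPB) changes both the distribution
volume and the clearance of hydrophilic, renally eliminated drugs like TXA,
so typical-population dosing can land patients outside the intended exposure
window. `txapk` implements a complete nonlinear mixed-effects (NLME)
analysis of TXA concentration–time data from a double-bolus CPB regimen
(1000 mg at the start of surgery, 1000 mg when CPB is discontinued):
structural model, estimation, covariate selection, and model qualification —
together with a synthetic-cohort generator so the whole pipeline runs and is
tested without access to patient data.

## Structural model

Disposition is a two-compartment model with first-order elimination from the
central compartment, parameterized by clearances and volumes: central volume
$V_1$ (L), peripheral volume $V_2$ (L), elimination clearance $CL_1$ (L/h)
and intercompartmental clearance $CL_2$ (L/h). For instantaneous boluses the
concentration is the closed-form superposition

$$C(t) = \sum_{d} \frac{amt_d}{V_1}\left[A\,e^{-\alpha (t-t_d)} +
  B\,e^{-\beta (t-t_d)}\right],\qquad t \ge t_d,$$

with hybrid rate constants $\alpha \ge \beta$, the roots of
$x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21}$, and
$A = (\alpha-k_{21})/(\alpha-\beta)$, $B = (k_{21}-\beta)/(\alpha-\beta)$,
so $A + B = 1$ and $C(0^+) = \mathrm{dose}/V_1$ after a single bolus. Doses
are treated as true boluses: the regimen's administration duration is not
reported, and with the earliest sample drawn half an hour after dosing a
short infusion is indistinguishable from a bolus at these sampling times.

Two clinical formulas feed the covariate model: Cockcroft–Gault creatinine
clearance $CL_{cr}$ (mL/min, serum creatinine converted from µmol/L to
mg/dL by dividing by 88.4) and DuBois–DuBois body surface area.

## Statistical model

* **Inter-individual variability.** $P_i = TV(P)\,e^{\eta_i}$ with
  $\eta_i \sim N(0, \omega^2)$, independent across parameters (diagonal
  $\Omega$). By default $CL_1$ and $V_1$ carry IIV: they are the two
  parameters this sparse design (at most 7 samples per subject) identifies
  well; placement is configurable via `pop_model(iiv = ...)`.
* **Residual error.** Combined additive + proportional:
  $SD(C_{obs}\mid C_{pred}) = \sqrt{\sigma_1^2 + (C_{pred}\,\sigma_2)^2}$,
  with $\sigma_1$ in mg/L and $\sigma_2$ dimensionless.
* **Covariate effects.** Power laws normalized at a reference value,
  e.g. $V_1 = TV(V_1)\,(BW/61.4)^{\theta_{BW}}$. References default to the
  dataset median (re-derived when fitting new data); the shipped
  `txa_final_model()` carries the study medians 61.4 kg and 61.0 mL/min.
  The reference for $CL_{cr}$ is read in mL/min — 61.0 is the cohort
  median on that scale, which keeps the typical-patient arithmetic
  internally consistent.

## Estimation: FOCE with interaction

The marginal likelihood has no closed form; `txapk` uses the standard
first-order conditional approximation with interaction (FOCE-I). Per
subject, the inner problem minimizes the joint −2 log density
(`subject_objective()`) over $\eta$ by a damped Newton iteration (gradient
tolerance `1e-8`); the model is then linearized in $\eta$ around the
conditional mode $\hat\eta$, with the residual SD evaluated at the
conditional prediction, giving

$$OFV_i = n_i\log 2\pi + \log|V_i| + r_i^\top V_i^{-1} r_i,\qquad
  V_i = F_i\,\Omega\,F_i^\top + \Sigma(\hat\eta_i),\;
  r_i = y_i - f_i(\hat\eta_i) + F_i\hat\eta_i.$$

Derivatives $F_i = \partial f/\partial\eta$ are computed by complex-step
differentiation of the closed-form solution, exact to machine precision, so
the outer objective is smooth. The outer minimization runs `nlminb` on
log-transformed typical values, $\omega^2$ and $\sigma$ (exponents on the
natural scale) with relative tolerance `1e-6`, warm-starting each subject's
$\hat\eta$ across iterations. Standard errors come from the inverse central
finite-difference Hessian of $OFV/2$ (step `1e-4` on the transformed
scale), propagated through the log transform; `%RSE = 100·SE/estimate`.

The commercial FOCE-ELS implementation used in the original analysis is
proprietary; this engine is therefore validated against an *independent*
oracle: adaptive Gauss–Hermite quadrature of the exact marginal likelihood
on small problems (the test suite requires agreement within 0.5 OFV units
on 5-subject problems with one or two random effects, and within 0.1 on a
sparse single-subject problem).

Numerical edge cases handled explicitly:

* near-degenerate hybrid roots ($\alpha-\beta < 10^{-10}\alpha$) switch to
  the repeated-root closed form;
* $\omega^2$ below $10^{-12}$ pins the corresponding $\eta$ at zero (the
  OFV then collapses to the fixed-effect weighted deviance);
* non-finite predictions during optimization are replaced by a large
  penalty so the optimizer retreats; user-facing `ofv()` raises an error
  naming the subject instead.

## Model comparison and covariate search

Nested models are compared by the OFV difference against
$\chi^2$ quantiles; one extra parameter is significant at $p<0.01$ when the
OFV drops by more than 6.635. The covariate search is exhaustive
("shotgun"): all $2^k$ subsets of the candidate effects are fitted
($k \le 4$). Each table row reports its OFV change against the subset with
the last-added effect removed, mirroring the familiar ladder layout. For
*selection* we use the leave-one-out reading of the retain/remove rule —
a subset qualifies when dropping any single included effect raises the OFV
by more than 6.635 — and among qualifying subsets the lowest OFV wins, ties
going to fewer parameters. The published ladder is consistent with this
rule; a chain-based reading (each effect tested only against the order in
which it happened to be added) would make selection depend on candidate
ordering, which an exhaustive search is meant to avoid.

## Diagnostics and qualification

* **PRED/IPRED/CWRES** (`gof_diagnostics()`): population predictions at
  $\eta=0$, individual predictions at $\hat\eta$, and conditional weighted
  residuals — the residual about the FOCE-linearized marginal mean,
  whitened by the Cholesky factor of $V_i$. Under the generating model
  CWRES are approximately standard normal; the tests check mean, SD and
  skewness on a ~450-observation cohort.
* **VPC** (`vpc()`): simulates replicate datasets on the observed design
  (same subjects, covariates, doses, times) with fresh $\eta$ and
  $\varepsilon$; per time bin the 5th/50th/95th percentiles are computed in
  each replicate (quantile type 6, whose tail estimates are less biased
  than the default at bin sizes of tens of observations, keeping the band
  at its nominal level) and summarized by their across-replicate median.
  Binning
  follows the nominal sampling occasion (the 7 protocol times, carried in
  the `OCC` column) because the design is sparse at fixed occasions;
  continuous-time binning would split identical occasions across bins.
  Bins with fewer than two observations merge with a neighbor and the
  merge is logged. Simulated concentrations below zero are truncated at
  zero for percentile computation. The headline check is calibration:
  when the observations come from the same model that generates the band,
  the fraction inside the 90% band must sit in the binomial envelope
  [0.86, 0.94] at ~453 observations.
* **Bootstrap** (`bootstrap_model()`): subjects are resampled with
  replacement (original cohort size), each replicate refitted from the
  original point estimate — fast, stable, and meaning that a replicate
  failure indicates a genuinely uninformative resample. Converged
  replicates are summarized by median, 2.5%/97.5% percentiles and
  `%RSE = 100·SD/median` (the reporting convention for bootstrap tables;
  the original report does not state its formula). More than 50% failures
  aborts with a diagnostic.

## The synthetic cohort generator

No raw data accompany the study, so `cohort_design()` +
`simulate_dataset()` reproduce its *design*: 77 subjects; 51/77 male;
log-normal body weight, height and serum creatinine calibrated so median
and IQR match the reported cohort (61.4 [54.6–75.2] kg,
161.8 [156.5–170.7] cm, 85.7 [72.5–105.2] µmol/L; the log-normal is fitted
to the median and the symmetrized quartile ratio); truncated-normal age
(69 [60–75], range bounds 26–84); CPB duration log-normal
(170 [136–210] min). Dose 1 (1000 mg) at $t=0$; dose 2 (1000 mg) at CPB
discontinuation; nominal sampling 0.5/1/2/5 h after dose 1 and 1/6/16 h
after dose 2 with Gaussian jitter (SD 0.1 h, reflecting the protocol's
"approximately"); any dose-1 sample falling at or after the second dose is
dropped — with the median CPB duration under 3 h this removes most 5-h
draws and lands the realized sample count near the reported 453 out of the
nominal 539 slots.

Generation truth defaults to the published fixed effects
($V_1$ 12.77 L, $V_2$ 6.857 L, $CL_1$ 3.263 L/h, $CL_2$ 2.859 L/h;
exponents 0.911 and 0.752). The study does not report its variance
components, so the defaults are conventional pharmacometric magnitudes
fixed once in `txa_truth()`: 30% CV IIV on $CL_1$ and $V_1$
($\omega^2 = 0.09$) and combined error $\sigma_1 = 1$ mg/L,
$\sigma_2 = 0.15$.

What the generator deliberately does **not** emulate: correlation between
covariates (only marginals are reported; $CL_{cr}$ and BSA are *computed*
from the drawn covariates, which induces the physiological part of the
correlation), CPB-circuit sequestration and hemodilution dynamics, bleeding
or ultrafiltration losses, and the study's three low-concentration outlier
patients, for which no quantitative mechanism is reported. Passing tests on
these cohorts therefore demonstrate correctness of the estimation machinery
under the stated design — not robustness to the unmodeled clinical
phenomena above.

## Worked example

```{r example, eval = FALSE}
ds  <- simulate_dataset(cohort_design(), txa_truth(), seed = 1)
fit <- fit_population(ds, txa_final_model())
fit
vpc(evaluate_model(ds, txa_final_model(), txa_truth()),
    n_replicates = 200, seed = 11)
```

A typical patient at the covariate references has
$CL_1 = 3.263\,(60/61)^{0.752} = 3.223$ L/h at $CL_{cr} = 60$ mL/min and
$V_1 = 12.77$ L at 61.4 kg — the arithmetic `apply_covariates()` reproduces
exactly.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit integer seed and is bit-for-bit
reproducible from it (datasets, VPC, bootstrap, pipeline artifacts). The
shipped experiments use sizes chosen to exercise the statistics they check:
the full 77-subject design for parameter recovery (10 seeds), CWRES
calibration and VPC coverage (200 replicates); reduced cohorts
(n = 30–40) for the exhaustive covariate search and its 20-replicate
decoy-rejection experiment; and n = 30 with 30 replicates for the bootstrap
consistency check. Validation replicate counts for reported analyses
default to the conventional 1000.

## Known limitations

* Boluses only — no infusions or oral absorption; no saturable elimination.
* Diagonal $\Omega$; no inter-occasion variability or mixture models.
* Residual models: additive or combined (a pure proportional model is the
  small-$\sigma_1$ limit of the combined model).
* FOCE-I is an approximation; agreement is asserted against quadrature on
  small problems, not against the proprietary implementation's output.
* No below-quantitation-limit handling: all positive observations enter
  the likelihood, matching the reported analysis.
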