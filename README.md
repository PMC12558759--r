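# matrinepk

Minimal physiologically based pharmacokinetics (PBPK) of the alkaloid
**matrine in the pig intestinal lumen** after oral dosing.

Matrine restores the susceptibility of *Escherichia coli* to several
antibiotics in vitro, which makes it a candidate adjunct for porcine
colibacillosis — but the infection site is the intestinal lumen, so the
exposure that matters is the drug concentration in intestinal contents,
not plasma. This package implements the analysis workflow around a
minimal four-compartment, flow-limited PBPK model of that exposure:

* **Forward simulation** of single and repeated oral doses
  (`pk_simulate()`), with a stomach depot emptying first-order into the
  lumen, absorption into blood, biliary recirculation back to the lumen,
  fecal excretion, and renal elimination from a lumped other-organs
  space. The mass-balance equations, with amounts `A_i`, concentrations
  `C_i = A_i/V_i`, and free arterial concentration `Ca = C_b (1 − Pb)`:

  ```
  dA_st/dt  = −k_st A_st
  dA_int/dt =  k_st A_st + k_bi A_l − (k_a + k_e) A_int
  dA_l/dt   =  Q_l (Ca − C_l/P_l) − k_bi A_l
  dA_ot/dt  =  Q_ot (Ca − C_ot/P_ot) − Ca Cl_renal BW
  dA_b/dt   =  f_a k_a A_int + Q_l C_l/P_l + Q_ot C_ot/P_ot − Q_tot Ca
  ```

* **Non-compartmental analysis** (`nca()`, `nca_by_subject()`): Cmax,
  Tmax, linear-trapezoidal AUC, terminal slope λz by
  best-adjusted-R² suffix regression, t½ = 0.693/λz, MRT, CL/F, V/F.
* **Maximum-likelihood estimation** (`pk_fit()`, `pk_fit_batches()`):
  Nelder–Mead on a log-normal likelihood with bound-respecting
  transforms and staged (batched) optimization.
* **Local sensitivity analysis** (`pk_sensitivity()`): ±0.1%
  central-difference normalized sensitivity coefficients (NSC) per time
  slice; |NSC| > 0.1 flags sensitive parameters.
* **PK/PD regimen metrics** (`steady_state_window()`,
  `time_above_threshold()`, `cmax_ratio()`, `regimen_metrics()`):
  steady-state intestinal Cmax and the percentage of a 24-h window above
  the in vitro effective window (300–500 µg/g).
* **Evaluation statistics** (`eval_pred_obs()`, `one_sample_t()`,
  `two_sample_t()`) for predicted-versus-observed assessment.
* **Synthetic cohorts** (`cohort_spec()`, `sample_cohort()`,
  `generate_observations()`): virtual pigs with lognormal
  inter-individual variability, multiplicative residual error and
  censoring at the 2 µg/kg quantification limit, emulating both the
  single-dose cannulated-pig design and the repeat-dose sacrifice
  design.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on results. A thin command
line (`mt_cli()`, wrapper in `inst/scripts/matrinepk`) exposes
`simulate`, `nca`, `fit`, `sensitivity`, `regimen`, `evaluate` and
`generate` subcommands.

## Worked example

Simulate a single oral 40 mg/kg dose in a 27 kg pig with the optimized
parameter set, run NCA on the simulated lumen profile, then evaluate the
recommended repeat regimen:

```r
library(matrinepk)

params <- mt_params(BW = 27)                  # optimized parameter set
sim <- pk_simulate(params, dose_regimen(40, 0, bw_kg = 27))
prof <- ct_profile(1L, sim$time_h, sim$C_int_ug_per_kg)
nca(prof, dose_mg_per_kg = 40)
#>   cmax_ug_per_L tmax_h auc_0_t lambda_z t_half_h  mrt_h cl_f_L_h_kg v_f_L_kg
#> 1      839986.3      1 2718864   0.0272   25.516 3.0176      0.0147   0.5413

regimen_metrics(params, dose_mg_per_kg = 70, interval_h = 8)
#>   dose_mg_per_kg interval_h bw_kg ss_day threshold_ug_per_g cmax_ug_per_L cmax_ratio pct_above
#> 1             70          8    27      2                300       1504814       5.02     57.44
#> 2             70          8    27      2                500       1504814       3.01     46.12
```

Reading the output: the simulated single-dose lumen profile peaks at
~840,000 µg/L one hour post dose with AUC(0–120 h) ≈ 2.72 × 10⁶ h·µg/L
and a terminal half-life of ~25 h — inside the observed animal ranges
(e.g. group mean Cmax 783,916.7 ± 324,337 µg/L, AUC 2,684,040 ±
359,993 h·µg/L, CL/F 0.0151 ± 0.0019 L/h/kg). Under 70 mg/kg every 8 h
the lumen reaches steady state on day 2; the steady-state peak is 3.0×
the upper (500 µg/g) effective concentration, and the concentration
stays above the lower 300 µg/g bound for 57.4% of the day — the basis
for recommending repeated rather than single dosing.

A synthetic study in three lines:

```r
spec <- cohort_spec(n_subjects = 6, dose_mg_per_kg = 40, seed = 1)
obs <- generate_observations(sample_cohort(spec, params))
fit <- pk_fit(obs, dose_regimen(40, 0, 27), start = mt_params_start(),
              fit = c("k_st", "k_a", "k_bi"))
tidy(fit)
```

## Package layout

```
R/                 model, NCA, estimation, sensitivity, PK/PD, synthetic data, CLI
inst/extdata/      packaged parameter files (optimized and starting values)
inst/scripts/      command-line wrapper
tests/testthat/    unit, property and acceptance tests (oracles in helper-oracles.R)
vignettes/         methods vignette: model reading, numerical choices, limitations
scripts/           acceptance script
```

See `vignettes/matrine-pbpk-methods.Rmd` for the model equations, the
reading of the protein-binding and bioavailability terms, numerical
tolerances, what the synthetic generator does and does not emulate, and
known limitations.
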