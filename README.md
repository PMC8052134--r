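# cyclopop

Population pharmacokinetics and Bayesian forecasting of cyclosporine from
therapeutic drug monitoring (TDM) data.

Cyclosporine (CsA) is a narrow-therapeutic-index immunosuppressant with
large between-patient and between-visit variability; dosing is guided by
whole-blood concentration monitoring. `cyclopop` implements the full
model-informed precision dosing workflow around a published population model
for adult TDM patients:

* **Structural model** — two-compartment disposition with lagged first-order
  oral absorption, parametrised as `tlag`, `ka`, `Cl/F`, `Q/F`, `V1`, `V2`
  (apparent, oral dosing). Closed-form steady-state/multi-dose profiles plus
  an independent ODE oracle (`pk_concentration()`, `ode_concentration()`,
  `auc_tau()`).
* **Population model** — log-normal inter-individual variability on `Cl/F`
  and `Q/F`, inter-occasion variability on `tlag`, `ka`, `Cl/F` with a
  correlated occasion-level `ka`–`Cl` pair; clearance scales with creatinine
  clearance as `Cl = Cl_pop (ClCr/98.62)^-0.204`; combined residual error
  `sd = 7.52 + 0.228 C` ng/mL (`pop_params()`, `individual_parameters()`,
  `cockcroft_gault()`).
* **Estimation** — SAEM maximum likelihood (`saem_fit()`),
  importance-sampling log-likelihood and AIC (`log_likelihood()`), stepwise
  likelihood-ratio covariate search (`covariate_search()`; forward
  ΔOFV ≥ 3.84, backward 6.63).
* **Forecasting** — MAP empirical-Bayes individual estimation
  (`estimate_individual()`) and the sequential occasion-by-occasion workflow
  (`sequential_forecast()`) with rIPE / MPPE / rRMSE predictive-performance
  metrics.
* **Diagnostics** — prediction-corrected VPC (`pcvpc()`), normalized
  prediction distribution errors (`npde()`), with `autoplot()` methods.
* **Synthetic data** — cohort and TDM dataset generators that emulate the
  study design (37 training subjects, 0–4 h steady-state profiles over 1–4
  occasions; a sparse 16-subject forecasting group), so the whole pipeline
  is testable without clinical data (`generate_cohort()`,
  `generate_training_dataset()`, `generate_forecasting_cohort()`).

Fitted objects follow broom conventions (`tidy()`, `glance()`) and datasets
are plain tibbles in a NONMEM-style CSV layout (`read_tdm()` /
`write_tdm()`; `TIME` is hours after the most recent dose).

## Worked example

Simulate a synthetic TDM study under the packaged final model, refit it, and
forecast a sparse patient:

```r
library(cyclopop)

pop <- pop_params()          # published final model
pop
#> <pop_params> population pharmacokinetic parameters
#>   typical: tlag 0.512 h, ka 0.523 1/h, Cl/F 30.3 L/h, Q/F 17 L/h, V1 17.9 L, V2 400 L
#>   covariate: Cl ~ (ClCr/98.62)^-0.204
#>   IIV CV%: Cl 39.8, Q 53.2 | IOV CV%: Cl 38.0, tlag 54.1, ka 52.6 (rho ka-Cl -0.551)
#>   residual: sd(C) = 7.52 + 0.228 * C ng/mL

# a steady-state 0-4 h profile for the typical patient (150 mg q12h)
p <- pk_params(0.512, 0.523, 30.3, 17, 17.9, 400)
pk_concentration(p, dosing_regimen(150, 12, TRUE), times = 0:4)
#> # A tibble: 5 × 2
#>    time  conc
#>   <dbl> <dbl>
#> 1     0  142.
#> 2     1 1171.
#> 3     2 1056.
#> 4     3  714.
#> 5     4  491.
auc_tau(p, dosing_regimen(150, 12, TRUE))   # = 1000*150/30.3
#> [1] 4950.495
```

The trough (C0 ≈ 142 ng/mL) reflects the accumulated tail of earlier doses;
the 1-h peak (~1170 ng/mL) follows the 0.5-h absorption lag; the
steady-state exposure AUCτ equals dose/(Cl/F) exactly.

```r
# synthetic training study + SAEM refit
dat <- generate_training_dataset(pop, cohort_profile(), seed = 1)
fit <- saem_fit(dat, control = saem_control(seed = 2))   # ~2-3 min
tidy(fit)              # population estimates (+ CV% for variabilities)
autoplot(fit)          # convergence trajectories

# sequential Bayesian forecasting on a sparse cohort
fc <- generate_forecasting_cohort(pop, n = 16, seed = 3)
report <- sequential_forecast(pop, fc)
report$by_occasion     # MPPE / MAPE / rRMSE per occasion
autoplot(report)       # rIPE boxplots vs occasion
```

In `report$by_occasion`, occasion 1 is predicted from the population model
and covariates alone; later occasions use MAP estimates from earlier visits
— the absolute errors shrink as occasions accumulate, the signature of
Bayesian forecasting.

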