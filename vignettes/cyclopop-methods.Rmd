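---
title: "Population pharmacokinetics of cyclosporine: model, estimation and forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of cyclosporine: model, estimation and forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cyclopop implements a complete population-pharmacokinetic workflow for
cyclosporine (CsA) therapeutic drug monitoring: a two-compartment structural
model with lagged first-order oral absorption, a nonlinear mixed-effects
variability model with a renal-function covariate, SAEM maximum-likelihood
estimation, MAP (empirical-Bayes) individual estimation with sequential
occasion-by-occasion forecasting, and the standard simulation-based
diagnostics (pcVPC, NPDE). This vignette is the package's account of the
science: the model and its assumptions, the numerical choices, and what the
synthetic-data experiments do and do not demonstrate.

## Structural model

Whole-blood CsA concentrations after oral dosing are described by a
two-compartment disposition model with first-order elimination and a lagged
first-order absorption:

$$
\frac{dA_d}{dt} = -k_a A_d,\qquad
\frac{dA_1}{dt} = k_a A_d - (k_{10}+k_{12})A_1 + k_{21}A_2,\qquad
\frac{dA_2}{dt} = k_{12}A_1 - k_{21}A_2,
$$

with the dose entering the depot $A_d$ at `tlag` hours after intake, and
micro-constants $k_{10} = Cl/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$. All
disposition parameters are *apparent* (scaled by the unknown oral
bioavailability $F$), the identifiable quantities after oral dosing. The
central concentration is the triexponential closed form with hybrid rate
constants $\lambda_1 > \lambda_2$ (`pk_concentration()`); at steady state
under a $\tau$-periodic regimen every exponential term carries its
accumulation factor $1/(1-e^{-\lambda\tau})$, so the pre-dose tail of earlier
doses persists through the lag window. Internal computation uses mg, L and
hours; the interface reports ng/mL (the immunoassay scale).

Two numerical choices matter here:

* **Coincident rates.** When $k_a$ collides with a disposition eigenvalue
  (relative distance below $10^{-8}$) the closed form degenerates; the
  package perturbs $k_a$ by $10^{-7}$ relative rather than implementing the
  confluent limit. The case has measure zero and the induced error is far
  below the residual error scale.
* **Oracle route.** `ode_concentration()` integrates the three-state system
  with `deSolve::lsoda` (lagged bolus as an event; steady state by simulating
  intervals until the within-interval profile changes by less than $10^{-8}$
  relative). It exists purely as an independent check of the closed form —
  the test suite verifies agreement to better than $10^{-5}$ relative over
  1,000 random parameter sets — and is never used inside estimation loops,
  where the closed form is orders of magnitude faster.

The steady-state exposure identity $AUC_\tau = \text{dose}/(Cl/F)$ holds
exactly in the model and is verified against quadrature of the profile.

## Variability and covariate model

Each structural parameter is log-normal around its typical value
($\theta_i = \theta_{pop} e^{\eta_i}$). The final model places
inter-individual variability (IIV) on $Cl/F$ and $Q/F$, and inter-occasion
variability (IOV, redrawn at every monitoring visit) on `tlag`, $k_a$ and
$Cl/F$, with a correlation between the occasion-level $k_a$ and $Cl$
effects. Variabilities are reported as coefficients of variation,
$CV\% = 100\sqrt{e^{\omega^2}-1}$. The only covariate is creatinine
clearance on clearance,

$$
Cl_i = Cl_{pop}\,\left(\frac{ClCr_i}{ClCr_{ref}}\right)^{\beta}\,
e^{\eta_{Cl,i} + \kappa_{Cl,ik}},
$$

with $ClCr_{ref} = 98.62$ mL/min and $\beta = -0.204$ in the packaged final
model (`pop_params()`, also shipped as a flat config file under
`inst/extdata/`). Creatinine clearance is computed from serum creatinine by
Cockcroft–Gault. A missing covariate is a hard error — the package never
imputes silently.

Two conventions deserve an explicit note because the source material is
ambiguous about them:

* **Residual error.** The residual model is the standard "combined-1" form
  $Y = C + (\sigma_{add} + \sigma_{prop}\,C)\,\varepsilon$,
  $\varepsilon \sim N(0,1)$. A purely multiplicative reading
  ($Y = C(1+\varepsilon_{prop}+\varepsilon_{add})$) would be dimensionally
  inconsistent with an additive sd quoted in ng/mL; combined-1 is also the
  convention of the estimation software under which the reference estimates
  were produced.
* **CV conversion.** $CV\% = 100\sqrt{e^{\omega^2}-1}$ (with the square
  root); the conversion is exactly invertible and the packaged variances
  round-trip through the published CV percentages.
* **Placement of the ka–Cl correlation.** $k_a$ carries no IIV term while
  both $k_a$ and $Cl$ carry IOV, so the $-0.551$ correlation is placed
  between the occasion-level effects. Whether the occasion is a visit or a
  hospitalisation episode is not specified in the source; one visit = one
  occasion is assumed throughout.

## Synthetic study generator

No clinical data ship with the package; every experiment runs on synthetic
cohorts that emulate the study design the model came from:

* **Demographics** (`cohort_profile()`, `generate_cohort()`): 37 subjects
  (16 M / 21 F), age 34.4 ± 15.85 y and weight 64.3 ± 11.0 kg from truncated
  normals (bounds 12–85 y, 35–120 kg). The truncated distribution itself is
  moment-matched: the parent parameters are solved so the *truncated* mean
  and sd equal the targets (naive truncation would shift the age mean up by
  ~2.5 y). Serum creatinine is log-normal with median 1.0 mg/dL and log-sd
  0.5, chosen so the sample mean (~1.1 mg/dL) and the derived
  creatinine-clearance mean (~98.6 mL/min) match the cohort table; the wide
  published ClCr range emerges from the creatinine tail rather than from
  independent sampling. Creatinine clearance is always *derived* via
  Cockcroft–Gault from the generated age/weight/SCr/sex, preserving the
  covariate-formula linkage exactly.
* **Design**: steady-state profiles sampled at 0/1/2/3/4 h post-dose;
  occasions per subject drawn from {1: 40%, 2: 30%, 3: 20%, 4: 10%}, chosen
  so the expected observations per subject (~11–12) is of the order of the
  ~17 in the original training data. The dose is fixed at 150 mg q12h — the
  source reports no dosing amounts, so this is a package convention, not a
  reproduced value, and it is configurable per subject.
* **Forecasting cohort** (`generate_forecasting_cohort()`): 16 subjects with
  2–4 occasions; occasion 1 a short C0/C1/C2 profile, later occasions 1–3
  sparse samples among 0/1/2 h — totalling on the order of the 81
  observations in the original evaluation group.
* **Censoring**: raw simulated values are kept as drawn (they can dip below
  the 12.5 ng/mL assay quantification limit when the additive error is
  inflated); an optional switch truncates at the LLOQ. How sub-LLOQ values
  were handled in the original estimation is unreported, so the default
  leaves them untouched.

What passing tests on these data show: that the estimation and forecasting
machinery recovers known truth under the study's design and noise levels.
What they cannot show: robustness to real-data features the generator does
not emulate — model misspecification, within-subject creatinine drift,
irregular sampling times, dose changes mid-study, assay artefacts.

## SAEM estimation

`saem_fit()` maximises the marginal likelihood by stochastic approximation
EM. The E-step samples each subject's random effects from their conditional
posterior by Metropolis-within-Gibbs with four kernels per sweep
(two sweeps per iteration by default):

1. an independence kernel proposing from the prior;
2. a componentwise random walk, scale adapted during burn-in toward ~30%
   acceptance;
3. a joint random walk over all components;
4. a *decomposition-swap* kernel specific to the IIV + IOV structure on
   clearance: it shifts mass between $\eta_{Cl}$ and all of the subject's
   $\kappa_{Cl,k}$ simultaneously. The realised parameters — hence the
   likelihood — are unchanged, so the move is accepted on the prior ratio
   alone. This mixes the between/within-subject variance split, which the
   generic kernels traverse slowly; without it the IIV of clearance is
   systematically under-dispersed at this design size.

The M-step combines three update types:

* **Variance components** (closed form): stochastic-approximation averages of
  the sampled second moments, with the grand means of the sampled effects
  first *recentred* into the fixed effects (an exact reparametrisation that
  leaves every realised individual parameter unchanged). Recentring is what
  lets the typical values track the data even though they enter the
  structural model nonlinearly; without it the population means stall while
  the random effects absorb the offset and the IOV variances inflate.
* **Covariate coefficients** on parameters that carry random effects: a
  regression of the subject-level sampled deviation on the design column,
  applied as the same kind of likelihood-preserving reshuffle.
* **Remaining fixed effects and residual sigmas** (no closed form): a short
  bounded quasi-Newton maximisation of the complete-data likelihood given
  the current samples, relaxed with the SAEM step size. The box bounds
  (±log 50 around the starting values) keep structurally flat directions —
  chiefly $V_2$, which a steady-state 0–4 h design barely identifies — from
  random-walking to absurd values.

Step size is 1 for 300 burn-in iterations and $k^{-0.7}$ for 200 smoothing
iterations (the standard two-phase schedule); the reported estimate is the
smoothing-phase average of the trajectory (geometric for positive
parameters), which damps the residual Monte-Carlo noise of the final
iterate. During burn-in a variance component may shrink by at most 5% per
iteration (a simulated-annealing constraint): premature collapse is
otherwise an absorbing state, because the proposal scales of the sampler
track the prior standard deviations. Chain lengths, kernel counts and initial values are package
conventions chosen from standard SAEM practice — the reference software's
internals are unpublished. Default initial values are deliberately generic
(clearance from a crude AUC of the observed profiles, all variabilities at
30% CV); the recovery experiments start there, not at the truth. Variances
are floored at $10^{-10}$ with a warning (collapse detection), and the
correlation is clamped to ±0.95.

At the study scale (37 subjects × 3 occasions × 5 samples, ~555
observations) a default fit takes roughly 2–3 minutes on one core. The
recovery experiment in the acceptance suite checks each recovered parameter
against three relative standard errors of the reference fit — the
uncertainty the original design itself implies.

The observed-data log-likelihood for AIC and likelihood-ratio testing is
computed by `log_likelihood()` with importance sampling (default 5,000
draws/subject from a 4-df multivariate t centred at the subject's MAP mode,
scaled by the local curvature; the Monte-Carlo sd is reported alongside) —
never from the SAEM trajectory, so nested models are compared on a common
footing. `covariate_search()` wraps the stepwise procedure: forward
inclusion at ΔOFV ≥ 3.84 (χ², 1 df, 5%), backward deletion retaining only
covariates whose removal costs ≥ 6.63 (1%).

## MAP estimation and sequential forecasting

`estimate_individual()` minimises
$\sum_j \left[(y_j-f_j)^2/g_j^2 + \log g_j^2\right] + \eta'\Omega^{-1}\eta +
\sum_k \kappa_k'\Gamma^{-1}\kappa_k$ over all effects informed by the data
(effects of unobserved occasions stay at the prior mode 0). The optimiser is
BFGS from the prior mode plus four jittered restarts, with a derivative-free
fallback and polish cycles — near-noise-free objectives are extremely sharp
and can defeat a single quasi-Newton pass. One identifiability caveat is
documented rather than blocked: with IIV *and* IOV on clearance, a subject's
data pin down the per-occasion sums $\eta_{Cl}+\kappa_{Cl,k}$, while the
split between them is prior-determined; the realised per-occasion parameters
are the well-identified quantities. A history consisting of a single trough
sample still updates $\eta_{Cl}$, with correspondingly heavy shrinkage.

`sequential_forecast()` reproduces the TDM evaluation loop: occasion 1 is
predicted from the population model and covariates alone; occasion $k\ge 2$
from MAP effects estimated on occasions $1..k\!-\!1$, with the forecast
occasion's IOV effects at 0 (point prediction at the conditional mode).
By construction no observation of occasion $k$ enters its own prediction.
Accuracy is summarised per occasion and per sampling-time label (C0, C1,
…) as the signed mean percentage error (MPPE), its absolute companion
(MAPE — reported because "mean percentage error" is often quoted as a
magnitude), and the relative root-mean-squared error (rRMSE). The
acceptance experiment simulates 400 three-occasion patients — with the
observations floored at the assay quantification limit, as any reported TDM
concentration is — and verifies that the mean absolute rIPE strictly
decreases from occasion 1 to occasions 2 and 3, with significance assessed
by one-sided paired Wilcoxon signed-rank tests at α = 0.05 (the per-patient
differences are heavily right-skewed, which is exactly the situation the
signed-rank test is built for): the qualitative improvement pattern that
motivates Bayesian forecasting, checked as a property because the original
cohort's numbers depend on unavailable clinical data. Without the
quantification-limit floor, simulated troughs arbitrarily close to zero put
unbounded mass in the right tail of the relative errors and any mean-based
comparison loses its power for what is, on the log scale, a clear
improvement.

## Diagnostics

* **NPDE** (`npde()`): observations are decorrelated per subject with the
  inverse Cholesky factor of the empirical covariance of (default 1,000)
  simulated replicates; the rank-based discrepancy is mapped through
  $\Phi^{-1}$, with the $1/(2K)$ correction at the bounds and a ridge
  fallback for singular empirical covariances. Under the null
  (self-simulated data) the suite requires mean within ±0.1 and variance in
  [0.85, 1.15] at 500 observations.
* **pcVPC** (`pcvpc()`): each observed and simulated value is rescaled by
  the typical population prediction, enabling pooling across heterogeneous
  doses and covariates — the defining advantage over a raw VPC, verified by
  a mixed-dose experiment in the tests. Binning defaults to one bin per
  nominal sampling time (the design is nominal-time) with quantile bins as
  the fallback for irregular times; the bin reference is the median typical
  prediction in the bin. Displayed percentiles default to 10/50/90 with a
  95% simulated confidence band from 500 replicates; the percentile choice
  is configurable (figure captions in the source material disagree between
  10/90 and 5/95).

## Problem sizes and limitations

Test and acceptance experiment sizes were chosen as the smallest that make
each scientific property unambiguous: the oracle equivalence uses 1,000
random parameter sets; recovery runs at the study's own scale (one dataset,
~555 observations); the forecasting trend uses 400 simulated patients;
NPDE calibration uses 500 observations × 1,000 replicates and the pcVPC
coverage check 20 independent experiments (its per-bin coverage was
measured at ~95% over a larger calibration run). Known
limitations: $V_2$ (and to a lesser degree $V_1$) is weakly identified by a
steady-state 0–4 h design, exactly as the large reference RSEs indicate;
the IOV of `tlag` tends to be under-estimated at this design size; standard
errors of the population fit are not computed (no Fisher-information
machinery — resampling the synthetic pipeline is the intended route to
uncertainty); and categorical covariate relations are not implemented in
the search (the final model contains none).
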