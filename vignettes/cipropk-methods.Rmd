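---
title: "Population pharmacokinetics of intravenous ciprofloxacin in the ICU: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of intravenous ciprofloxacin in the ICU: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipropk)
```

## The problem

Critically ill patients handle drugs very differently from the stable
patients in whom standard antibiotic doses were established: volumes of
distribution expand, clearance can be either augmented or impaired, and the
spread between patients is large. For a concentration-dependent antibiotic
such as ciprofloxacin, whose efficacy tracks the ratio of free-drug exposure
to the pathogen's minimal inhibitory concentration (fAUC~0–24~/MIC ≥ 100,
fC~max~/MIC ≥ 8), this variability translates directly into a risk of
underdosing. `cipropk` implements the full population-pharmacokinetic
workflow used to quantify that risk from sparse intensive-care sampling:
structural model, nonlinear mixed-effects estimation, covariate screening,
model qualification, and Monte Carlo dosing simulations — together with a
synthetic-cohort generator that emulates the observed study design, so every
step is testable end-to-end without access to patient data.

## Structural model

Disposition is a two-compartment model with zero-order (infusion) input,
parameterized by clearance $CL$ (L/h), central volume $V_c$ (L), peripheral
volume $V_p$ (L) and inter-compartmental clearance $Q$ (L/h). The micro
constants are $k_{10} = CL/V_c$, $k_{12} = Q/V_c$, $k_{21} = Q/V_p$, and the
disposition exponents $\alpha > \beta$ solve
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$. Concentrations are
evaluated in closed form (`concentration()`): during an infusion of rate
$R_0$ each exponential term accumulates as $(1-e^{-\lambda t})$, after the
infusion it decays, and multiple doses superpose. Steady state uses the
accumulation-factor form $1/(1-e^{-\lambda\tau})$ exactly rather than
simulating many doses; day-2 fitting and simulation instead carry the full
dose history, because sampling on the second day of therapy is close to,
but not exactly at, steady state for the longer intervals. Closed-form
profiles are verified against numerical integration of the underlying ODE
system to 10^-6^ relative tolerance in the test suite.

Free (unbound) exposure uses a fixed unbound fraction $f_u = 0.7$
(30% plasma protein binding): $fAUC_{24} = f_u \cdot D_{24}/CL$ by
linearity, $fC_{max}$ is the model concentration at the end of a
steady-state infusion — the true maximum for intravenous infusion — and
$fC_{min}$ the end-of-interval trough. The sampled "peak" drawn 15–30 min
after the end of the infusion is a property of the sampling design and is
handled by the cohort generator, not by the exposure metrics.

## Population model

Between-subject variability is log-normal,
$P_j = \theta_P \cdot \prod_k m_{jk} \cdot e^{\eta_{P,j}}$, with
$\eta \sim N(0, \Omega)$. The default $\Omega$ is a 2×2 block on
$(CL, V_c)$ with correlation 0.5: the published analysis reports
variability of 67.8% on $CL$ and 51.0% on $V_c$ with a covariance block but
does not print the covariance itself, so the correlation is a package
default chosen as a typical positive value — it affects only the realism of
simulated cohorts, and is configurable (`cipro_final_model(cl_vc_corr =)`).
A diagonal variance on $Q$ can be added with `iiv_q =`; it is off by
default because the published parameter table reports variability for $CL$
and $V_c$ only. Variability is reported as $CV\% = 100\sqrt{\omega^2}$, the
common pharmacometric convention, under which 67.8% maps exactly to
$\omega = 0.678$.

Residual error is combined proportional-plus-additive,
$y = f(1+\varepsilon_p) + \varepsilon_a$, with defaults
$\sigma_p = 0.153$ (15.3%) and $\sigma_a = 0.143$ mg/L.

Covariate relations are multiplicative and composable: continuous
covariates enter as power functions normalized to the population median,
$\theta_i = \theta_{pop}(cov_i/cov_m)^{\theta_{cov}}$, binary covariates as
multipliers $\theta_{cov}^{cov_i}$.

## Estimation

`fit_poppk()` maximizes an approximate marginal likelihood of the
first-order-conditional-with-interaction family: for each subject the joint
$-2\log$-density $h(\eta)$ is minimized over $\eta$ (a damped Newton
iteration with finite-difference derivatives, vectorized across subjects,
with a trust region of 2 on the log scale and Levenberg-style safeguarding
of indefinite Hessians), and the Laplace correction
$\log\det(H/2)$ is added at the mode, with the residual variance evaluated
at individual predictions (the "interaction"). All $2\pi$ constants are
kept, so with $\Omega = 0$ the objective equals the exact Gaussian
deviance — one of the oracle checks in the test suite. Because a NONMEM
OFV carries different additive constants, objective values are not
comparable across implementations; all acceptance is therefore by parameter
recovery, never by OFV matching.

Free parameters are transformed to an unconstrained scale: typical values
and residual SDs as logarithms, $\Omega$ through its Cholesky factor with
logged diagonal. The outer optimization is restarted Nelder-Mead (fresh
simplex after each 500-iteration pass, stopping when a restart improves the
objective by less than 0.01); random-effect modes are warm-started between
objective evaluations, and the reported objective is recomputed from a cold
start so that fitted results are reproducible independent of the
optimization path. Standard errors come from the finite-difference observed
information (step 0.01 on the unconstrained scale, wide enough that
inner-optimization noise is negligible) and a numerical delta method to the
reported natural-scale quantities; they are reported as percent relative
standard errors.

Shrinkage follows the usual conventions:
$100(1-SD(\hat\eta)/\omega)$ per random effect and $100(1-SD(IWRES))$ for
the residual. Observations below the assay's lower limit of quantification
(0.04 mg/L) are discarded with a recorded count — the M1 policy — both by
the CSV reader and by the cohort generator.

## Covariate search

`covariate_search()` implements greedy forward inclusion followed by
backward elimination: a candidate enters if it lowers the objective by at
least 3.84 ($\chi^2_1$, p = 0.05; the best qualifying candidate per round,
ties broken by list order), and survivors are retained only if their
removal raises the objective by strictly more than 10.83 (p = 0.001).
Candidate fits that fail to converge are skipped with a warning. The test
suite checks both calibration (the forward step admits a spurious covariate
in ≈5% of null datasets) and power (a strong simulated eGFR effect on
clearance, exponent 0.75 at 100 subjects, is selected essentially always).

## Model qualification

* **Bootstrap** (`bootstrap_poppk()`): subjects are resampled with
  replacement (optionally stratified by dose interval — the published
  analysis does not state stratification, so it is off by default), each
  resample refitted, and percentile intervals taken over successful fits;
  failures are counted and a result with more than 50% failures is flagged.
* **VPC** (`vpc()`): replicates of the dataset are simulated at the
  original design; observed median and 5th/95th percentiles per
  time-after-dose bin are compared with the simulated 95% confidence bands
  of the same percentiles. Default bins split time-after-dose at its
  quintiles, which reproduces the five nominal sampling occasions of the
  design; explicit edges can be supplied. A prediction-corrected variant is
  available but off by default, matching a plain VPC.
* **NPDE** (`npde()`): the standard decorrelation algorithm — per subject,
  simulated vectors are mean-centered and whitened by the inverse Cholesky
  factor of their empirical covariance (ridge-regularized with a warning if
  singular), the observed vector is whitened identically, each observation's
  percentile among its simulated counterparts is clipped to
  $(1/2K, 1-1/2K)$ and probit-transformed. Under the generating model the
  NPDEs are close to standard normal; the suite checks mean and variance
  within three standard errors and Shapiro-Wilk behavior. The simulation
  count is not stated in the published analysis; the default is 1000.
* **Goodness of fit** (`gof()`): population and individual predictions,
  IWRES, and CWRES from a first-order linearization around the
  empirical-Bayes mode with interaction.

## Dosing simulations

`simulate_pta()` samples virtual patients from the population model,
computes steady-state free exposure per patient, and reports the fraction
attaining the target across a doubling-dilution MIC grid
(0.0312–8 mg/L by default), with 95% and 99% bands from a normal
approximation over 20 batches of the virtual cohort (the published
simulation software does not document its interval method; batching is a
transparent choice). Because the fAUC target depends on clearance alone,
a closed-form oracle exists:
$PTA = \Phi\!\left(\log\frac{f_u D_{24}/(100\,MIC)}{CL_{pop}}\Big/\omega_{CL}\right)$,
implemented in `pta_closed_form()` and used to validate the Monte Carlo
engine within sampling error. The fC~max~ target involves all four
structural parameters and is validated against a brute-force fine-grid
maximum instead.

Individual-level PTA computed this way does not reproduce the published
claim that 1200 mg/day attains ≥95% PTA at MIC 0.25 mg/L: at the final
parameter estimates the closed form gives ≈0.66 at that dose and MIC, and
the published figure is only consistent with an attainment criterion based
on the typical-value exposure ("required on average"). Both views are
available here — the typical-value curve is the $\omega = 0$ limit — and
the package asserts only the individual-level definition, which is the one
the Monte Carlo method actually samples. Virtual-patient covariates are not
simulated, since the final model carries no covariate effects.

## The synthetic cohort generator

`generate_cohort()` emulates the observed study design: 42 patients split
3/25/14 across 400 mg q24h/q12h/q8h, 1 h infusions (the study reports
30–60 min without a per-patient rule; 1 h is the package default and
configurable), dosing from therapy start through day 2, and five samples in
one day-2 interval — pre-dose trough, a peak drawn uniformly 0.25–0.5 h
after the end of the infusion, 1 h and 3 h post-infusion, and the
next pre-dose trough. Each planned sample is dropped independently with
probability 0.03, the package's reading of the study's 204 observed of 210
nominal samples; observations simulated below 0.04 mg/L are censored (M1)
with a recorded count. Covariates are drawn from log-normal marginals
matched to the published medians and interquartile ranges (body-mass index
is matched to its published bracket as a min–max range, since 17.8–46.3 is
far too wide for an IQR at median 26); sex and renal-replacement flags are
Bernoulli with the published frequencies 25/42 and 10/42. An optional flag
reproduces the study's dose-by-renal-function confounding (group eGFR
medians 28/52/82.5); it is off by default because it matters only for
illustrating that confounding. The generator returns the hidden truth
(per-subject etas and parameters) alongside the observable dataset for
recovery testing.

What the generator does **not** emulate: correlation between covariates
(each marginal is drawn independently), time-varying renal function or
fluid status, assay error structure beyond the combined residual model,
informative dropout, and any relation between covariates and PK parameters
(absent by design in the null cohort, present only via
`covariate_effect_scenario()`). Passing tests on synthetic cohorts
therefore demonstrate that the estimator and diagnostics recover what the
model family can express — not that the model family captures every feature
of real ICU data.

## Numerical choices and problem sizes

* Inner Newton: finite-difference step 10^-4^, gradient tolerance 10^-5^,
  at most 50 iterations, step length capped at 2 on the log-eta scale.
* Outer optimization: restarted Nelder-Mead, relative tolerance 10^-8^,
  500 iterations per pass, up to 8 passes, restart-improvement threshold
  0.01; a fit is flagged unconverged if the last restart still improved by
  more than that.
* Residual SDs are floored at 10^-8^ on entry to the unconstrained scale
  (a zero SD is representable in simulation but not on the log scale).
* Degenerate inputs: a model with no (or empty) omega is fitted without
  random effects; zero predicted variance raises an error naming the
  subject; singular simulated covariances in the NPDE are
  ridge-regularized with a warning.
* The test suite scales stochastic studies to sizes that keep the full run
  in minutes while leaving the checked properties comfortably powered:
  forward-step calibration uses 200 replicate 12-subject cohorts with a
  one-eta model, selection power uses 20 replicate 100-subject cohorts,
  the bootstrap consistency check uses 30 resamples of a 14-subject
  cohort, and diagnostic null checks use 400–500 simulation replicates.

## Known limitations

* The estimator is a Laplace-family approximation; with five observations
  per subject its small-sample behavior is good, but objective values are
  not exchangeable with other software's constants.
* The published mean elimination half-life (6.96 h) is a mean over
  individual empirical-Bayes half-lives and does not equal the terminal
  half-life implied by the typical values (≈7.8 h by eigenvalue
  computation); the package reports half-lives from `micro_constants()`
  and makes no attempt to force agreement.
* Inter-occasion variability, time-varying covariates, BLQ likelihood
  methods beyond M1, and SAEM-type estimators are out of scope.
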