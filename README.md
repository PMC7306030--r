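# cipropk

Population pharmacokinetics and dosing-target attainment of **intravenous
ciprofloxacin in critically ill patients**, as a tested, reusable R
pipeline. The package is aimed at pharmacometricians and infection
pharmacologists who want to reproduce, stress-test, or extend a sparse-data
ICU popPK analysis: structural PK, mixed-effects estimation, covariate
screening, model qualification, and Monte Carlo probability of target
attainment (PTA), driven by a synthetic-cohort generator so that no patient
data are required.

## The model

Disposition is two-compartment with zero-order infusion input:
parameters `CL` (clearance, L/h), `Vc`, `Vp` (central/peripheral volumes,
L) and `Q` (inter-compartmental clearance, L/h). Between-subject
variability is log-normal,

    CL_j = CL_pop * exp(eta_CL),   eta ~ N(0, Omega),

with a covariance block on (CL, Vc), and residual error is combined
proportional-plus-additive: `y = f(1 + eps_p) + eps_a`. Covariate
relations are power functions normalized to the covariate median
(continuous) or multipliers (binary), screened by forward inclusion
(ΔOFV ≥ 3.84) and backward elimination (ΔOFV > 10.83). Estimation is a
Laplace-with-interaction (FOCE-I-family) approximate marginal likelihood.
Efficacy targets are free-drug ratios `fAUC24/MIC ≥ 100` and
`fCmax/MIC ≥ 8` with unbound fraction 0.7.

The default "truth" (`cipro_final_model()`) carries the published
final-model estimates for ICU patients: CL 25.4 L/h, Vc 91.1 L, Vp 164 L,
Q 91.9 L/h, IIV 67.8%/51.0% on CL/Vc, proportional error 15.3%, additive
0.143 mg/L. The default study design (`study_design()`) emulates the
observed cohort: 42 patients on 400 mg q24h/q12h/q8h (3/25/14), 1 h
infusions, five samples in one day-2 dosing interval.

## Worked example

```r
library(cipropk)

# 1. simulate an ICU cohort at the published truth
truth  <- cipro_final_model()
cohort <- generate_cohort(seed = 1)
cohort                      # 42 subjects, ~204 observations

# 2. fit the two-compartment mixed-effects model
fit <- fit_poppk(cohort, truth)
fit

# 3. dosing simulations: PTA across the MIC grid
pta <- simulate_pta(truth, dosing_regimen(400, 12, 1), n = 5000, seed = 1)
pta
plot_pta(pta)
```

The fit prints (seed 1):

```
popPK fit: OFV = 174.588 (converged), 42 subjects / 199 observations
Population PK model (two-compartment, IV infusion)
  theta: CL=29.6 L/h  Vc=83.5 L  Vp=198 L  Q=87.6 L/h
  IIV (CV%): CL=62.2  Vc=57.0
  residual error: proportional 16.9%, additive 0.137 mg/L
  eta shrinkage (%): CL=0.6  Vc=27.3;  eps shrinkage: 13.4%
```

Each typical value lands inside the published bootstrap 95% interval
(CL 20.6–30.6 L/h, Vc 61.8–110.7 L, Vp 120.1–216.2 L, Q 77.2–128.3 L/h) —
the simulation-estimation loop recovers the generating parameters from a
42-subject sparse design. The PTA table shows, per MIC, the fraction of
5000 virtual patients attaining `fAUC24/MIC ≥ 100` under 400 mg q12h with
95%/99% confidence bands; at the 0.5 mg/L clinical breakpoint it is
0.12 (95% band 0.112–0.130), which is why higher daily doses are advocated
for ICU patients.

Model qualification mirrors standard practice:

```r
boot <- bootstrap_poppk(cohort, fit$estimates, n_resamples = 200, seed = 2)
v    <- vpc(cohort, fit$estimates, n_sim = 1000, seed = 3); plot_vpc(v)
nd   <- npde(cohort, fit$estimates, n_sim = 1000, seed = 4)
```

## Package layout

- `R/pk-core.R` — closed-form two-compartment infusion kinetics, exposure metrics
- `R/population.R` — population model, IIV, residual error, covariate effects
- `R/dataset.R` — NONMEM-style CSV event records, JSON parameter files
- `R/synthetic.R` — ICU study-design emulation and cohort generation
- `R/estimation.R` — Laplace/FOCE-I-style OFV, fitting, shrinkage, stepwise covariate search
- `R/evaluation.R` — bootstrap, VPC, NPDE, goodness-of-fit residuals
- `R/pta.R` — Monte Carlo PTA, closed-form oracle, observed attainment
- `R/plots.R` — VPC / GOF / PTA figures (ggplot2)
- `vignettes/cipropk-methods.Rmd` — models, assumptions, numerical choices
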