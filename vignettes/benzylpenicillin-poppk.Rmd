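---
title: "Population pharmacokinetics of benzylpenicillin in critical illness: model, estimation and dosing simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of benzylpenicillin in critical illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penpk)
```

## The problem

Benzylpenicillin is a time-dependent beta-lactam: bacterial killing tracks
the fraction of the dosing interval during which the *unbound* plasma
concentration stays above the organism's minimum inhibitory concentration
(%fT>MIC). In critical illness, clearance and distribution volumes are
highly variable — acute kidney injury depresses clearance while augmented
renal clearance inflates it — so standard bolus dosing can leave a
substantial minority of patients underexposed at the clinical breakpoint
MIC of 2 mg/L. `penpk` implements the full analysis chain for a small
intensive-care pharmacokinetic study of intravenous benzylpenicillin:
a population (nonlinear mixed-effects) model, approximate maximum-likelihood
estimation, model diagnostics, and Monte-Carlo simulation of alternative
dosing strategies.

## The model

Disposition is linear and two-compartmental. For subject $i$ with weight
$W_i$ (kg) and serum creatinine $Cr_i$ (scaled to a reference of 70):

$$CL_i = \theta_{CL}\,(W_i/70)^{0.75}\,(Cr_i/70)^{\theta_{Cr}}\,e^{\eta_{CL,i}},\qquad
Q_i = \theta_Q\,(W_i/70)^{0.75},$$
$$V_{1,i} = \theta_{V1}\,(W_i/70)\,e^{\eta_{V1,i}},\qquad
V_{2,i} = \theta_{V2}\,(W_i/70)\,e^{\eta_{V2,i}},$$

with allometric exponents fixed (0.75 for clearances, 1 for volumes) and
independent log-normal subject effects $\eta \sim N(0, \omega^2)$ on CL,
V1 and V2 (none on Q, whose between-subject variability was found
negligible in the source analysis). Observed total concentrations follow
the combined residual model $y = f(1+\varepsilon_1) + \varepsilon_2$.

The micro constants are $k_{10} = CL/V_1$, $k_{12} = Q/V_1$,
$k_{21} = Q/V_2$, and the macro constants $\alpha \ge \beta$ solve
$x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21} = 0$; the terminal
half-life is $\ln 2/\beta$. The final published estimates are packaged:

```{r}
m <- bpen_final_model()
m
individual_params(m, weight = 70, creatinine = 70)
```

At the reference covariates this reproduces the reported terminal
half-life of 1.11 h (67 min).

### Reading the published variability

The source report lists its random-effect rows as "$\omega^2$ (%CV)" with
values 42.0 (CL), 22.6 (V1) and 20.5 (V2). `bpen_final_model()` follows
the conventional pharmacometric reading — the printed numbers are
coefficients of variation, so $\omega^2_{CL} = 0.42^2 = 0.1764$ — while
`bpen_final_model("variance")` takes them as the variances themselves
($\omega^2_{CL} = 0.420$). The table is genuinely ambiguous, and the two
readings bracket the published simulation results: the package's own
simulations (below) reproduce several of the reported attainment
percentages under the CV reading and others under the variance reading,
but no single reading reproduces all of them, so the default stays with
the field convention and the alternative remains available as a
sensitivity toggle.

## Analytic kinetics

`conc_profile()` evaluates the closed-form bolus response
$A e^{-\alpha t} + B e^{-\beta t}$ and its zero-order-infusion integral,
superposed over arbitrary dose events; `pk_state()` carries the analytic
compartment amounts and the eliminated mass $CL\int C\,dt$, so the mass
balance `administered = central + peripheral + eliminated` is testable to
round-off. Two numerical choices matter:

* **Repeated eigenvalues.** When the discriminant of the macro quadratic
  is below $10^{-12}$ (relatively), the degenerate $t e^{-\lambda t}$
  limiting form is used instead of the ill-conditioned two-exponential
  difference.
* **Grid-free %fT>MIC.** Within any interval free of dose-event
  boundaries the profile is a constant plus two exponentials, which has
  at most one interior stationary point. `fraction_time_above()` splits
  the evaluation window at event boundaries and the analytic stationary
  point, then bisects each monotone piece (tolerance $10^{-9}$ h), so
  attainment fractions do not depend on a sampling grid. "Above" is
  strict; ties have measure zero for continuous profiles.
* **Pre-dose convention.** A concentration sampled at the instant of a
  dose is a trough: prediction of observed data excludes a bolus given at
  exactly the sampling time, while simulated profiles are
  right-continuous (`C(0) = D/V1` after a bolus at zero).

## Estimation

`foce_objective()` implements the first-order conditional approximation
with interaction: per subject, the conditional mode $\hat\eta$ of the
joint density is located by a modified-Newton inner optimization
(gradient tolerance $10^{-8}$, deterministic perturbed restarts), the
residual variance is evaluated at the *individual* prediction, and the
marginal $-2\log L$ contribution is assembled with the Gauss–Newton
curvature $\Omega^{-1} + \sum_j f_\eta f_\eta^\top / g_j$
(`method = "foce"`) or the full numerical curvature of the conditional
objective (`method = "laplace"`). The $\log 2\pi$ constants are included,
so absolute OFVs differ from software that drops them, but nested-model
differences — the quantities used for selection — are unaffected.

In cross-checks against an adaptive Gauss–Hermite quadrature oracle
(64 nodes) on low-noise single-subject toys, the Laplace curvature agrees
to better than 0.01 in OFV; the Gauss–Newton flavor, which is the field's
standard and the default for fitting, carries the well-known additional
approximation error of order 0.05–0.2 on such toys. The package's test
suite therefore checks quadrature agreement with the Laplace curvature
and uses the FOCE-i default everywhere data are actually fitted.

`foce_fit()` optimizes log-transformed fixed effects and variance
components (covariate coefficients untransformed) with `nlminb`,
warm-starting every subject's conditional mode from the previous outer
iteration. Standard errors come from central finite differences of the
objective (observed information), delta-transformed to the natural scale;
a non-invertible information matrix is flagged, never fatal. Starting
values come from `initial_estimates()` — a naive pooled log-scale
least-squares fit with $\omega^2 = 0.1$ — since the source analysis
reports no initials. Variances hitting their (log-scale) bounds are
reported as boundary estimates.

Model development steps are reproduced as operations: `lrt_step()`
applies the $\chi^2$ acceptance rule (3.84 for one added parameter at
p < 0.05), and `stepwise_covariates()` runs forward selection over power
(continuous) or proportional-shift (categorical) candidate terms,
recording every tested OFV drop in a ledger. `pk_bootstrap()` resamples
subjects with replacement, refits from the final estimates, and reports
per-parameter medians with 2.5/97.5 percentiles; non-converged replicates
are excluded and counted (the source report does not state its policy).

Because the raw clinical data are unavailable, the published parameter
estimates, OFV drops (104.4 for the structural step, 19.1 for
creatinine) and bootstrap intervals cannot be reproduced; the test suite
replaces them with property-based checks: oracle agreement of the solver
and the objective, recovery of the generating parameters from synthetic
100-subject studies, type-I calibration of the covariate step under a
null world, and the threshold arithmetic of the reported decisions.

## Diagnostics

`gof_table()` produces one record per observation with the population
prediction ($\eta = 0$), the individual prediction ($\hat\eta$) and the
individually weighted residual. `pc_vpc()` implements the
prediction-corrected visual predictive check: observations and simulated
replicates are scaled by (bin-median population prediction)/(record's
population prediction), binned on time-after-dose folded to each
subject's own interval and capped at 4 h, and the observed 2.5/50/97.5
percentiles are overlaid on simulation bands. Bin edges are
quantile-based (default 4 bins) and the band level is 95% from 1000
replicates by default — the source figure shows its bins only as tick
marks and does not print its simulation count, so both are package
choices, stated here.

## The synthetic study generator

`generate_study()` emulates the design of the source study so that the
estimation and diagnostic code can be exercised without any clinical
data: 12 subjects (eight on 1.2 g 4-hourly, two on 1.2 g 6-hourly, two
on 2.4 g 4-hourly), opportunistic sampling at fixed offsets within two
consecutive dosing intervals (4-hourly: 0.1, 2, 3.5, 4 then 0.2, 1, 3,
4 h; 6-hourly: 0.1, 2, 3, 6 then 0.1, 1, 5, 6 h), and covariates drawn
from log-normal distributions matched to the reported medians and
interquartile ranges (weight 70 kg, IQR 65.7–90; creatinine 70, IQR
52–103.5; similarly albumin, age, height and severity score; sex is an
even coin flip; temperature is N(37.5, 0.8), a package choice since no
summary was reported). Only medians and IQRs are published, so the
log-normal match is itself a modelling decision — clinical covariates
are positive and right-skewed — and the generator does not reproduce the
real study's heavy creatinine tail (three of twelve patients had acute
kidney injury with creatinine up to 486) beyond what the log-normal
implies. Sampled intervals are placed after five maintenance doses so
observations sit at steady state, which the source design leaves
unstated. The full schedule yields 96 samples; an optional dropout rate
(0.2) emulates the opportunistic loss that left the real study with 77.
Concentrations are generated as $f(1+\varepsilon_1)+\varepsilon_2$,
truncated at zero.

What passing tests on these synthetic studies shows is therefore that
the *machinery* is correct and well calibrated under the stated model —
not that the model describes any particular patient population; no
censoring below a quantification limit, renal replacement therapy or
time-varying creatinine is simulated, because the source analysis
describes none of them.

## Dosing simulations

`simulate_pta()` draws subjects from the population model (random effects
only — residual error is measurement noise, not biology), realizes each
subject's parameters, and computes exact %fT>MIC per subject:

```{r}
pta <- simulate_pta(bpen_final_model(), "b", n = 2000, mic = c(0.5, 1, 2),
                    seed = 1)
pta
attainment_fraction(pta, mic = 2, ft_threshold = 50, "fail")
```

The five packaged strategies deliver (a) 1.2 g bolus 4-hourly, (b) 2.4 g
bolus 4-hourly, (c) 1.2 g bolus plus 6 g over 24 h, (d) 7.2 g over 24 h,
and (e) 1.2 g infused over 2 h, 4-hourly; (a), (c) and (d) share the
same 7.2 g daily dose. Design decisions, all configurable:

* **Evaluation window.** The source text does not say whether bolus
  regimens were summarized at steady state or from the first dose.
  Intermittent strategies here are dosed from $t = 0$ for 24 h and
  evaluated over the last complete interval — with a terminal half-life
  near 1.1 h, steady state is long since reached — while continuous
  strategies are evaluated over the whole 24 h as stated for them.
* **Covariate policy.** The headline simulations use typical covariates
  (70 kg, creatinine 70) with between-subject variability only;
  `policy = "resample"` instead draws weight and creatinine from the
  study's covariate distributions. The original analysis does not state which
  policy produced its figures, and the choice moves several attainment
  percentages by more than the Monte-Carlo error.
* **Protein binding.** The unbound fraction defaults to 0.4 (60%
  binding, the reference-label value) but is an argument, since the
  literature spans a range of binding estimates.
* **MIC grid.** A doubling series 0.0625–4 mg/L covering the clinical
  breakpoints; attainment queries refuse off-grid MICs rather than
  interpolate.

With $n = 10{,}000$ subjects the Monte-Carlo standard error of an
attainment percentage is at most 0.5 points, so simulation noise is
negligible against the ±5-point comparisons used in the acceptance
checks; differences beyond that reflect the simulation-policy ambiguities
above, which is why they are surfaced as explicit toggles rather than
hidden defaults.

## Problem sizes used by the shipped checks

The package's own verification uses: 50 random regimen/parameter
instances for the solver-versus-ODE oracle (relative error $<10^{-6}$);
20 low-noise single-subject toys for quadrature agreement ($<0.01$ in
OFV); 20 replicates of 100-subject synthetic studies for parameter
recovery (outer tolerance $10^{-5}$ for these simulation fits); 400
null-world simulations of the covariate step for type-I calibration
(one-compartment, 50 subjects, 4 samples each — chosen so the $\chi^2$
reference is accurate while each fit stays fast); and 10,000-subject
dosing simulations per strategy. These sizes are the package's
documented defaults for its validation studies.

## Known limitations

* The approximate likelihood is FOCE-i/Laplace, not exact; small-sample
  LRT calibration degrades for sparse designs (the null-calibration
  study above quantifies the regime where it is accurate).
* The bootstrap refits from the final estimates; with 12-subject
  resamples, occasional replicates sit at variance boundaries and are
  excluded with a count rather than imputed.
* Only diagonal random-effect covariance and power/shift covariate forms
  are supported — matching the scope of the source analysis.
* Saturable elimination, oral absorption and three-compartment closed
  forms are out of scope; the structural comparison beyond two
  compartments would use the generic eigen-solver rather than new closed
  forms.
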