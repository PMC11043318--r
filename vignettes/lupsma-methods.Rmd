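---
title: "Model and methods behind lupsma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind lupsma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupsma)
```

`lupsma` implements a population pharmacokinetic/pharmacodynamic (PKPD)
model of radioligand therapy with [^177^Lu]Lu-PSMA-I&T in metastatic
castration-resistant prostate cancer, and everything needed to use it as a
simulation and estimation laboratory: individualized parameterisation,
virtual-population trial simulation of the two clinical dosing schedules,
synthetic SPECT/PSA dataset generation, empirical-Bayes and naive-pooled
fitting, and the tumor exposure–response threshold analysis. This vignette
explains the model, the conventions the package commits to where more than
one reading is possible, and the numerical choices, so that results can be
interpreted — and distrusted — for the right reasons.

## The kinetic model

The radioligand distributes over five lumped compartments: central (blood,
volume $V_1$ = 10.3 L, fixed), salivary glands, kidneys, tumor (all
segmented lesions as one compartment) and a combined remaining-tissue
compartment. All transfers are first order except uptake into the salivary
glands, which saturates against a maximum binding capacity
$B_{max}$ = 134 MBq (a proxy for PSMA receptor expression):

$$\frac{dA_2}{dt} = k_{12}\,A_1\left(1 - \frac{A_2}{B_{max}}\right) - k_{21} A_2 .$$

The same saturation factor multiplies the central-side outflow, so the
transfer conserves mass; activity leaves the system only through renal
excretion ($k_{10}$ = 0.253 h⁻¹) and, in physical mode, radioactive decay.
Saturation of kidney and tumor uptake was not identifiable at clinical
specific activities and is not modelled. Derived quantities follow directly:
renal clearance $k_{10} V_1 \approx 2.61$ L/h, effective half-lives
$\ln 2 / k_{21} \approx 11$ h for organs at risk and
$\ln 2 / k_{41} \approx 46$ h for tumor.

### Decay bookkeeping: the corrected scale is canonical

Quantitative SPECT data in this setting are decay-corrected to the time of
injection, and every rate constant and drug-effect coefficient of the model
was estimated on that scale. The package therefore treats the
**decay-corrected** system (no explicit decay term; `decay_mode =
"corrected"`) as canonical: it is the observation scale of the synthetic
datasets, the prediction scale of the estimators, and — critically — the
concentration scale driving the PSA model. A physical-activity mode
(`decay_mode = "physical"`, uniform decay $\lambda = \ln 2/159.5\ \mathrm{h}$
on all compartments) is provided for genuinely dosimetric quantities.

This was a genuinely open design choice, and we resolved it empirically:
driving the PSA kill terms with the physical concentration depresses the
simulated 24-week response rates by roughly ten percentage points relative
to the reported simulation results, while the decay-corrected drive
reproduces them closely and places the typical subject's two-cycle tumor
exposure (≈ 735 MBq·h/mL) on the same scale as the clinical response
thresholds (709.5 and 1188 MBq·h/mL). Both facts indicate that the
estimated kill coefficients live on the corrected scale, so using them with
physical concentrations would misstate the drug effect.

## Individual parameterisation

Individual parameters are composed multiplicatively (the order is
immaterial and logged as: covariates → allometry → IIV → IOV → cycle
effect):

* **Tumor volume** (power functions): $k_{14}$ scales with
  $(TV/0.0443)^{1.08}$ — doubling the volume raises tumor uptake 2.11-fold —
  and $k_{12}$ with $(TV/0.0443)^{0.0910}$ (a mild tumor-sink effect on the
  salivary glands).
* **Allometric body weight**: all rate constants scale with
  $(WT/79)^{-0.25}$ and $V_1$ with $(WT/79)^{1}$, the standard fixed
  exponents. $B_{max}$ is an amount, not a rate or volume; the stated
  exponents do not cover it and it is left unscaled.
* **Cycle effect**: tumor uptake falls structurally to 73.1%, 49.8% and
  43.6% of the first-cycle rate in cycle 2, 3 and 4–7. Cycles beyond 7
  reuse the last fraction with a warning. A descriptively reported salivary
  cycle effect (84.6% in cycle 2, 98.1% in cycle 3) is not part of the
  final model and is available only behind an explicit flag.
* **Random effects**: log-normal inter-individual variability on $k_{10},
  k_{13}, k_{14}, k_{15}, B_{max}$ and the PD parameters, plus
  inter-occasion (cycle-to-cycle) variability on $k_{14}$ (37.8% CV), one
  occasion per treatment cycle. No correlations (none reported).
* **Renal function** (GFR) is carried as a covariate but never used: it was
  tested and rejected on $k_{10}$.

### CV% to omega

Variability is reported as CV%. The package default converts it with the
exact lognormal relation $\omega = \sqrt{\log(1 + CV^2)}$, under which
$e^\eta$ carries exactly the stated CV; the common reporting approximation
$\omega = CV/100$ is available (`cv_mode = "direct"`). For the small PK CVs
the two are indistinguishable, but the PD CVs are large (179%, 140%, 91%,
87.5%) and the choice materially changes the tails. We made the exact
relation the default because, at population scale, it reproduces the
reported simulated response rates to within about one percentage point,
whereas the direct approximation systematically overshoots both endpoints —
evidence that the reported CV% figures live on the exact lognormal scale.

## PSA dynamics

PSA grows exponentially ($k_G$ = 0.000408 h⁻¹, an untreated doubling time of
≈ 71 days) and is eliminated by two drug effects:

$$\frac{dPSA}{dt} = \left(k_G - E_{drug} - k_{D,delay}\,C_e\right) PSA,
\qquad \frac{dC_e}{dt} = k_{e0}\,(C_{tumor} - C_e),$$

a **direct** effect proportional to the current tumor concentration
($k_{D,direct}$ = 0.00335 L·day⁻¹·GBq⁻¹; a results-text variant 0.000335 is
inconsistent with the reported confidence interval and is not used) and a
**delayed** effect driven by an effect compartment that equilibrates slowly
($k_{e0}$ = 0.00128 h⁻¹, half-time ≈ 23 days), which sustains the PSA
decline after treatment ends. Maximum-effect and sigmoid forms of the direct
effect are implemented as alternatives but were not supported by the data;
the final model is linear in both effects. The kill coefficients keep their
reported — deliberately asymmetric — units in all configuration surfaces
(L·day⁻¹·GBq⁻¹ vs L·day⁻¹·MBq⁻¹) and are converted internally to per-hour
rates against MBq/L, avoiding silent reinterpretation.

The random effect on $k_G$ is Box-Cox transformed
($\eta^\ast = ((e^\eta)^\theta - 1)/\theta$, shape $\theta$ = −0.822) before
exponentiation, skewing growth rates low; the transform reduces to the
identity as $\theta \to 0$. The baseline PSA covariate is implemented
literally as $PSA_0 = 140 + 57.5\,(TV/0.0443)$ µg/L (197.5 at the median
volume); a centered variant ($140$ at the median) is selectable because the
reported phrasing admits both readings. The choice largely cancels in the
percent-change endpoints.

## Virtual populations and the regimen comparison

The two clinical schedules are `4x6` (7.4 GBq at weeks 0, 6, 12, 18) and
`2x2_repeated` (7.4 GBq at weeks 0, 2, 12, 14), both evaluated 24 weeks
after the first dose — six and ten weeks after the respective last cycles.
All simulated subjects complete their full regimen; no response-adaptive
dropping is modelled.

Only medians and ranges of the covariates are available (weight 79 kg,
61–116; segmented tumor volume 0.0443 L, 0.000122–0.546), and the
tumor-volume range is severely asymmetric on the log scale. A single
lognormal matched to those ranges and truncated shifts the median by about
12%, so each covariate is drawn from a **split lognormal**: side-specific
log-scale spreads calibrated so each range endpoint sits at the 0.5% tail of
its side, truncated to the range, preserving the median exactly. Weight and
tumor volume are drawn independently (no correlation reported). This is an
approximation to an unreported joint distribution and is the dominant
non-Monte-Carlo uncertainty in the simulated rates.

Endpoints are classified on the noise-free individual prediction — response
is a ≥ 50% PSA decrease versus the individual baseline (inclusive), stable
disease is no increase (inclusive); response implies stable disease.
Residual error exists only in the dataset generators. At $n = 2000$ per arm
the binomial Monte-Carlo standard error of a rate near 45% is ≈ 1.1
percentage points; with the covariate approximation on top, agreement with
the reported rates is expected within a few percentage points, not exactly.

## Synthetic data

The generators emulate the study's measurement structure: per cycle, three
SPECT scans at offsets drawn from 4.6 ± 0.95 h, 23.8 ± 4.5 h and
163.2 ± 11.0 h post injection, observing blood concentration (MBq/L) and
salivary/kidney/tumor amounts (MBq) on the decay-corrected scale; PSA drawn
at baseline (inside a < 6-week pre-dose window) and every four weeks
thereafter. Residual error follows the estimated models — combined
proportional (55.5%) + additive (9.57 MBq/L) for blood, proportional for
the organs (39.7%, 31.9%, 32.7%) and PSA (29.3%). Blood values pass through
the SPECT-blood correction chain (slope 0.828, intercept 6.27 MBq/L) and
negative corrected values can be filtered out, mirroring the study's
exclusions. The generator does **not** emulate image-reconstruction
artifacts, per-lesion heterogeneity, or scan-protocol changes; passing
recovery tests on these data demonstrates the internal consistency of the
implementation, not fidelity to any real cohort.

## Estimation

Full nonlinear mixed-effects estimation (FOCE-I) is intentionally out of
scope. Two simpler surfaces validate the implemented equations:

* **MAP / empirical Bayes** per subject: minimises
  $-2\log L + \sum \eta^2/\omega^2$ over the requested effects (BFGS, three
  starts at 0 and ±0.3, objective tolerance 10⁻¹⁰, excursions beyond
  |η| = 8 rejected). The residual variance in the likelihood is evaluated at
  the observed value rather than the prediction, which makes the objective
  exactly self-consistent: noise-free data attain their global minimum at
  the generating effects. With a prediction-based variance the log-variance
  term trades against misfit and shifts the optimum — a real property of
  exact normal likelihoods with proportional error, and with the clinical
  sigma values the prior legitimately shrinks estimates (both behaviours
  are tested). Note that an inter-individual and an inter-occasion effect
  on the same parameter are jointly identified only through the prior.
* **Naive-pooled** weighted least squares across subjects on log-scale
  parameters (`nlminb`, objective tolerance 10⁻⁸), with weights from the
  residual model. On noise-free synthetic data this recovers freed
  structural parameters (growth rate, cycle fractions, rate constants)
  essentially exactly — the package's central inverse-crime check that the
  generator and the estimator implement the same equations.

## Exposure–response

Tumor exposure is the trapezoid time integral of the tumor concentration
over the first two cycles (default window: first dose to week 12, covering
wash-out before any third exposure), reported in MBq·h/mL on the
decay-corrected scale for comparability with the clinical thresholds.
Percent PSA change (nadir or last value in the window) is regressed on
exposure by ordinary least squares, and the fitted line is inverted at −50%
to a threshold exposure. Formal inference is deliberately omitted:
individually estimated exposures are not independent observations. The
clinical thresholds themselves (709.5 and 1188 MBq·h/mL) derive from
patient data and are shipped only as reference constants
(`reference_auc_thresholds`); synthetic cohorts yield thresholds of the
same order but not those values.

## Numerical choices

* Integration: `deSolve::lsoda`, relative tolerance 10⁻⁸, absolute 10⁻¹⁰
  MBq, restarted at every bolus (state continuous except the central jump).
  The right-hand side is compiled C for population-scale work; an R
  implementation of the same equations is kept as a reference path and the
  two agree to solver tolerance. An independent fixed-step RK4 oracle (step
  0.01 h) written directly from the equations bounds the solver error at
  10⁻⁶ relative in the test suite.
* Output grids are decoupled from solver accuracy; dose events and the
  evaluation time are always included in the grid.
* AUC uses trapezoids with window endpoints closed by interpolation; it is
  additive across windows by construction.
* Problem sizes in the test suite and acceptance script: the regimen
  comparison uses $n = 2000$ subjects per arm (the reported simulation
  size); recovery checks use 5–20 noise-free subjects; oracle comparisons
  use single-subject horizons of 1–24 weeks.

## Limitations

The package simulates and fits the *model*; it cannot manufacture clinical
truth. Known gaps: the covariate joint distribution is approximated from
medians and ranges; decay bookkeeping across overlapping cycles follows the
corrected-scale convention described above rather than per-lesion physical
dosimetry; absorbed dose (Gy) is out of scope; cycle effects beyond the
seventh cycle are extrapolated; and the exposure–response analysis inherits
the linearity assumption with all its documented uncertainty.
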