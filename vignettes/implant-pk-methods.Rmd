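---
title: "Methods: from sparse bolus PK to implant release kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sparse bolus PK to implant release kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantpk)
```

This vignette documents the models behind `implantpk`, the assumptions they
rest on, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The two study designs

The package analyses a linked pair of rat studies of a subcutaneous (SC)
drug-eluting implant:

* a **bolus dose-ranging study**: SC solution doses of 0.1, 0.3 and
  1 mg/kg in adult rats (mean body weight 0.307 ± 0.02 kg), sampled
  destructively at 0.17, 0.5, 1, 2, 4, 6 and 24 h with three animals per
  timepoint per dose — each animal contributes exactly one plasma sample
  (drug, ng/mL) and one PBMC sample (active intracellular metabolite,
  pmol/million cells);
* an **implant study**: ten animals carrying a reservoir-style implant
  loaded with 98.6 ± 3.31 mg of drug, with serial plasma sampling in
  ~two-week increments; the analysis horizon is 154 days, beyond which
  inter-individual variability in the source cohort made profiles
  unreliable.

The bolus study characterises *disposition* (what the body does to
absorbed drug); the implant study is then *deconvolved* against that
disposition to recover what the implant did.

## Sparse NCA

With one observation per animal, individual NCA is impossible, so
endpoints are computed on the per-timepoint arithmetic mean of quantifiable
values (naive pooling), the standard sparse-NCA convention. Key choices:

* **BLQ censoring.** Observations below the lower limit of quantification
  (LLOQ, 0.1 ng/mL plasma by default) are excluded from NCA with a
  reported count — the discard-with-count reading of the "M2" censoring
  policy. The likelihood-adjustment reading of M2 belongs to mixed-effects
  estimation, not trapezoidal NCA, so discarding is the default and a
  `zero_before_tmax` alternative is exposed for sensitivity analysis. BLQ
  rows are flagged, never deleted, and keep their LLOQ so the policy can be
  changed post hoc.
* **AUC.** Linear-up/log-down trapezoids from the first to the last
  quantifiable timepoint; no back-extrapolation to zero, no extrapolation
  to infinity. Rising or flat segments use the arithmetic trapezoid,
  falling segments the logarithmic one.
* **Terminal slope.** Unweighted log-linear regression of the pooled means
  within a 4–24 h window, requiring at least three quantifiable points
  (`t1/2 = ln 2 / λz`); profiles failing this (e.g. a low dose whose 24 h
  sample is BLQ) report `t1/2` as not estimable rather than a value.
* **C~avg~.** AUC~last~ divided by the nominal 24 h profile duration. The
  24 h denominator (rather than the observed span) keeps dose levels
  comparable when a truncated low-dose profile spans fewer hours, and
  matches how the endpoints this package is benchmarked against were
  computed.
* **Dose proportionality.** Unweighted OLS of ln(endpoint) on ln(absolute
  dose). The slope is invariant to rescaling all doses by a constant, so
  weight normalisation does not affect it. Linearity is declared for
  slopes in [0.8, 1.25] with r² > 0.8; the band is explicit configuration
  because "approximately 1" is not a number.
* **Intracellular:plasma ratio.** Metabolite amounts per million PBMCs are
  converted to molarity assuming 0.2 pL per cell; plasma drug is converted
  with a molar mass. Both the parent (293.3 g/mol) and the triphosphate
  metabolite (533.2 g/mol) presets are provided, because the two
  conventions differ by ~1.8× and published ratios are reproduced only
  under the triphosphate mass — which is therefore the default, with the
  choice surfaced as an argument rather than buried.
* **Outliers.** A two-sided Grubbs test (closed-form statistic, t-quantile
  critical value, at most one outlier per call) supports explicit
  exclusion; exclusions are flagged with a reason, never silently dropped.

## Naive-pooled compartmental model and the UIR

All animals' quantifiable plasma observations are pooled as if from one
subject — appropriate when destructive sampling precludes any
inter-individual model — and a first-order-absorption model in the
macro-constant parameterisation is fitted:

$$C(t) = \frac{D}{D_{ref}}\left[A e^{-\alpha t} + B e^{-\beta t} - (A+B) e^{-K_a t}\right]$$

with `C(0) = 0` by construction, `α > β` enforced by sorting after the
fit, and `D_ref` the mean absolute dose. This form is continuous in `Ka`
(no `1/(Ka − α)` factor), so near-coincident rates need no special-case
reparameterisation.

* **Likelihoods.** Exact pooled normal likelihoods for three residual
  models — additive (constant SD), multiplicative (SD proportional to the
  prediction) and log-additive (normal on the log scale, with the Jacobian
  term included so log-likelihoods are comparable across error models).
  The residual scale is profiled out analytically, so the optimiser works
  in 3 (one-compartment) or 5 (two-compartment) dimensions on the log
  scale.
* **Optimisation.** Multi-start (default 5) Nelder–Mead followed by BFGS
  refinement, starting from method-of-residuals (curve-stripping) initials
  plus jittered replicates; the best objective wins. Non-convergence from
  all starts is reported, not hidden.
* **BLQ during fitting** defaults to exclusion, mirroring the NCA policy;
  a censored-likelihood option (adding `P(obs < LLOQ)` for BLQ rows) is
  available but off by default, since its benefit is unclear in a pooled
  context.
* **Selection.** Candidates are ranked by AIC with BIC tie-break;
  non-convergent candidates and candidates whose worst %CV (delta-method,
  from the inverse observed information on the log-parameter scale) is
  ≥ 30% are demoted below all passing candidates.
* **UIR.** The selected two-compartment macro constants divided by the
  average dose give the unit impulse response
  `u(t) = A₁e^(−α₁t) + A₂e^(−α₂t)` in (ng/mL)/ng. The absorption
  exponential is dropped: with `Ka` near 12 h⁻¹ absorption is effectively
  instantaneous on the implant's timescale (the absorption term changes
  predictions by under 1% beyond roughly half an hour, and the implant is
  sampled in weeks). Eta-shrinkage diagnostics do not apply to a pooled
  fit (there are no etas) and are deliberately absent.

## Deconvolution

Plasma concentration under an arbitrary input rate `r(τ)` (ng/h) is the
convolution `C(t) = ∫₀ᵗ r(τ) u(t−τ) dτ`. The package represents `r` as
piecewise-constant on the observation grid — one segment per inter-sample
interval, ~11 segments over 154 days — and builds the convolution matrix
from the exact integral of each exponential over each interval:

$$\int_a^b A_i e^{-\alpha_i (t-\tau)}\,d\tau = \frac{A_i}{\alpha_i}\left(e^{-\alpha_i(t-\min(b,t))} - e^{-\alpha_i(t-a)}\right)$$

No numerical quadrature is involved, so on noise-free staircase inputs the
inversion is exact to solver precision. The linear system (square at the
study's sampling density) is solved by non-negative least squares by
default, which guarantees a monotone non-decreasing cumulative mass;
unconstrained least squares (lower or equal RSS, possibly negative rates)
and an optional ridge penalty for deliberately fine grids are available.
Unit handling is internal: the solver works in ng/h and hours, results are
reported in mg/day and days. The burst mass at `t = 0` is taken as
negligible for a reservoir system, so cumulative mass starts at zero, and
the day-0 sample is a predose BLQ anchor. Cohort exclusions are an
explicit ID list in configuration — never automatic — so the analysis
cohort is reproducible. Group contrasts of per-animal mean rates at day 90
and the horizon use Welch's unequal-variance t-test.

A deliberate scope note: which smoothing or constraint a commercial
deconvolution toolkit applies is generally undisclosed, so fine structure
of recovered rate profiles may differ between tools even on identical
data; the staircase-plus-NNLS choice here is transparent and well-posed at
this sampling density.

## Release-kinetics models

Deconvolved cumulative-mass profiles `M_t` (mg over days) are fitted to
four laws with the burst mass fixed at zero:

| model | form | fitted constant |
|---|---|---|
| zero-order | `M_t = K_Z t` | `K_Z` (mg/day), closed form |
| first-order | `M_t = M_inf (1 − e^(−K_F t))` | `K_F` (1/day), `M_inf` fixed at the loaded dose |
| Higuchi | `M_t = K_H √t` | `K_H` (mg/day^0.5), closed form |
| Ritger–Peppas | `M_t/M_inf = K_R tⁿ` | `K_R`, `n` jointly; log–log initials, nonlinear refinement |

All models are judged on the untransformed mass scale by
`r² = 1 − SS_res/SS_tot` with a mean-centred `SS_tot`, which makes the
four models comparable and allows negative r² when a forced-through-origin
curve fits worse than a constant. `M_inf` is the loaded dose (a known
quantity for a reservoir implant), not a fitted parameter. Ranking uses
the mean r² over converged fits only, with non-convergent fits counted as
not-reportable, and a 0.75 acceptance threshold. The Ritger–Peppas
exponent classifies transport for a cylindrical device: `n ≤ 0.45` Fickian
diffusion, `0.45 < n ≤ 0.89` anomalous, `n ≥ 1.5` Super Case-II, and the
band `0.89 < n < 1.5` zero-order — the upper edge of the zero-order band
is a package decision (halfway toward the textbook Super Case-II value of
2) since finite noisy data scatter estimated exponents around 1.

Two open points are worth stating. First, "first-order release" is
sometimes printed ambiguously in the literature; the saturating form above
is the standard one and is what this package fits. Strongly negative
first-order r² values reported elsewhere cannot be reproduced exactly
without the underlying data, so first-order behaviour is verified by
properties (exact-data identity, negative r² on near-flat data) rather
than by value. Second, whether published r² values used centred or
uncentred `SS_tot` is rarely stated; centred is implemented, as is
standard.

## The synthetic-study generator

The generator exists so that every stage is testable against known truth.
It emulates:

* the exact bolus design arithmetic (3 × 7 × 3 destructive samples),
  per-animal weights drawn Normal(0.307, 0.02) kg clipped at ±3 SD;
* true disposition from a configurable UIR (default: the rat SC
  disposition `A₁ = 9.8×10⁻⁴`, `A₂ = 9.6×10⁻⁶` (ng/mL)/ng, `α₁ = 1.2`,
  `α₂ = 0.103` 1/h) with first-order absorption `Ka = 12` 1/h;
* the implant design (10 animals, 14-day sampling to day 154 — eleven
  post-dose samples, matching the source design's ~15-day increments —
  loaded dose Normal(98.6, 3.31) mg) with true concentrations computed by
  the exact closed-form convolution of the chosen release law with the
  UIR: elementary exponentials for zero- and first-order inputs, and an
  exponentially-scaled incomplete-gamma kernel (series for small
  arguments, asymptotic expansion beyond) for Higuchi/power-law inputs —
  accurate to ~10⁻¹³ against quadrature, with no numerical integration in
  the generator itself;
* multiplicative residual error at 76% CV (the residual magnitude of the
  final bolus fit) and BLQ flagging below the LLOQ;
* an indirect-response (formation-limited) intracellular metabolite
  compartment, `dM/dt = k_in·scale·C_p − k_out·M`, solved in closed form.
  Defaults (`k_in = k_out = 0.2` 1/h, gain 0.018) place metabolite Tmax at
  2–4 h and peak values of order 0.05–0.6 pmol/million cells across the
  dose range. This compartment is a stand-in: its parameters are chosen
  for realistic shape and magnitude, not calibrated to any reported
  cellular PK, so metabolite-side results validate the *pipeline*, not
  the biology.

**Noise model.** "Multiplicative error" is implemented as lognormal
factors `exp(ε − s²/2)`, `ε ~ N(0, s²)`, `s² = log(1 + CV²)`: the factors
have mean exactly 1 and coefficient of variation exactly the nominal CV,
and concentrations stay positive at any error magnitude. The naive
alternative `C(1+ε)` must be truncated to keep concentrations positive,
and at a 76% CV that truncation removes ~9% of the distribution's mass,
inflating the mean and compressing the realized CV to ~0.57 — it would
generate data that contradict the very error magnitude being emulated. The
truncated variant remains available (`error_model =
"proportional_truncated"`) for sensitivity analysis.

**What passing tests do and do not show.** The generator draws no
inter-individual disposition variability (the analysis model is naive
pooled), no time-varying release failure modes (e.g. loss of mechanical
integrity late in a study), no assay batch effects, and identical release
truth across animals. Recovery of truth from synthetic data therefore
demonstrates correctness of the estimators under the stated model, not
robustness to the full messiness of in vivo data.

## Numerical choices and problem sizes

* Optimiser tolerances: Nelder–Mead `reltol 1e-12` (≤ 4000 iterations)
  then BFGS `reltol 1e-14`; release-model nonlinear refinement via
  Levenberg–Marquardt (≤ 500 iterations). Exponential-pair ordering is
  restored by sorting, since sums of exponentials are exchangeable.
* Degenerate inputs have defined behaviour: all-BLQ profiles and
  under-determined deconvolution grids are errors with advice; zero
  variance disables the Grubbs test; fewer than three terminal points make
  `t1/2` not-estimable rather than wrong; non-convergent release fits are
  N.R., excluded from means and counted.
* Tie-breaks: model selection orders by (converged, %CV pass, AIC, BIC);
  identical fits keep a stable order.
* Simulation sizes used by the test-suite and acceptance checks were
  chosen to make stochastic assertions stable: 10,000 draws for noise-CV
  calibration, ~500 animals (24 per timepoint) at 20% CV for rate-constant
  recovery within 10%, 50 replicate studies at 20% CV for the
  recovery-error median, and the study's own 10-animal design at 20% CV
  for deconvolution recovery. Rate-constant recovery at the full 76% CV
  with only 57 observations is information-limited (median β error ~26%),
  which is why recovery calibration uses the 20% CV condition while the
  residual-error magnitude is verified under the 76% condition.

## Known limitations

* The UIR derives from an extravascular (SC) bolus, so absolute
  bioavailability is folded into the UIR coefficients; deconvolved
  "absorbed mass" is mass reaching plasma, and recovery comparisons
  against loaded dose inherit that assumption.
* Naive pooling provides population-typical parameters only; no
  inter-individual variability or shrinkage diagnostics are available by
  construction.
* Piecewise-constant deconvolution cannot resolve input structure finer
  than the sampling interval; the optional ridge path trades bias for
  resolution if a finer grid is forced.
* No allometric or interspecies dose translation is attempted: for this
  compound class, intracellular:plasma ratios differ markedly between
  species, limiting the utility of direct scaling.
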