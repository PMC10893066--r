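# implantpk

Pharmacokinetic deconvolution and release kinetics for long-acting
subcutaneous implants.

## What this package is for

Long-acting drug-eluting implants (for example a biodegradable
poly(ε-caprolactone) reservoir implant eluting the antiretroviral
islatravir for HIV pre-exposure prophylaxis) are developed preclinically by
asking two linked questions: *how fast does the implant actually release
drug in vivo*, and *is that release profile constant enough, high enough
and safe enough*? Plasma concentrations alone do not answer this — the
implant's input has to be separated from the animal's disposition.
`implantpk` implements the standard modelling chain that does so, for
pharmacometricians and formulation scientists working with rodent implant
studies:

1. **Sparse NCA** of a subcutaneous bolus dose-ranging study with
   destructive sampling (one sample per animal): naive-pooled mean
   profiles, linear-up/log-down AUC, BLQ censoring with exclusion counts,
   Grubbs outlier screening, and dose-proportionality assessment by the
   power model (unweighted OLS of ln-endpoint on ln-dose; linearity
   declared for slopes near 1 with r² > 0.8).
2. **Naive-pooled compartmental fitting** in the macro-constant
   parameterisation
   `C(t) = (D/D_ref) [A e^(−αt) + B e^(−βt) − (A+B) e^(−Ka t)]`
   under additive, multiplicative or log-additive residual models, with
   AIC/BIC/%CV-based model selection. The selected macro constants divided
   by the average dose give the **unit impulse response (UIR)**
   `u(t) = A₁e^(−α₁t) + A₂e^(−α₂t)` — the plasma concentration per unit of
   instantaneously absorbed dose.
3. **Deconvolution** of serial implant plasma profiles against the UIR:
   the absorption rate is represented as a staircase on the sampling grid,
   the convolution matrix is built from the exact exponential integrals
   (no quadrature), and non-negative least squares yields per-animal
   absorption rate (mg/day), cumulative mass (mg) and fraction of the
   loaded dose, with Welch comparisons between implant arms.
4. **Release kinetics**: zero-order (`M_t = K_Z t`), first-order
   (`M_t = M_inf(1 − e^(−K_F t))`), Higuchi (`M_t = K_H √t`) and
   Ritger–Peppas (`M_t/M_inf = K_R tⁿ`) models fitted to each cumulative
   profile on the mass scale, ranked by mean r² (threshold 0.75, with
   non-convergent fits reported as N.R.), and the release exponent `n`
   classified into Fickian / anomalous / zero-order / Super Case-II
   transport for a cylindrical device.

A **synthetic-study generator** reproduces both designs (3 dose levels ×
7 timepoints × 3 rats bolus; 10 implant animals sampled every 14 days to
day 154) with multiplicative residual error and BLQ censoring, so the whole
chain is testable and simulatable without animal data.

## Worked example

```r
library(implantpk)

# simulate the bolus dose-ranging study and fit the disposition model
bolus <- generate_bolus_study(bolus_sim_config(sigma = 0.2, seed = 42))
fit   <- fit_macro_model(bolus, macro_model_spec(2, "multiplicative"))
u     <- derive_uir(fit)
u
#> <unit impulse response>
#>   A1 = 0.00105272 (ng/mL)/ng   alpha1 = 1.22429 1/h
#>   A2 = 1.09294e-05 (ng/mL)/ng   alpha2 = 0.118025 1/h
#>   integral = 0.000952466 h*(ng/mL)/ng

# deconvolve a simulated implant cohort against that UIR
implant  <- generate_implant_study(implant_sim_config(sigma = 0.2, seed = 43))
profiles <- deconvolve_study(implant, u)
summarize_absorption(profiles)$summary
#>     group  n mean_rate sd_rate mean_cumulative_mass percent_of_load
#> 1 overall 10    0.0693  0.0033                 10.7            10.8

# rank the release laws and classify the mechanism
rk <- rank_models(fit_release_models(profiles))
rk$table[, c("model", "mean_r2", "mean_exponent")]
#>           model mean_r2 mean_exponent
#> 1 ritger_peppas   0.998          1.04
#> 2    zero_order   0.995            NA
#> 3   first_order   0.994            NA
#> 4       higuchi   0.804            NA
classify_exponent(1.04)
#> [1] "zero_order"
```

Reading: the fitted UIR says one absorbed nanogram transiently contributes
about 1.05 × 10⁻³ ng/mL that decays with half-lives of ~0.6 h and ~6 h.
Deconvolution recovers a near-constant absorption of ~0.07 mg/day
(the simulation truth is 0.072), amounting to ~11% of the 98.6 mg payload
over 154 days. The Ritger–Peppas exponent near 1 classifies the release as
zero-order (constant-rate), the desired behaviour for a reservoir implant.

`run_full_pipeline(pipeline_config())` chains all stages (including PBMC
metabolite NCA, safety flagging of intervals above 0.25 mg/day, and Welch
group comparisons) and writes a traceable report plus every intermediate
table; see the methods vignette for the modelling details.

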