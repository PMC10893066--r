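Reference values reported by the originating preclinical rat studies of the
islatravir-eluting subcutaneous implant, stored as plain-text inputs for the
worked-example checks:

- reference_nca_endpoints.csv: noncompartmental endpoints (Cmax, AUC_last,
  C_avg) per dose level (mg/kg) for plasma islatravir (ng/mL units,
  AUC h*ng/mL) and intracellular islatravir triphosphate
  (pmol/million cells).
- reference_release_r2.csv: per-animal r-squared values of the four
  release-kinetics models fitted to deconvolved cumulative-mass profiles
  (NA = not reportable due to model non-convergence).
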