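Package: implantpk
Title: Pharmacokinetic Deconvolution and Release Kinetics for Long-Acting
    Subcutaneous Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical pharmacokinetic characterisation
    of drug-eluting subcutaneous implants, developed around an
    islatravir-eluting biodegradable reservoir implant studied in rats.
    Provides sparse noncompartmental analysis with below-quantification-limit
    censoring and dose-proportionality assessment, naive-pooled macro-constant
    compartmental model fitting with error-model selection and derivation of a
    unit impulse response, exact-kernel numerical deconvolution of in vivo
    implant absorption (rate, cumulative mass, fraction of loaded dose), and
    fitting and ranking of zero-order, first-order, Higuchi and Ritger-Peppas
    drug-release models including mechanism classification from the release
    exponent. A synthetic-study generator reproduces both study designs so the
    full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
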