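Package: msinfluence
Title: Influence Diagnostics for Clock-Reset Multistate Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the generalized Cox partial likelihood for clock-reset
    multistate survival models (transition-specific covariate effects,
    Breslow tie handling, Nelson-Aalen baselines) and provides global and
    local influence diagnostics: exact and one-step case-deletion estimates,
    likelihood displacement, the one-step generalized Cook distance, and
    case-weight local influence via conformal normal curvature under three
    perturbation schemes (per transition-patient component, per transition,
    per patient). Includes a synthetic multistate cohort generator with
    contamination operators for validating the diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), survival, optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
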