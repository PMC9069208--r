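Package: sprct
Title: Stopping-Power-Ratio Prediction from Dual-Layer Spectral and Single-Energy CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based prediction and validation of ion stopping-power
    ratio (SPR) maps for particle-therapy treatment planning. Implements the
    dual-layer spectral CT (DLCT) route (Bethe equation on relative
    electron-density and effective-atomic-number volumes, with a piecewise
    log-linear mean-excitation-energy mapping and DEEDZ mass-density
    estimation) and the single-energy CT (SECT) route (two-parameter
    stoichiometric CT-number model and a piecewise-linear Hounsfield look-up
    table). Ships a synthetic cylindrical-phantom generator with tissue
    surrogate and implant inserts, ROI-based accuracy statistics,
    water-equivalent path-length and distal-range-shift evaluation, and a
    local-normalization 3D gamma-index engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
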