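Package: lfpbold
Title: Simulating Local Field Potential and BOLD Responses from a Common
    Neuronal Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the dendritic current time series of a neuronal
    population driven by three parameterised inputs (asynchronous broadband
    noise, coherence-varying narrowband gamma, and inhibitory alpha
    oscillations) and derives from the same population both a local field
    potential (the power of the summed currents) and a BOLD proxy (the sum
    of the per-neuron power).  Provides the closed-form expressions for both
    measures under an equicorrelated Gaussian population, a Welch-based
    spectral decomposition of the field potential into broadband, narrowband
    gamma, and alpha components, calibration curves that map input strengths
    to spectral components and their numerical inversion, and cross-validated
    regression tools relating BOLD amplitudes to field-potential components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
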