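Package: vibraman
Title: Simulated Raman Spectra and SERS Band Matching for Drug-Receptor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts quantum-chemistry vibrational results for drug-receptor
    binding sites (clopidogrel thiol metabolite with arginine, aspirin with
    arginine) into simulated Raman spectra, preprocesses experimental
    surface-enhanced Raman (SERS) spectra onto a fixed wavenumber grid, and
    matches theoretical normal modes to experimental bands to nominate
    candidate biomarker bands of antiplatelet-drug binding. Implements linear
    harmonic wavenumber scaling, Raman activity-to-intensity conversion with a
    Boltzmann thermal factor, Lorentzian line broadening, fixed-grid binning
    with replicate averaging and normalization to 100, mass-weighted fragment
    attribution of normal modes, and tolerance-based greedy peak matching,
    together with a synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
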