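Package: duvdecon
Title: Deconvolution of Deep-UV Resonance Raman Spectra of Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing deep-ultraviolet (DUV, ~248.6 nm) resonance
    Raman spectra of microbial cells and molecular standards. Implements the
    standard preprocessing chain for replicate point spectra (cosmic-ray
    rejection, laser-intensity correction, wavenumber recalibration against
    the atmospheric N2 line, atmospheric peak subtraction, fingerprint-range
    cropping, linear baseline subtraction, averaging, guanine-peak
    normalization); non-negative linear unmixing of a target spectrum into
    nucleobase and aromatic amino acid standard components with chi-squared
    model comparison across standard sets of increasing structural
    complexity; quantification of the unexplained spectral residual; a
    macromolecular composition budget for aromatic (DUV-resonant) residues
    in an average Escherichia coli cell with an artificial cell-mimic
    mixture recipe; and a seeded generator of realistic synthetic replicate
    spectra for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
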