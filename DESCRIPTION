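Package: sersev
Title: Raman and SERS Characterization of Plasma Extracellular Vesicle Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free liquid-biopsy spectroscopy of plasma
    extracellular-vesicle (EV) fractions by spontaneous Raman and
    surface-enhanced Raman spectroscopy (SERS). Provides an axis-safe spectral
    data model with readers and writers for delimited spectrum tables, Raman
    maps and a JCAMP-DX subset; fingerprint-region preprocessing
    (Savitzky-Golay smoothing, asymmetric-least-squares baseline correction,
    band-maximum intensity normalization); selection and averaging of the most
    intense spectra from Raman maps; cancer-versus-control difference spectra
    with chord-baselined marker-band integration, band ratios and
    noise-thresholded sign calls; EV mass-concentration estimation from
    nanoparticle tracking analysis counts and dynamic light scattering
    diameters together with silver-nanoparticle mixing arithmetic; and a
    seeded generator of synthetic SERS/Raman spectra, maps and patient cohorts
    for end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
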