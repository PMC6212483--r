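Package: SpeRe
Title: Spectral Reflectometry Decoding of Dielectric Microsphere Probes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and nanometre-precision decoding of the
    interference reflectance spectra of dielectric microsphere probes
    ("reflectophores"). A ray focused at the centre of a sphere behaves as a
    normal-incidence ray through a thin film of matching thickness, so the
    reflectance spectrum is a Fabry-Perot fringe pattern that encodes the
    sphere's optical size. The package provides dispersive material models and
    a lossless transfer-matrix solver, a diameter-indexed spectrum database
    with Pearson-correlation decoding of measured spectra, a wavenumber-domain
    phasor representation (fringe frequency and phase), microenvironmental
    sensing models (protein-adlayer redshift and density inversion,
    liquid-crystal effective-index shifts), photometric comparisons against
    fluorophores, and a synthetic confocal spectral-reflectometry instrument
    for fully reproducible offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'materials.R'
    'optics.R'
    'database.R'
    'decode.R'
    'phasor.R'
    'sensing.R'
    'photometry.R'
    'instrument.R'
    'io.R'
    'cli.R'
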