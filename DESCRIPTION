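Package: conedrive
Title: Silent-Substitution Stimulus Design and Cone-Driven Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring post-retinal cone function in the dog.
    Designs silent-substitution spectral modulations on a multiprimary light
    engine using Govardovskii pigment templates and canine lens filtering;
    estimates pupillometry response amplitude and phase at the stimulation
    frequency with exhaustive bootstrap errors; preprocesses blocked-flicker
    BOLD fMRI sessions (linear detrending, MAD-based spike detection,
    motion-PCA confound regression, hemispheric mirror averaging) and fits a
    nonlinear forward model with a three-component hemodynamic basis and
    per-acquisition response amplitudes. A fully seeded synthetic-data
    generator emulates wild-type and retinal-degeneration disease models
    (RCD1, XLPRA2, CRD2, and CRD2 after gene therapy) for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
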