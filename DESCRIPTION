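Package: ssnadyn
Title: Conformational Ensembles and Chain Dynamics of Single-Stranded
    Nucleic Acids from Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for nanosecond chain dynamics of short
    single-stranded nucleic acids probed by single-molecule Foerster
    resonance energy transfer (FRET) and nanosecond fluorescence
    correlation spectroscopy (nsFCS). Provides parametric end-to-end
    distance distributions (Gaussian chain, worm-like chain, SAW-nu),
    calibration of those models to measured transfer efficiencies,
    Boltzmann inversion to potentials of mean force, maximum-entropy
    (BioEn) ensemble reweighting against transfer-efficiency moments,
    correlation times and end-to-end contact rates for diffusive chain
    motion in a potential of mean force, photon burst analysis with
    count corrections and shot-noise photon distribution analysis,
    photon-pair correlators with full-FCS and nsFCS model fitting,
    polarized fluorescence decay (anisotropy) fitting with IRF
    reconvolution, hierarchical chain growth from fragment libraries,
    and seed-deterministic generators for Brownian end-to-end distance
    trajectories and FRET photon streams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
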