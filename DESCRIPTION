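Package: memtitra
Title: Constant-pH Monte Carlo Titration with Transmembrane pH Gradients
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metropolis Monte Carlo sampling of protonation microstates for
    interacting titratable sites under one or two proton baths, pH
    replica-exchange (pHRE) driving of a pluggable conformational propagator,
    and the downstream analyses used to characterise membrane-inserting
    pH-sensor peptides: signed residue insertion relative to the local lipid
    phosphate surface, annulus half-thickness and local bilayer deformation
    profiles, and insertion-binned protonation and pKa profiles obtained by
    Hill-equation fitting with Bayesian-bootstrap errors. Includes exact
    enumeration oracles and synthetic surrogate systems (a one-dimensional
    peptide-membrane model with a depth-dependent intrinsic pK, and a
    membrane-frame generator with controlled deformation) so that the whole
    pipeline can be exercised and validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    bio3d,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
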