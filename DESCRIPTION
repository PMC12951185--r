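Package: focalcoil
Title: Focal-Deep TMS Coil Design and Evaluation in a Spherical Head Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of focal-deep transcranial magnetic
    stimulation (TMS) coils. Optimizes a divergence-free surface current
    (stream function) on a parametric coil support for minimum stimulated
    volume at a prescribed depth, subject to peak-field, energy, and
    wire-fit constraints; discretizes the optimal current into
    manufacturable single- and hybrid-layer wire windings; and evaluates
    depth, spread, energy, inductance, and scalp-exposure figures of merit
    using the closed-form quasi-static electric field inside a homogeneous
    spherical head model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    Rcpp,
    pracma,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
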