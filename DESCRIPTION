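Package: telofold
Title: Kinetics and Single-Molecule FRET Analysis of Consecutive
    Telomeric G-Quadruplex Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how consecutive G-quadruplexes fold on long
    human telomeric DNA repeats from single-molecule FRET data. Implements an
    off-path kinetic partitioning model of G-quadruplex nucleation in which
    internally nucleated structures block complete folding, with deterministic
    (rate-equation) and stochastic (Gillespie) solvers, closed-form equilibria,
    and weighted least-squares rate fitting to folded-fraction time courses.
    Includes alternating-laser-excitation FRET corrections (donor leakage,
    direct excitation, detection imbalance), FRET efficiency histograms and
    folded-fraction estimates with split-sample uncertainties, Gaussian hidden
    Markov segmentation of FRET traces with dwell-time and lifetime analysis,
    Forster distance-to-efficiency conversion, and a synthetic trace generator
    emulating the full measurement chain for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
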