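Package: mscscreen
Title: Thermostability Candidate-Site Screening by Flexibility, Steered
    Pulling and Conservation Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens enzyme active-centre residues for thermostability
    engineering by combining three desk-scale analyses: per-residue
    root-mean-square fluctuation (RMSF) compared between a low- and a
    high-temperature trajectory, substrate-contact persistence measured
    with an adaptive-acceleration steered-pulling simulator, and
    entropy-based multiple-sequence-alignment conservation graded on the
    1-9 ConSurf-style scale. Candidate sites pass a flexibility-difference
    threshold, lose residues with prolonged hydrophobic substrate
    contacts, and lose strictly conserved residues. Also provides the
    enzyme-characterisation computations used to rank mutants:
    Michaelis-Menten kinetics, first-order thermal-inactivation half-life,
    activity-profile normalisation, fold and percent comparisons, and
    fibrin-plate calibration against a urokinase standard curve.
    Synthetic-data generators with known ground truth back every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
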