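Package: fodes
Title: Two-Stage Protein Folding Intermediate Analysis (Early-Stage Geometry
    and Fuzzy-Oil-Drop Hydrophobic Core)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the two folding intermediates of the two-step protein
    folding model. The early-stage (ES) module measures backbone geometry
    through the V-angle between sequential peptide bond planes and the radius
    of curvature of pentapeptide CA traces, scores chains against a calibrated
    second-degree polynomial relating the two (D_average), and derives the
    elliptical Ramachandran subspace of ES-accordant conformations. The
    late-stage (LS) module implements the fuzzy-oil-drop analysis: effective
    atoms with Aboderin hydrophobicity parameters, canonical principal-axis
    orientation, a 3D Gaussian theoretical hydrophobicity density, the Levitt
    observed hydrophobicity distribution with a 9 Angstrom cutoff, and
    Kullback-Leibler divergences O/T and O/R classifying the hydrophobic core
    as model-accordant (O/T < O/R) or not. Synthetic fixture generators
    (ideal helices, extended chains, toy globules) make every stage testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
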