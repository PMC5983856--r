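Package: nodulesig
Title: Exemplar-Based Voxel Characterization of Lung Adenocarcinoma CT
    Nodules with Inter-Observer Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes lung adenocarcinoma nodules on CT by
    classifying every segmented voxel against nine learned density
    exemplars (affinity propagation over 9x9 in-plane histogram
    features), summarizing each nodule as a parametric signature of
    class fractions with a VIRO (solid/invasive) burden and a
    Good/Intermediate/Poor risk call.  Includes seed-voxel region-growing
    segmentation with scripted edit operations, synthetic CT nodule
    phantoms with simulated observers, and the inter-observer agreement
    battery: two-way random-effects variance components and ICC with
    F-based confidence intervals, Dice overlap, Fleiss kappa, and
    Kruskal-Wallis comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
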