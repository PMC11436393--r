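Package: mgscaffold
Title: Synthetic Micro-CT Analysis of Bioresorbable Magnesium Coronary Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and quantify the degradation of bioresorbable
    magnesium-alloy coronary scaffolds in micro-CT volumes. Provides a
    parametric six-crown/two-link scaffold geometry with a strut-segment
    connectivity graph, a voxel phantom generator (isotropic surface erosion,
    corrosion-product substitution, strut fractures, partial-volume blur,
    additive noise), histogram peak fitting for remaining-volume estimation,
    strut-discontinuity and scaffold inner-area quantification, and an
    isotropic square-strut degradation model with scenario simulation and
    least-squares fitting of the 50% and complete degradation periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
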