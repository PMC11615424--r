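Package: canalssm
Title: Statistical Shape Modeling of the Proximal Femoral Intramedullary Canal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds point-distribution statistical shape models of canal-like
    tubular anatomy, in particular the intramedullary canal of the proximal
    femur. Provides mesh and voxel geometry primitives (volume, surface RMSE,
    intersection-over-union, rigid iterative-closest-point registration),
    threshold-based segmentation of CT-like phantoms with Boolean cavity
    extraction, Gaussian smoothing with fidelity validation, landmark-based
    anatomical frames, template-to-target point correspondence with iterative
    mean-shape estimation, and PCA shape models with explained-variance
    reporting, mode perturbation export and volume-trace interpretation of
    the size mode. Includes a synthetic canal-population generator with
    planted, orthonormal modes of variation (size, proximal torsion,
    anteversion, varus/valgus, distal twist) so every stage of the pipeline
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
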