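Package: latticeplan
Title: Simulation-Free Lattice Radiotherapy Planning on Synthetic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for a simulation-free lattice radiation therapy (LRT)
    planning workflow driven by deformation-predicted synthetic CT. Provides
    3D image/dose raster types with NIfTI input and output, a seeded digital
    phantom generator for paired diagnostic/planning CT anatomy with known
    deformations, CT couch removal and bone-based rigid alignment, a toy 3D
    encoder-decoder that predicts a deformation vector field used to warp a
    diagnostic CT into a synthetic planning CT, image similarity metrics
    (MAE, NCC, SSIM, GMSD), geometric lattice sphere placement inside a
    tumor volume under organ-at-risk clearance rules, a synthetic lattice
    dose painter, and dose-volume histogram evaluation including
    isodose-based sphere fitting and exact Wilcoxon signed-rank plan
    comparison.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
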