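Package: BoxCC
Title: Box Correlation Coefficient Toolkit for Local Quality Assessment
    of Crystallographic Protein Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residue-level quality assessment of protein crystal structures
    against electron density maps. Synthesizes electron density from atomic
    coordinates with Gaussian scattering factors, computes structure factors
    and Fourier-space map manipulations (resolution truncation, noise),
    extracts residue-centered voxel boxes from crystallographic maps, and
    scores each residue with the box correlation coefficient (bCC), a local
    quality metric that correlates the model-calculated density with a
    high-resolution observed map over a cubic box around the residue.
    Includes a mask-based real-space correlation coefficient (RSCC) baseline,
    ligand delta-bCC assessment for compound binding, five-channel voxel
    descriptors, per-amino-acid 3D convolutional network regressors that
    predict bCC from a map and coordinates alone, and a self-contained
    synthetic crystal simulator for generating labeled training corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    methods
Imports:
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
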