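Package: dtihisto
Title: Linking In Vivo Diffusion Tensor Imaging to Quantitative Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline connecting in vivo diffusion tensor
    imaging (DTI) to histological tissue microstructure in experimental
    brain damage. Computes DTI scalar maps (FA, AD, RD, MD) and Westin
    shape indices (CL, CP, CS) from tensor eigenvalues; quantifies
    histology micrographs by automated cell counting, pixelwise 2D
    structure-tensor anisotropy, and skeleton-based astrocyte
    morphometry (branches, junctions, endpoints, triple and quadruple
    points) with small-fragment filtering; provides estimation
    statistics (Cohen's d with BCa bootstrap confidence intervals,
    studentized permutation t-tests, Benjamini-Hochberg FDR); and fits
    cross-validated multivariate regression models predicting histology
    from DTI, with leave-one-animal-out and leave-one-region-out
    schemes reporting cross-validated R and Q2. Includes synthetic
    phantom generators (Nissl-like cell fields, oriented fiber
    textures, branching astrocyte trees, cohort tables with a known
    linear DTI-histology relation) so the whole pipeline is testable
    end to end without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    withr,
    tiff,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageAnalysis, CellBiology, Regression
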