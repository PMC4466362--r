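Package: npquant
Title: Quantification of Internalized Nanoparticles from 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to count silica nanoparticles internalized by adherent
    cells from multi-channel 3D STED/confocal image stacks, and to place the
    counts in a dosimetric context. Provides a ground-truthed synthetic stack
    generator (cell phantom, Gaussian point-spread function, Poisson shot
    noise, detector saturation), Richardson-Lucy deconvolution, Otsu
    thresholding with 3D morphological cell-mask extraction, watershed-based
    particle object detection with strict inside-cell classification,
    Gaussian line-profile FWHM fitting, a 1D sedimentation-diffusion
    (particokinetics) solver for the delivered dose, agglomerate packing
    models, and administered/delivered/intracellular dose arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    rlang,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
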