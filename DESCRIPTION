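Package: nnfdk
Title: Neural Network FDK Reconstruction for Circular Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for circular cone-beam computed tomography at desk scale:
    a native forward/backprojector pair, the Feldkamp-Davis-Kress (FDK)
    filtered-backprojection algorithm with standard Ram-Lak and Hann filters,
    and the NN-FDK reconstruction algorithm, a shallow multilayer perceptron
    whose first-layer weights are exponentially binned FDK filters. Includes
    phantom simulation (Fourshape and Defrise families) with Beer-Lambert
    Poisson noise, Levenberg-Marquardt training with validation gating, a
    nonnegativity-constrained SIRT baseline, and quantitative evaluation
    (test set error, structural similarity, segmentation overlap metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
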