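Package: skinget
Title: Numerical Modeling of Skin Electroporation for Gene Electrotransfer
    Protocol Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and comparing pulse delivery protocols for
    gene electrotransfer (GET) to skin. Implements an eight-layer anisotropic
    skin model with electric-field-dependent conductivity, a stationary
    sequential finite-volume solver for electrode-array pulse protocols,
    reversible/irreversible electroporation volume metrics, generators and
    validators for hexagonal-array commutation protocols, and quantification
    of transfection from fluorescence images by thresholded area, mean
    intensity, and integrated density.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
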