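Package: TAAinvert
Title: Synthetic Thoracic Aortic Aneurysm Maps and Neural-Operator Inversion
    of Mechanobiological Insults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic thoracic aortic aneurysm (TAA) datasets from
    spatially correlated mechanobiological insult fields (compromised elastic
    fiber integrity and dysfunctional cellular mechanosensing) using a reduced,
    mechanobiologically equilibrated growth-and-remodeling membrane model of
    the aortic wall; builds localized dilatation and distensibility maps in
    physical ("heat") and 8-bit grayscale encodings; and trains and compares
    four neural-operator architectures (CNN- and FNN-branch deep operator
    networks, a UNet, and a Laplace neural operator) that invert those maps
    back to the initiating insult fields. Includes a self-contained
    reverse-mode neural network core, evaluation metrics (whole-domain and
    insult-filtered relative L2 errors), and a reproducible end-to-end study
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
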