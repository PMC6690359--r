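Package: gvtsig
Title: Network-Weighted Plasma-Proteomics Signatures of Graft-Versus-Tumor
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a six-step systems-biology pipeline that turns paired
    isotope-labeled plasma-proteomics heavy/light ratio tables into a
    disease-specific biomarker signature: fold-ratio filtering, exclusion of
    disease-confounded proteins via gene sets, candidate protein-protein
    interaction subnetworks with an optional one-hop "outer gene" extension,
    network-weighted relevance scores, other-disease penalty scores,
    cross-experiment score combination, Gaussian-kernel terrain visualization
    of the scored network, and overlap of the signature with antigen-specific
    single-cell expression categories. Ships a synthetic-data generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
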