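Package: nmjquant
Title: Quantification of Marker Accumulation and 3D Proximity at
    Neuromuscular Junctions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Object-based colocalization analysis for multichannel
    fluorescence microscopy of neuromuscular junctions (NMJs). Implements a
    per-NMJ accumulation classifier (a marker is called immunopositive at an
    NMJ when its mean intensity in the alpha-bungarotoxin-defined region of
    interest exceeds the muscle-fiber mean plus one fiber standard
    deviation), threshold-based 3D segmentation with object-size filtering
    and image-edge exclusion, anisotropic edge-to-edge nearest-object
    distance analysis in physical units, and a ground-truthed synthetic
    multichannel image generator (postsynaptic plaques in a synapse band,
    apposed presynaptic boutons, filamentous axons, diffuse receptor signal,
    PSF blur, Poisson and Gaussian noise) so that every stage of the
    pipeline can be validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
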