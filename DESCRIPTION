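Package: octflow
Title: Doppler Optical Coherence Tomography Reconstruction and Cerebral
    Microvascular Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of cerebral blood flow velocity (micro-ODT) and
    angiography (micro-OCA) volumes from repeated-B-scan optical coherence
    tomography acquisitions, removal of bulk-motion stripe artifacts and
    phase noise by self-supervised convolutional models (gated-convolution
    structure-aware inpainting of vesselness masks; intensity-remapping and
    vessel-cropping augmentation for 3D volume enhancement), and
    quantification of vascular networks: Hessian-based vessel orientation and
    Doppler-angle correction, arteriole/venule discrimination from branching
    flow direction, vessel diameters, skeleton-based capillary density, and
    per-ROI relative flow time courses. A physics-based phantom generator
    produces synthetic vascular trees and complex OCT acquisitions with
    ground-truth sidecars so the whole pipeline is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
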