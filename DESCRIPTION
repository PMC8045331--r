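Package: ctvMargins
Title: Direction-Dependent Clinical Target Volume Margins from Expert
    Contour Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes clinical target volume (CTV) margins from a gross
    tumor volume (GTV) in arbitrary clinician-specified 3D directions by
    casting expansion vectors between binary-mask surfaces, quantifies
    interobserver margin disagreement per direction with the coefficient
    of variation of per-expert margins, builds STAPLE consensus
    segmentations from expert mask ensembles, and summarizes margins
    across cases by route-of-spread class. Ships an analytic phantom
    generator with exact ground-truth margins for validation, NIfTI and
    NRRD mask I/O, a planar-contour rasterizer, and a command-line
    interface for study runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    oro.nifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
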