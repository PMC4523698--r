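Package: vesselvote
Title: Multi-Modal Multi-Scale Tensor-Voting Vessel Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extraction of bright tubular (vascular) structures from one or
    more co-registered 3-D angiographic volumes. Voxels are screened with a
    multi-scale Hessian vesselness filter, encoded as second-order symmetric
    tensors at their locally optimal scale, and refined by tensor voting with
    a scale-adaptive neighbourhood. The accumulated tensor field is decomposed
    into surface, curve and junction saliency maps, and per-modality maps are
    fused into a single vessel-probability volume by a cosine consistency
    measure (with min/max baselines). Includes fuzzy Dice evaluation,
    multi-rater consensus construction, a synthetic multi-modal vascular
    phantom generator with ground truth, NIfTI I/O and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
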