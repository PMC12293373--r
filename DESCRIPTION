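Package: fewshot3d
Title: Few-Shot Classification of 3D Medical Image Volumes with
    Prototype Networks and the GE2E Embedding Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Episodic 2-way k-shot classification of 3D grayscale volumes
    (e.g. knee MRI series) with a small 3D convolutional embedding encoder.
    The encoder is trained with the generalized end-to-end (GE2E) loss,
    which pulls embeddings of same-label samples toward their label
    centroid under cosine similarity and pushes other labels away; query
    volumes are classified by the Euclidean distance of their embedding to
    per-class prototypes (support-set mean embeddings). Includes volume and
    manifest input/output (NIfTI and NumPy array stacks), deterministic
    preprocessing, a synthetic lesion-phantom generator with known ground
    truth, patient-disjoint episode sampling, supervised (cross-entropy)
    pre-training for transfer experiments, and a sensitivity/specificity/
    accuracy/ROC-AUC evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
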