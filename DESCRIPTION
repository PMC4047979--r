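Package: endolight
Title: Searchlight SVM Mapping of Candidate Neuroimaging Endophenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate group comparison of spatially normalized gray-matter
    volume maps with an exhaustively overlapping cubic searchlight. Each
    in-mask voxel centres a small cubic region whose voxel pattern is scored
    by cross-validated linear support-vector-machine accuracy; region-level
    significance is assessed by label permutation with Benjamini-Hochberg
    false-discovery-rate control, and significant accuracies are projected
    back to voxels by max-projection. Two pairwise comparisons (controls
    versus cases, controls versus unaffected siblings) are intersected and
    summarised against a labelled atlas to map candidate endophenotypes, and
    a classifier-transfer test checks whether siblings express the case
    pattern. Includes a phantom-cohort generator with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
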