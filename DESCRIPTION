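Package: adaptune
Title: Release-from-Adaptation Tuning Analysis for fMRI Repetition Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the brain's response to a deviant
    stimulus recovers ("releases") from repetition suppression as a
    function of feature-based similarity between the adapted and the
    deviant object. Computes cosine similarity from feature-production
    norms and bins object pairs into four similarity levels; generates
    behavioral and rapid event-related fMRI adaptation designs; simulates
    reaction-time datasets and 4D BOLD runs with planted adaptation decay
    and similarity-graded release; fits finite-impulse-response and
    canonical-HRF general linear models voxel-wise; derives the
    adaptation contrast and voxel-wise similarity-tuning regressions;
    performs one-sample sign-flip permutation inference with
    threshold-free cluster enhancement (TFCE); and clusters tuning curves
    with leave-one-out k-means and consensus regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
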