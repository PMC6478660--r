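Package: petez
Title: Epileptogenic-Zone Localization from Interictal FDG-PET by Dynamic
    Single-Subject Parametric Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise statistical parametric mapping of a single interictal
    FDG-PET study against a normative control cohort for presurgical
    epileptogenic-zone (EZ) localization.  Implements the full processing
    chain: affine spatial normalization to a PET template, quotient-histogram
    parabola intensity normalization (with SPM-style proportional scaling as
    an alternative), Gaussian smoothing, single-subject versus cohort t-maps,
    dynamic (p, cluster-extent) segmentation with anatomical exclusion rules,
    cluster ranking, side/sublobar EZ calling, and the associated evaluation
    statistics (concordance summaries, Cohen's kappa with verbal bands, exact
    McNemar, chi-square, one-way ANOVA).  A synthetic brain-phantom generator
    with known ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
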