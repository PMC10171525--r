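Package: gmsignature
Title: Consensus Gray-Matter Brain Signatures from Subsampled Voxelwise Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gray-matter "brain signature" regions associated with a
    behavioral outcome by running voxelwise regressions with nonparametric
    cluster-size permutation inference in many random discovery subsets,
    aggregating the surviving clusters into consensus masks at several
    t-thresholds, and deriving a single signature variable from mean
    gray-matter density within those masks.  Includes tools for validating
    signature models against demographic and atlas-ROI competitor models
    (bootstrap confidence intervals on adjusted R-squared differences,
    paired-subset replication with Bland-Altman agreement), spatial mask
    similarity (Dice, eta-squared), and a synthetic-cohort generator with
    planted effects so the whole pipeline can be exercised with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
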