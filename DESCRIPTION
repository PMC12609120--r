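Package: eoquant
Title: Quantification of Pancreatic Endocrine Objects in Chromogen-Stained Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pancreatic endocrine objects (EOs) --
    single endocrine cells through whole islets -- in bright-field images of
    chromogen-immunolabeled pancreas sections.  Implements optical-density
    stain deconvolution for hematoxylin/DAB/Warp Red labeling, connected-
    component EO detection with size and staining-artifact filters, hormone-
    content classification (insulin/glucagon), log2 size binning, shape
    morphometrics (circularity, solidity, Feret diameters), cross-platform
    annotation matching, and cohort-level aggregation with the rank-based and
    ANOVA statistics used in islet morphometry studies.  A synthetic-section
    and synthetic-cohort generator provides ground-truthed inputs so every
    stage of the pipeline can be validated without access to tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
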