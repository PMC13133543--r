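Package: miaqsar
Title: Multivariate Image Analysis QSAR for Congeneric Herbicide Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR) models
    from multivariate image analysis (MIA) descriptors: aligned 2D ball-and-stick
    depictions of a congeneric series are rasterized with pixels recoded to atomic
    properties (Pauling electronegativity or van der Waals radius), unfolded into
    a descriptor matrix, and regressed against pIC50 by single-response NIPALS
    partial least squares. Includes Kennard-Stone representative splitting,
    leave-one-out cross-validation, y-randomization and bootstrap stability tests,
    a full external-validation metric suite (r2m, CCC, Q2F1/Q2F2, MAE),
    Williams-plot applicability-domain assessment, VIP and coefficient image maps,
    activity prediction for proposed analogs, and a synthetic congeneric-series
    generator with known planted effects for end-to-end testing. Ships a
    33-compound phenyltriazolinone protoporphyrinogen-oxidase (PPO) inhibitor
    dataset and a transcribed scaffold template library as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
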