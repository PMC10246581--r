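Package: yieldmil
Title: Attention-Based Multiple Instance Learning for Multi-Modal Grain
    Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-plot grain yield in plant breeding trials by fusing
    variable-size bags of time-stamped UAV images (multispectral, thermal,
    digital elevation models) with SNP genotype dosages through a
    permutation-invariant, attention-based multiple instance learning model.
    Includes a synthetic breeding-trial generator with tunable genetic
    architecture, genotype quality-control filters, vegetation-index baseline
    featurization, grouped/stratified evaluation protocols, cross-environment
    genotype-only prediction, attention-based interpretation, and
    selection-gain curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    tiff,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
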