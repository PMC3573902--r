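Package: phytoflow
Title: Synchronous Leaf and Root Growth Phenotyping from Grey-Value Time-Lapse Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-temporal-resolution plant growth phenotyping from
    grey-value time-lapse image stacks. Dense velocity fields are estimated by
    a structure-tensor (total-least-squares brightness-constancy) optical-flow
    method; leaf relative growth rate is derived both as the divergence of the
    velocity field over a tracked area of interest and from the log-area
    formula on the advected polygon; root elongation is quantified by tracking
    the root tip relative to the spatially fixed mature region. Diel
    (nocturnal/diurnal) aggregation with replicate standard errors and
    treatment comparisons is included, together with a synthetic scene
    generator that renders leaf expansion and root elongation with exact
    ground truth so every stage of the pipeline can be validated without real
    imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    EBImage,
    mgcv,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
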