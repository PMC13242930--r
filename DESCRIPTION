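Package: rrmlw
Title: Random Regression Animal Model for Total Litter Weight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pedigree-based REML/BLUP analysis of total litter weight in
    multiparous species, modelling the genetic effects of the dam and the
    sire as random linear regression slopes on standardized litter size.
    Provides pedigree utilities (inbreeding, numerator relationship matrix
    and its sparse inverse), restricted maximum likelihood estimation of the
    slope (co)variance components with average-information standard errors,
    best linear unbiased prediction of parental effects with prediction
    error variances and reliabilities, litter-size-dependent heritability,
    transformations between slope and maternal-direct parameterizations, a
    restricted likelihood ratio test for the sire component, traditional
    baseline models (total, adjusted and average birth weight), a bivariate
    litter weight-litter size model, and a pedigree/litter simulator for
    validation and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
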