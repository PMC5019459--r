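Package: phantomdose
Title: Stylized Reference Phantoms and Photon Monte Carlo Internal Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs MIRD-type stylized adult reference phantoms (the
    Taiwanese reference man and woman and the ORNL adult phantom) from
    quadric-surface solids, calibrates organ models to reference volumes,
    and computes specific absorbed fractions (SAFs) and MIRD S-values for
    photon emitters with an analog Monte Carlo transport engine based on
    Woodcock delta-tracking.  Ships tissue compositions, a semi-empirical
    elemental photon cross-section model, and emission data for I-131 and
    Tc-99m.  Results are returned as tibbles with plotting and tidying
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
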