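Package: fluidcell
Title: Single-Cell and Collective NF-kB Activation Under Localized Agonist Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing single-cell, cluster, and
    whole-culture NF-kB activation of macrophage-like reporter cells under
    localized TLR-agonist delivery from a microfluidic (FluidFM) probe.
    Provides a closed-form dispensing-diffusion concentration model with
    build-up and decay, a clustered synthetic-culture generator with a
    dose-time-density activation response model, minimal two-channel image
    rendering and nuclear/cytoplasmic ratio quantification, calibration-cutoff
    activation calling with bootstrap uncertainty, spatial neighbor and
    density statistics, resampling inference (exceedance test, permutation
    ANOVA, rank-sum, bootstrap effect sizes), log-dose logistic dose-response
    fitting, and an order-of-magnitude free-vs-bound ligand budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
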