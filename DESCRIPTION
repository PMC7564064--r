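Package: ecoqsar
Title: Multi-Effect QSAR Design of Eco-Friendly Flame-Retardant Plasticizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-objective molecular design of phthalate-ester
    (PAE) plasticizers that couple flame retardancy with reduced ecological
    impact. Implements the empirical limited-oxygen-index (LOI) estimate from
    char residue, min-max normalization with ideal-point comprehensive
    scoring of flammability, biotoxicity and bioconcentration, a CoMSIA-style
    3D similarity-field engine with NIPALS partial-least-squares regression,
    leave-one-out cross-validation and contour-map export, substituent-based
    derivative enumeration with eco-friendliness screening, and modified-group
    coupling-value analysis. Molecular structures are handled through an
    RDKit backend; packaged property tables make every stage reproducible
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    generics,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with the rdkit package, discoverable as
    'python' or 'python3' on the PATH or via option 'ecoqsar.python'.
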