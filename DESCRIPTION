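Package: spinlls
Title: A-Priori Prediction of Long-Lived Nuclear Spin-State Lifetimes in Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts magnetization storage lifetimes in small endogenous
    molecules from their declared proton spin systems. Builds the coherent
    Liouvillian and the dipolar Bloch-Redfield-Wangsness relaxation
    superoperator on the product-operator basis, identifies long-lived
    states and their lifetimes by Liouville-space eigenanalysis, optimizes
    bilinear three-spin scalar-product states, and simulates the
    spin-lock-induced-crossover (SLIC) experiment with Monte-Carlo decay
    fitting. Ships idealized fixtures for common amino acids and fumarate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
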