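Package: zfpk
Title: Compartmental Pharmacokinetics of Paracetamol in Zebrafish Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing drug uptake and clearance in zebrafish
    larvae from pooled destructive-sampling experiments. Implements a
    compartmental model with zero-order uptake from the incubation medium and
    first-order elimination, naive-pooled maximum-likelihood estimation with
    additive/proportional/combined residual-error models, likelihood-ratio
    model selection and weighted-residual diagnostics; larval volume
    estimation from pooled wet weights; conversion of fractional to absolute
    clearance; cross-species allometric scaling of clearance with confidence
    and prediction intervals; and a synthetic-data generator emulating the
    experimental designs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
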