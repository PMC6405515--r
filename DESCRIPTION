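Package: hepaflux
Title: Constraint-Based Prediction of Liver-Driven Plasma Metabolite Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Attributes plasma metabolite changes during short-term fasting to
    liver metabolism with a constraint-based workflow: production scoring of
    exchangeable metabolites in a genome-scale (or toy) metabolic network under
    two physiological flux-bound conditions via minimum-weighted-total-flux
    linear programs, a pooled percentile-bootstrap caller for the direction of
    plasma metabolite fold changes across multiple studies, and an
    exact-binomial concordance evaluation of predicted versus observed
    directions. Includes a synthetic-data module (gluconeogenic toy liver
    network with planted production-direction truths, and log-normal MS count
    tables with planted fold changes and left-censored missingness) and an
    end-to-end pipeline driver. The linear-programming core is a self-contained
    bounded-variable two-phase simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
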