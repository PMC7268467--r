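Package: pgxchain
Title: Simulated Smart-Contract Storage and Query of Pharmacogenomics Observations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Stores and queries pharmacogenomics observations (gene, variant,
    drug, outcome, suspected gene-outcome relation, serious side effect) with
    two contract-storage designs modelled on Ethereum smart contracts: an
    index-based multi-mapping design that stores every observation, and a
    pooled design that keeps one aggregate record per unique gene-variant-drug
    combination. Both run against a minimal hash-linked, single-sealer ledger
    with per-storage-operation gas accounting, so correctness of wildcard
    intersection queries and the scalability separation between the two
    designs can be measured without any blockchain network. Includes a
    seedable synthetic observation generator, a brute-force query oracle, a
    gas-based benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
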