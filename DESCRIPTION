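Package: almanet
Title: Multi-Target Link Assessment with Markov-Shannon Entropy
    Descriptors and Moving Averages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target-assay interaction links from molecular
    structure and pharmacological assay context. Molecules are encoded as
    Markov-Shannon entropy descriptors of the electronegativity-weighted
    molecular graph; assay context enters through Box-Jenkins style
    moving-average operators computed over condition subsets (experimental
    measure, assay, organism, target). A linear discriminant model scores
    candidate links, and observed or predicted links are assembled into
    tripartite drug-target-assay networks with per-node degree and
    Markov-Shannon entropy statistics. Includes a synthetic endpoint-table
    generator with planted coefficients for validation, and a command-line
    interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
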