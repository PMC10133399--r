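Package: deggs
Title: Differentially Expressed Gene-Gene Interaction Subnetworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts phenotype-group-specific gene-gene interaction
    subnetworks from a prior molecular-interaction network and a matrix of
    normalized expression values. Each retained edge is scored for
    differential co-expression between groups with a (robust) linear
    regression carrying a Gene x Group interaction term; the percolation
    cut-off on node mean expression is tuned to maximize the number of
    statistically significant differential interactions. Includes a seeded
    synthetic-data generator with planted group-dependent edges, a
    command-line interface, and a self-contained static HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
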