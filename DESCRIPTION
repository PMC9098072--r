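Package: immunet
Title: Metabolite-Immune Process Association Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds protein-metabolite interaction networks from
    database-style tables (Gene Ontology immune-process terms, protein and
    metabolite catalogs, STRING-style scored protein-protein interactions,
    Rhea-style reaction participant lists), lets metabolites inherit
    immune-process annotations from neighbouring proteins at configurable
    order, scores metabolite-process associations by harmonic closeness
    centrality, precision and Fisher overrepresentation with
    Benjamini-Hochberg correction, flags biomarker candidates, and evaluates
    predicted associations against a literature-derived gold standard.
    Includes a seeded synthetic-fixture generator and a packaged miniature
    atlas for a T cell-mediated immunity process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
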