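Package: oxascreen
Title: Genome Mining of Bacterial Oxalate Metabolism Toolkits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens bacterial proteomes for the enzymes and the transporter
    of oxalate metabolism, using protein local alignment with Karlin-Altschul
    bitscore and E-value statistics and a four-way hit filter (E-value,
    bitscore, percent identity, query coverage). Builds presence/absence and
    copy-number trait matrices, summarises enzyme occurrence per genus,
    classifies strains by completeness of the biomineralization
    (oxalyl-CoA decarboxylase, formyl-CoA transferase, oxalate:formate
    antiporter) and assimilation (glyoxylate carboligase, hydroxypyruvate
    reductase, serine-glyoxylate transaminase) toolkits, compares key-enzyme
    protein sequences between oxalate-positive and oxalate-negative strains
    to classify conservative versus non-conservative substitutions, and
    places strains in context with a MinHash genome distance matrix and a
    neighbor-joining tree. Ships a seeded synthetic-cohort generator with a
    ground-truth manifest so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
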