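Package: gw2drug
Title: Genomics-Driven Drug Repurposing from GWAS Associations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An offline pipeline that turns genome-wide association study
    (GWAS) catalog associations for a disease into ranked drug-repurposing
    candidates. Lead variants passing genome-wide significance are expanded
    to linkage-disequilibrium proxies, the genes carrying those proxies are
    scored against six binary functional-annotation criteria (missense
    variant, whole-blood cis-eQTL, Gene Ontology biological process,
    cellular component and molecular function enrichment, and primary
    immunodeficiency membership), genes reaching the risk threshold are
    expanded one hop through a protein-protein interaction network, and the
    expanded gene set is overlapped with a drug-target table. Each candidate
    drug is triaged as approved for the disease, in clinical trial, or
    novel. Includes a synthetic-data generator with planted ground truth so
    the whole pipeline is testable without database access, plus fixtures
    for a published multiple myeloma analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
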