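Package: ehrkg
Title: Knowledge Graphs from MIMIC-III-Style Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an OWL-style ontology for intensive-care electronic
    health records distributed as MIMIC-III-format CSV tables, maps those
    tables to RDF triples with deterministic IRI minting and typed
    literals, validates the resulting graph against the ontology's
    domain and range declarations (including union-of-classes domains),
    and evaluates SPARQL-subset cohort queries (diagnosis prefix,
    comorbidity, repeated ICU admission) over an in-memory triple store.
    Ships a seeded synthetic EHR generator with planted cohorts, a
    ground-truth manifest, and an independent relational oracle so the
    whole pipeline is testable without access to the credentialed
    clinical source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
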