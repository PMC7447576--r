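Package: litcooc
Title: Dictionary-Based Protein Co-Occurrence Mining from Abstract Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained literature-mining pipeline for building
    protein-protein co-occurrence networks from NCBI-PubMed/MEDLINE XML
    abstract collections. Abstracts are parsed into sentence-segmented
    records, bioentity names and biointeraction trigger terms are tagged
    against fully in-memory lexicons, and every pair of co-mentioned
    protein or gene names is classified into one of four reliability
    types (exact trigger between the names, exact trigger anywhere in the
    sentence, permissive stem-level trigger match, or same-abstract
    only). Results can be filtered by NCBI taxonomy identifier,
    aggregated into per-corpus summary reports with non-redundant counts,
    and exported as weighted co-occurrence networks (SIF, TSV, GraphML).
    Corpora are processed one file per worker so that output is
    byte-identical for any degree of parallelism, and a seeded synthetic
    corpus generator with planted, ground-truthed interactions supports
    end-to-end validation without network access.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    parallel,
    stats,
    stringi,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
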