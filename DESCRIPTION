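Package: studynet
Title: Geospatial Research Networks from Trial Registries and Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for mining geolocated clinical-research
    collaboration networks. Ingests trial-registry records (a documented
    subset of the ClinicalTrials.gov legacy full-study XML) and biomedical
    citations (a PubMed XML subset), geocodes study sites and unstructured
    author affiliations against a geonames-style gazetteer using a
    descending-priority cascade (known facility name, city plus country
    evidence, most populous city), normalizes multilingual disease terms to
    concept identifiers via an MRCONSO-style concept table with prefix
    autosuggestion, and assembles research networks in which every study
    induces a fully connected subgraph over its sites. Supports great-circle
    perimeter filtering, trial/article deduplication by registry and
    publication identifiers, GeoJSON and GraphML export, a seeded synthetic
    corpus generator with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    stringi,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
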