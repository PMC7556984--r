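Package: collabflow
Title: Institutional Collaboration and Knowledge-Flow Networks from
    Bibliographic Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds institution-level networks from tagged bibliographic
    corpora: an undirected collaboration network whose edge weights count
    co-publication cases, and a directed knowledge-flow network whose edge
    weights count citation cases from cited to citing institutions.
    Computes weighted network indices (industrial participation, weighted
    average clustering with geometric edge-weight averaging, weighted-degree
    assortativity, top-share concentration), within-institution citation-flow
    fractions, and annual publication/citation series with optional
    self-citation exclusion. Includes a synthetic corpus generator with
    Zipf-like institutional activity and preferential citation attachment,
    plus a deterministic end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
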