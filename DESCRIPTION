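Package: repmap
Title: Social Representation Analysis of Stakeholder Cognitive Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for signed cognitive maps elicited from
    stakeholders of a social-ecological system. Reads Mental-Modeler-style
    adjacency matrices and edge lists, condenses raw concept labels into
    components and types through a catalog, aggregates individual maps into a
    social cognitive map by matrix addition, classifies components into the
    four zones of a social representation with a centrality-frequency method,
    clusters respondents by principal component analysis of nine map metrics
    followed by hierarchical clustering, compares clusters, and extracts
    focal subgraphs around chosen challenges. A calibrated synthetic map
    generator with planted zone and cluster structure supports testing and
    power analysis when interview data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
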