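Package: netzip
Title: Compression-Based Comparison of Node-Labeled Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic grammar-style compression of node-labeled undirected
    multigraphs by iterative contraction of identical edges (CompressEdge) and of
    identical connected vertex sets canonicalized by dl-sequences
    (CompressVertices), together with a compression-based network similarity
    (GUSM) that approximates the universal similarity metric, Morgan-index
    relabeling, single-linkage clustering of network collections with Newick
    export, a matching-based baseline compressor, and seeded synthetic graph
    generators. Intended for comparing biological networks such as metabolic
    networks where vertices carry chemical-compound or structure-derived labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
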