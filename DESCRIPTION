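Package: gatlink
Title: Graph-Level Attention Networks for lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between long non-coding RNAs (lncRNAs) and
    diseases by classifying h-hop enclosing subgraphs of the lncRNA-disease
    bipartite graph with a graph neural network (one graph-convolution layer
    followed by stacked graph-attention layers). Node attributes combine
    Gaussian interaction profile kernel similarity of lncRNAs with a disease
    similarity derived from disease-module separation on a gene-gene
    interaction network. Includes cross-validation protocols for known pairs
    and for cold-start lncRNAs/diseases, candidate ranking for a disease of
    interest, and a synthetic-data generator with planted block structure so
    the full pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
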