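Package: dppin
Title: Differential Protein-Protein Interaction Network Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers condition-specific protein-protein interaction networks
    (PPINs) from expression profiles by fitting a per-protein linear
    association model over candidate interactors drawn from a PPI edge list,
    with model order selected by the Akaike information criterion and
    coefficients pruned by Student's t-tests.  Case and control networks are
    contrasted through an entrywise difference matrix, and each protein is
    ranked by the sum of the absolute differential association coefficients
    (its network relevance value), with significance assessed by
    condition-label permutation.  Includes quantile normalization and
    screening utilities, BioGRID ingestion, Cytoscape-compatible exports, a
    synthetic-data generator built on the same linear model for end-to-end
    validation, and a reproducible workflow driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression,
    DifferentialExpression, Network
RoxygenNote: 7.3.3
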