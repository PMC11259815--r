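Package: stoichnet
Title: Prior-Free Network Module and Pathway Inference from Multi-Omics
    Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers co-regulation network modules and multi-omics pathways
    from feature-by-sample abundance matrices without any prior pathway
    knowledge. Pairwise association is scored by combining a feature-wise
    rank-adjusted Spearman correlation with a rank-adjusted quartile-ratio
    stoichiometry score; modules are assembled from maximally scoring
    three-feature cliques with explicit join and trim rules, and modules are
    combined across omics layers into pathways by re-running the inference
    on module-median expression profiles. Modules and pathways are validated
    against annotation relations using size-preserving randomized nulls with
    Epanechnikov-kernel empirical p-values, and conservation is assessed in
    independent datasets. Includes a planted-module data simulator for
    calibration and testing, and a position-weight-matrix sliding-window
    predictor of ADAM-type protease cleavage sites.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
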