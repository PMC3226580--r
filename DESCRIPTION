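Package: hubpath
Title: Hub Pathway Discovery and Anti-Correlated Meta-Activity Analysis
        from Perturbation Transcriptomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Identifies "hub" molecular pathways and their inverted
        (anti-correlated) activity groups from multi-condition
        transcriptomic perturbation studies. Implements signed gene
        ranking by log10(1/P) from per-gene t-tests, preranked gene set
        enrichment (weighted Kolmogorov-Smirnov running sum with a
        permutation null, nominal p-values and normalized enrichment
        scores), responsiveness classification via a Normalized Pathway
        Coverage function, a Pearson correlation network over z-scored
        pathway meta-activities, hub detection by responsiveness and
        connectivity thresholds, a signed-graph two-group bipartition,
        and a seed-condition scoring scheme that extends group
        membership to non-hub pathways and quantifies anti-correlated
        behavior. Includes a synthetic-data generator with a planted
        two-group inverted hub structure for validation, and a
        reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, tools, igraph, yaml,
        jsonlite
Suggests: testthat (>= 3.0.0), fgsea, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
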