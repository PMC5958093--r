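Package: swimnet
Title: Switch-Gene Discovery in Signed Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies "switch genes" -- genes that mark the transition
    between two cellular conditions -- from a two-condition expression
    matrix. The pipeline finds differentially expressed genes (Welch test,
    Benjamini-Hochberg adjustment, fold-change filter), builds a signed
    Pearson co-expression network, classifies hubs as date, party or
    fight-club by their average neighbour correlation (APCC), clusters
    expression profiles with k-means, places every node on a heat
    cartography map via the clusterphobic coefficient K_pi and the
    within-module degree Z_g, and extracts switch genes as fight-club
    hubs in region R4. Includes a degree-preserving edge-rewiring null
    model, hypergeometric miRNA-target enrichment, Kaplan-Meier
    median-split prognostic screening, and a synthetic-data generator
    with planted modules and switch genes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
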