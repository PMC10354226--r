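Package: paralogsieve
Title: Selection of Single- and Low-Copy Nuclear Markers from Long-Read
    Target-Capture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines putative single- or low-copy nuclear loci from noisy
    long-read target-capture (hybridization capture) experiments. Reads are
    extracted by best hit against the locus references, clustered per
    individual by greedy identity-threshold clustering, and summarised as
    per-cluster majority consensus sequences. Four paralogy-diagnostic
    indices are computed per locus (mean standardized reads per cluster, a
    k-mer-based similarity score per species with its spread, the
    leaf-count-weighted Shannon entropy of each individual's distribution
    over dendrogram clades, and the silhouette-optimal number of clades),
    and loci are ranked jointly by percentiles to propose marker
    candidates. Companion tools split paralogous gene trees at long
    internal branches and prune them to at most one tip per accession
    (rooted-ingroup strategy), and a synthetic-data generator with known
    copy-number ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
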