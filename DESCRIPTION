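Package: holocompare
Title: Comparative Hologenome Analysis of Sponge Hosts and Their Microbial
    Symbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the protein-domain repertoires of
    high- and low-microbial-abundance sponge hosts and the expression of
    their symbiont communities. Host-side analyses cover domain occurrence
    counting, keyword-based selection of immune and symbiosis domains,
    fold-change expansion calls, background Z-scores, domain co-occurrence
    networks, and clustering of scavenger-receptor cysteine-rich (SRCR)
    like domain families by exact Smith-Waterman alignment and Markov
    clustering, with per-cluster conservation and cysteine profiles.
    Symbiont-side analyses cover rRNA read filtering, homology-group
    construction, quantile normalisation, differential-expression calling,
    and hypergeometric domain enrichment with FDR control. A synthetic-data
    generator emulates every input so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    edgeR,
    igraph,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
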