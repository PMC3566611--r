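Package: sexbiasnet
Title: Sex-Biased Expression Networks and Nodes of Sexual Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines sex-specific RNA-seq read-depth tables with curated
    gene-gene interaction networks to locate candidate loci of interlocus
    sexual conflict. Computes a depth-weighted, globally normalised log2
    sex-bias statistic per gene, classifies genes as male-biased,
    female-biased or sex-unbiased under configurable fold-change thresholds,
    overlays the classification on undirected interaction networks, and
    summarises the resulting sex-classed subnetworks, including binned
    degree distributions with power-law tail fits above a degree cutoff.
    Reports indirect conflict nodes (sex-unbiased genes interacting with
    both strongly male- and strongly female-biased partners) and direct
    conflict pairs (edges joining strongly male- and female-biased genes),
    together with hypergeometric gene-set overlap tests and Kendall rank
    concordance between bias tables. A seeded synthetic-data generator
    produces negative-binomial count matrices and heavy-tailed interactomes
    with planted conflict motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
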