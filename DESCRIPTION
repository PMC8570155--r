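Package: ncldvnet
Title: Gene-Sharing Networks and Host-Association Analyses for Giant Virus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative gene-content analysis of nucleocytoplasmic large DNA
    virus (NCLDV) genomes from orthogroup membership tables. Builds genome- and
    family-pangenome-level copy-count matrices, computes a normalized
    gene-sharing statistic (shared orthogroups over the geometric mean of each
    taxon's orthogroups shared with any taxon), clusters the resulting weighted
    network with a from-scratch Markov Clustering implementation, quantifies
    intrafamilial genomic variation against Shannon host-supergroup diversity,
    and screens for orthogroups shared between divergent viruses that infect
    the same host type, with a one-sided tie-aware Mann-Whitney-Wilcoxon test.
    Includes a synthetic-data generator with planted family, lineage and
    host-gene structure, and a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
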