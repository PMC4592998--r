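Package: polydiv
Title: Polymorphism and Divergence Analysis for Nonrecombining Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-aware McDonald-Kreitman counting and neutrality-index
    statistics (NI, Z, Z*, NI_TG with gene bootstrap and Woolf homogeneity
    tests), site-frequency-spectrum summaries (Tajima's D, Fu and Li's D,
    Fay and Wu's H) with Kingman-coalescent null distributions conditioned
    on the number of segregating sites, linkage-disequilibrium and
    four-gamete recombination tests, and a seeded synthetic-data generator
    that emits codon-structured population alignments with an outgroup and
    exact truth records. Designed for population samples of nonrecombining
    (e.g. mitochondrial) genomes analysed against one or two outgroup
    sequences, alongside recombining nuclear genes supplied as pre-tabulated
    count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
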