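Package: cupinfam
Title: Evolutionary Analysis of the Soybean Cupin Gene Family
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for duplication-centred evolutionary analysis of a plant
    gene family, developed around the soybean (Glycine max) Cupin family.
    Provides loaders for the family's published gene, duplicate-pair and
    selected-site tables; chromosomal distribution summaries, tandem-cluster
    detection and tandem/segmental duplication classification; p-distance
    neighbor-joining phylogenies with bootstrap support and paralog-pair
    extraction; Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction and Ks-based duplication dating (T = Ks/2*lambda); RPKM
    normalization and correlation-distance hierarchical clustering of
    expression matrices; a reverse-allele-distribution classifier for
    domestication selection scans of wild versus cultivated SNP panels; and
    seed-deterministic simulators that emulate each input with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
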