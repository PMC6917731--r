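Package: albamap
Title: Bulk Segregant and Association Mapping of a Dominant Wing-Colour Morph Locus
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to map a dominant, female-limited wing-colour morph
    (the Alba polymorphism of Colias butterflies) from pooled sequencing of
    informative crosses. Implements Mendelian-expectation allele-frequency
    filters on Popoolation2-style sync tables for a female informative
    (Aa x Aa) cross and two male informative (Aa x aa) crosses, the
    three-way contig intersection rule, Fisher exact case/control SNP
    association with Benjamini-Hochberg FDR control on a re-sequencing
    panel, read-depth genotyping of a presence/absence transposable-element
    insertion, and the morph-physiology statistics (Welch tests, lipid
    quantification with body-mass correction, pigment-granule aggregation).
    A forward cross simulator with known ground truth drives verification
    of every stage without access to raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
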