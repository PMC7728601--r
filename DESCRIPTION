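Package: malus
Title: Genome Ancestry, Pan-Genome and Allele-Specific Expression Analyses for Hybrid Apples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based genome-ancestry painting of a hybrid cultivar against
    two wild progenitor species using Jukes-Cantor corrected divergences,
    pan-genome presence/absence-variation analysis with power-law core/pan
    curve modelling and species-favored orthogroup detection, haplotype-resolved
    allele-specific-expression calling across fruit developmental stages,
    supporting population-genetic statistics (nucleotide diversity, Tajima's D,
    p-distance neighbor-joining phylogenies) and mutation-rate/age conversions.
    Includes a synthetic-data module that emulates the statistical structure of
    diploid hybrid genomes, read-coverage profiles and allelic count tables so
    that every analysis stage can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    withr,
    minpack.lm,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
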