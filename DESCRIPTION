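Package: heliocross
Title: Complementation-Cross Analysis of Heliconius Yellow-Bar Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-generation complementation crosses between
    Heliconius butterfly races: phase-aware Mendelian enumeration of gametes and
    cross outcomes with race-labelled alleles, epistatic genotype-to-phenotype
    architecture models for the Cr/Sd/Yb hindwing yellow-bar loci, diagnostic-SNP
    genotype calling from aligned marker sequences (including IUPAC heterozygote
    codes and an in-silico restriction assay), exact co-segregation and
    segregation-ratio statistics, ranking of candidate genetic architectures, and
    a seeded brood simulator with direction-dependent hybrid female
    sterility/inviability so every stage runs on generated or published count
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
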