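Package: fawtyper
Title: Marker-Based Haplotype Typing of Fall Armyworm Host Strains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of fall armyworm (Spodoptera frugiperda) specimens
    from Sanger-sequenced amplicon consensus sequences. Implements the
    mitochondrial COIB h-haplotype categories (R_COIB, CSh1-CSh4) defined by
    the two polymorphic sites mCOI1164D and mCOI1287R with lettered variant
    dereplication, Z-linked Tpi strain identification (C_Tpi, R_Tpi and the
    inter-strain hybrid call H_Tpi) from the gTpi183Y diagnostic with explicit
    heterozygote handling for diploid-Z males, TpiI4a200 intron haplotyping
    over the first 60 percent of the fourth Tpi intron, and population-level
    frequency profiles with G-test comparison, p-distance matrices and
    Neighbor-Joining trees. A synthetic-data generator emulates diploid-Z
    amplicon sequencing (IUPAC overlaps from heterozygous alleles, indel-driven
    downstream ambiguity, inter-strain hybrids) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
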