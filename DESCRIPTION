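Package: regindel
Title: Population Genetics of Insertion-Deletion Polymorphism in
    Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing insertion/deletion polymorphism in
    population resequencing alignments of regulatory DNA. Calls SNPs and
    indel events from gapped alignments, computes nucleotide diversity,
    Watterson's theta, Tajima's D, Fu and Li's D* and F*, haplotype
    statistics, between-class divergence (Dxy) and sliding-window scans;
    profiles linkage disequilibrium around a focal deletion; implements a
    neutral Kingman coalescent simulator with fixed segregating sites and
    Hudson's haplotype test; scans sequences with log-odds position weight
    matrices and reports binding sites removed or truncated by a deletion;
    fits latitudinal allele-frequency clines, pairwise F_ST and exact sign
    tests; and converts embryo stripe-boundary landmarks into relative
    positions on the anterior-posterior axis with per-boundary genotype
    contrasts. Seeded synthetic-data generators emulate the statistical
    structure of each input so every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
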