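Package: nucbarcode
Title: Nuclear DNA Barcode Discovery and Amplicon Read Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for discovering novel nuclear DNA-barcode
    primer pairs from collections of plant genomes and for applying them to
    amplicon sequencing data. Candidate seed sequences are screened against two
    anchor genomes, extended into conserved candidate regions, aligned, and
    scanned for pairs of highly conserved 20-base windows spaced so that the
    implied amplicon is 100-350 bp. Predicted amplicons from in-silico PCR over
    genome and database collections form a taxon-labelled reference set against
    which sequencing reads are demultiplexed, primer-trimmed, clustered at
    full-length 100 percent identity, and assigned a lowest-common-ancestor
    taxonomic conclusion. Species mixtures are quantified from marker-cluster
    read counts corrected by 1C genome mass (C-values). A synthetic-data module
    generates taxonomies, genomes with planted multi-copy loci, and
    error-bearing reads with known ground truth for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
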