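Package: polarscan
Title: Allele Polarization and Haplotype-Based Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Polarizes phased biallelic variants into ancestral and derived
    alleles against an Ensembl-style ancestral-allele FASTA, interpolates
    genetic positions from PLINK-format reference maps, and writes the
    .hap/.map haplotype files consumed by selscan and HaploSweep. Includes
    a self-contained EHH/iHH/iHS engine for small-scale scans, parsers for
    normalized iHS output, outlier classification and polarized-versus-
    unpolarized comparisons, annotated Manhattan and EHH decay plots, and
    a seeded sweep simulator that generates fully self-consistent synthetic
    inputs with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    vcfR,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
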