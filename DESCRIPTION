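Package: heterokit
Title: Comparative Genome-Architecture Analysis of Complete Ape Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the repetitive and heterochromatic architecture of
    telomere-to-telomere (T2T) primate genome assemblies: assembly QC
    (telomere detection, gap accounting with rDNA exemption, contig N50,
    T2T classification), satellite array segmentation and classification
    (including alpha-satellite higher-order-repeat minicentromere
    partitioning and haplotype pair comparison), centromere dip region
    (CDR) calling from per-CpG methylation with CDR-vs-array-length
    regression, subterminal heterochromatin cap decomposition into
    satellite tracts and hypomethylated spacers, rDNA/NOR copy-number
    accounting, and inversion phylogenetics (Fitch parsimony branch
    assignment, recall against prior callsets, and permutation tests of
    breakpoint feature enrichment). A synthetic-genome module generates
    diploid assemblies, annotations, methylation tracks and tree-evolved
    inversion genotypes with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
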