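Package: cogent
Title: Gene-Content Redundancy, Shared Genes and Genome Distances for
    Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how unevenly the protein-coding genes of a genome
    are spread over functional categories (COGs), using Shannon entropy
    together with the broken-stick null distribution: evenness H/H_max,
    two redundancy indices (1 - H/H_max and 1 - H/H_exp), and
    rank-positional over-representation calls. Also provides desk-scale
    implementations of the surrounding comparative-genomics workflow:
    threshold-based homolog detection (E-value and percent identity) with
    three-way Venn partitioning of proteomes, an ungapped seed-and-extend
    HSP finder with the three GGDC-style genome-to-genome ratio formulas,
    genome summary statistics from FASTA/GFF3, and synthetic-data
    generators with ground-truth manifests for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
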