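Package: phagestd
Title: Packaging-Aware Standardization of Phage Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the genome-packaging strategy of a double-stranded DNA
    bacteriophage from terminase homology and per-base read-coverage
    signatures, and standardizes draft contigs accordingly: re-linearization
    at the open reading frame upstream of the large terminase subunit for
    headful (pac) phages, cutting at coverage peaks or valleys for cos and
    direct-terminal-repeat phages, trimming of variable host-DNA ends for
    Mu-like phages, and inverted-terminal-repeat aware contig selection for
    protein-primed linear genomes. Includes a synthetic packaged-genome read
    simulator with ground truth for every strategy, an exact-seed read
    mapper, reciprocal-best-hit protein clustering and genome grouping,
    replicate-assembly average nucleotide identity, prophage screening
    against host genomes, and collection-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
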