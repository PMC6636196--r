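Package: mhciscan
Title: Mining, Classification and Regional Mapping of MHC Class I Genes in
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing the major
    histocompatibility complex (MHC) class I gene repertoire of a genome
    assembly. Provides a self-contained six-frame translated homology search
    (seed-and-extend with Karlin-Altschul statistics), frameshift-aware codon
    alignment for discriminating putatively functional genes from pseudogenes,
    localization of the canonical MHC class I region via its six framework
    marker genes and assignment of class I loci to the alpha, kappa and beta
    duplication blocks, detection of lineage-specific in-frame insertions in
    the alpha-1 peptide-binding domain, MaxChi and window-distance
    recombination screening with a consensus exclusion rule, and
    NeighborNet split networks from Jukes-Cantor distances with bootstrap
    edge support. Includes a synthetic-genome simulator that plants class I
    genes, pseudogenes, partial genes, insertion alleles and recombinants
    with a machine-readable truth set for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    pracma,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
SystemRequirements: MAFFT (for alpha-1 profile alignment)
Config/testthat/edition: 3
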