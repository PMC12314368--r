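Package: nsrscan
Title: Non-Syntenic Region Detection in Haplotype-Phased Genome Assemblies
Version: 0.1.0
Authors@R: person("Genome", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares the two haplotypes of a phased diploid genome assembly
    (or two closely related genomes) at the gene level. Detects collinear
    blocks from protein homology and gene order with an MCScanX-style
    chaining algorithm, estimates Ka/Ks for gene pairs by the Nei-Gojobori
    (1986) method on protein-guided codon alignments, and calls non-syntenic
    regions (nSRs) with a sliding-window scan over homolog density. Further
    utilities classify tandem gene duplications and species-specific tandem
    duplicates from orthogroups, test feature enrichment or depletion inside
    nSRs with exact hypergeometric tails and Benjamini-Hochberg adjustment,
    contrast expression-profile correlations of gene pairs by region, detect
    telomere arrays and assembly gaps for reference/alternate haplotype
    assignment, and forward-simulate haplotype pairs diverging by
    transposon-mediated unequal crossing over to provide ground-truth data
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
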