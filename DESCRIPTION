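Package: g4scope
Title: Discovery, Evolutionary Conservation and Feature Association of
    G-Quadruplex DNA Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of G-quadruplex (G4) DNA motifs: a
    loop-length-constrained scanner for runs of four or more G-tracts, merging
    and filtering of motif calls (telomeres, mitochondria, rDNA repeat
    collapsing), motif-level cross-species conservation calling in alignment
    blocks with an empirical null based on evolving aligned sequence under an
    estimated nucleotide substitution matrix, nucleotide-level conservation
    statistics contrasting structure-disruptive and non-disruptive G-tract
    positions, and permutation tests for association of motifs with genome
    features using chromosome- and length-matched random region sets with FDR
    control. Includes a synthetic-data generator producing genomes, pairwise
    alignments, conservation tracks and feature sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Software, SequenceMatching, Genetics, ComparativeGenomics,
    MotifDiscovery
Config/testthat/edition: 3
RoxygenNote: 7.3.3
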