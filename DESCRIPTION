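Package: felTCR
Title: Single-Cell T-Cell Receptor Repertoire Analysis for the Domestic Cat
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell V(D)J repertoire analysis of feline T
    cells. Reads 10x Genomics contig annotation tables and AIRR
    rearrangement files, applies productive-contig and chimera filters,
    classifies cells by their combination of expressed TCR loci (TRA, TRB,
    TRG, TRD), defines amino-acid junction clonotypes, and computes gene
    usage, junctional-length spectra, position weight matrices and
    cross-chain pairing diversity. Builds per-locus clonotype similarity
    networks (Hamming-distance-one edges), quantifies clonotype sharing
    across subjects, and detects invariant public gamma-delta clones with
    exclusive V-gene pairing. Includes a cross-species ortholog
    gene-symbol mapper with a priority-ordered tie-break over homology
    quality fields, and a synthetic repertoire generator with spike-in
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, ImmunoOncology, Sequencing
RoxygenNote: 7.3.3
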