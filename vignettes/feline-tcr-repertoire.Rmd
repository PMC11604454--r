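---
title: "Methods: single-cell TCR repertoire analysis in the cat"
author: "felTCR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell TCR repertoire analysis in the cat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felTCR)
```

# The analysis and its assumptions

`felTCR` analyses single-cell V(D)J data from the four T-cell receptor
loci — TRA, TRB, TRG, TRD — in the domestic cat. The input is an annotated
contig table (one row per assembled receptor transcript, with gene calls,
junction sequences and productivity flags) plus a per-cell metadata table
carrying the subject id and a T-cell subset label derived from an upstream
transcriptome clustering. The package treats those labels as given: it
never infers phenotype from expression, and conversely it defines lineage
from the receptor when the two disagree.

Three assumptions run through the design:

1. **Cells are identified by (subject, barcode).** The subjects were
   sequenced as separate 10x libraries, and 16-mer droplet barcodes
   collide freely across libraries, so a barcode alone is not a cell.
2. **A contig is trustworthy only if it is productive and complete.**
   Following standard practice for 10x V(D)J output we retain productive
   contigs whose V, J and C genes are all identified and share one locus
   prefix; anything else is an incomplete assembly or an inter-locus
   chimera. The D gene is deliberately not required — TRA and TRG
   rearrangements have none.
3. **A clonotype is a (locus, amino-acid junction) pair.** The junction is
   taken exactly as reported, including the conserved C...F/W anchors; no
   trimming or nucleotide-level identity is used. Keying by locus keeps a
   TRA junction and an identical TRB junction distinct, which is what
   per-locus sharing counts require.

# Filtering

`filterContigs()` applies its rules in a fixed order and logs the removal
count of each: cell/confidence pre-filter, non-productive, missing V/J/C,
undetermined locus, inter-locus chimera. The ordering matters only for
attribution (a non-productive chimera is counted as non-productive); the
retained set is order-independent, the filter is idempotent, and
`retained + sum(removed)` always reconstructs the input count. The
`is_cell`/`high_confidence` pre-filter defaults to on because raw 10x
files contain contigs from non-cell barcodes; both switches are exposed
since upstream pipelines differ in whether they already applied them.

Hybrid TRA/TRD gene names are resolved by trusting the chain column of the
annotation; a contig whose gene prefixes disagree with its chain is
removed as a chimera rather than reassigned.

# Chain-combination profiles

`profileCells()` labels each cell by the set of loci with at least one
retained contig, written in the fixed order TRA/TRB/TRG/TRD (a display
alias maps e.g. `TRB/TRG/TRD` to the conventional gamma-first
`TRG/TRD/TRB`). The denominator for `chainComboFrequencies()` is the
number of cells of the subset **with at least one retained contig** —
cells that lost every contig to filtering are not silently mixed in. Cells
with more than two contigs of one locus are flagged `multi_chain` but kept:
doublet removal belongs to the upstream transcriptome QC, and flagging
preserves the audit trail without double-filtering.

`selectSinglePairCells()` implements the receptor-based definition of a
γδ T cell: exactly one productive TRD and one productive TRG contig.
Contigs of other loci do **not** exclude a cell by default, because the
interesting biology is precisely the cells whose transcriptome says
"αβ effector" while their receptor says γδ; a strict flag
(`exclude_other_loci = TRUE`) is available. Concordance percentages are
reported to one decimal.

# Repertoire statistics

Gene usage and V/J combination tables are straightforward per-group
percentages over contigs of one locus. Position weight matrices require
equal-length sequences, so `buildPWM()` restricts to the modal junction
length and reports how many sequences were excluded; a modal-length tie is
broken toward the shorter length and flagged in the `length_tie`
attribute. Columns are normalised to sum to 1 over the 20 standard amino
acids.

`crossChainPairing()` pairs the V/J keys of two loci per cell. Cells with
multiple contigs of one locus contribute **all** their pairings (each
distinct pairing once per cell) and are counted in the `n_multi_chain`
attribute; selecting only the top-UMI chain is a reasonable alternative,
but with no stated selection rule the all-pairings convention is the one
that loses no information and stays deterministic.

Edit distances are unit-cost Levenshtein (computed via `utils::adist`);
they quantify how far divergent junctions sit from a consensus.

# Clonal networks

`buildNetwork()` connects clonotypes of identical junction length at
Hamming distance exactly 1. Edges are junction-only — V/J-agnostic — and
may join clonotypes from different subjects and subsets. Neighbour finding
masks one position at a time and buckets the remainder, which is
O(n·L) and, on ≤ 100 nodes, provably identical to the all-pairs oracle the
test suite carries. Clusters are connected components with ≥ 2 nodes;
singletons keep an `NA` cluster id. Cluster ids are deterministic:
components ranked by size (descending), ties by lexicographically smallest
junction.

For cluster characterisation, *mean centrality* is the mean **raw** node
degree. Degree centrality normalised by (n − 1) averages to exactly the
graph density, which would make the two reported axes algebraically
redundant; raw mean degree keeps size information in one axis and
connectedness in the other. Density is 2E / (n(n − 1)).

Publicity (`sharedClonotypes()`) counts the subjects carrying a clonotype;
it is reported per locus with `min_subjects = 2` as the sharing threshold,
and can never exceed the number of subjects in the input. No statistical
null for sharing is attempted — the counts themselves are the deliverable.

# Invariant clone detection

`trdTrgPairingMap()` crosses the TRD V gene with the TRG V gene over
single-pair cells, carrying phenotype counts, subject sets, and the J
genes each side rearranged to. J-gene restriction is *reported* (as a set
and as Shannon entropy), not enforced, so a claim like "this V gene
rearranges to a single J" is checkable from the output.
`detectExclusivePairings()` requires mutual exclusivity — each V gene has
exactly one partner — with a `min_cells` default of 5 so that singleton
strata cannot declare exclusivity; a one-sided variant is available.
Consensus junctions are plurality winners with lexicographic, flagged tie
breaks, and divergent junctions are listed with their edit distance to the
consensus.

# Ortholog symbol mapping

The cat reference annotation leaves many genes without symbols, so
cross-species work renames cat ENSEMBL ids to human symbols. One-to-one
orthologs map directly. Contested cases are resolved by comparing records
lexicographically over five homology-quality fields in a fixed order
(orthology confidence, gene-order conservation, whole-genome alignment
score, % query identical to target, % target identical to query): the
first field that differs decides, absent values rank below any present
value, and a full tie breaks on the source gene id so resolution is
deterministic and independent of input row order. Whether "choosing a
representative gene" means one winner per contested human symbol or one
target per multi-target source gene is genuinely ambiguous; both are
implemented, with per-symbol as the default since it guarantees symbol
uniqueness before uniquification. Collisions are suffixed `.1`, `.2`
(count-matrix feature names must be unique), and manual overrides
(`rename:`, `drop`, `keep`) are applied after the automatic map. The
headline mapped-symbol count of any given study depends on the BioMart
release and its manual override list, so it is a diagnostic here, not a
test assertion.

# The synthetic repertoire generator

`felinePreset()` encodes the study conditions the package is tested
against: four subjects; per-subset chain-combination probabilities
(CD8+ cytotoxic cells co-express TRG in 60.6% of cells; γδ-labelled cells
split 49.7% TRG/TRD, 16.4% TRG/TRD + TRB, 11.5% TRA/TRB/TRG); V/J pools
with the dominant genes weighted up (TRAV23, TRAV25, TRAV8-6, TRBV25,
TRBV4-2, TRGV2-2/TRGJ2-2); junction lengths per locus with the TRG length
skew toward 16 aa in the cytotoxic subset; and the invariant public clone
spike-in (TRDV4/TRDJ3 with CASDIGGSSWDTRQMFF, TRGV5-3/TRGJ5-1 with
CACWDESGWIKIF, 19 cells across 5/5/5/4 subjects, 16/19 exact TRG with two
position-6 substitutions and one histidine insertion, 18/19 labelled
CD4+ TEM). The γδ remainder (22.4%) is not broken down in the source
conditions; it is assigned once as 12.4% TRA/TRB plus 10% single-chain TRG
— single-chain dropout is a routine feature of 5' V(D)J libraries — and
not revisited. Default noise rates (5% non-productive, 2% missing C, 1%
chimera contigs, each appended to an existing cell and violating exactly
one filter rule) are typical magnitudes for 10x V(D)J annotation output.

What the generator does *not* emulate: UMI-level sequencing error,
allelically included multi-chain cells beyond the noise model, ambient
RNA, nucleotide-level convergent recombination (junction nucleotides are
random), or any transcriptome counts. Passing tests on generator output
therefore demonstrates the correctness of the bookkeeping and statistics,
not robustness to every artefact of real data.

Reproducibility: `generateRepertoire()` seeds R's RNG from the config and
uses integer-based sampling only, so a fixed seed yields byte-identical
output; spike-ins record their exact injections in a manifest that
recovery tests compare against.

# Problem sizes and numerical choices

The test suite and the acceptance script simulate 2000 cells per subset of
interest (500 per subject) for stochastic recovery checks — large enough
that three binomial standard errors are ≈ 3 percentage points at p ≈ 0.5 —
and keep exact worked examples at their natural sizes (154-cell cohort,
19-cell invariant stratum, 113-cell pairing fixture). Percentages are
reported unrounded except where a one-decimal display convention is
stated (lineage concordance). PWM columns sum to 1 within 1e-9. All
tie-breaks (cluster ids, consensus junctions, resolver) are lexicographic
and documented where they occur.

# Known limitations

* Junction-only network edges conflate convergent junctions that arise
  from different V/J contexts; that is the stated definition, but V/J-aware
  variants would be a natural extension.
* The concordance analysis inherits whatever label noise the upstream
  clustering produced; the package can flag disagreement but not arbitrate
  it beyond the receptor-based definition.
* The ortholog resolver assumes the homology export is internally
  consistent; it validates ranges and classes but does not detect stale
  symbols.
* No plotting is bundled; all outputs are plain tables designed to feed
  ggplot2/circlize-style figures directly.
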