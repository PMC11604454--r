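# felTCR

Single-cell T-cell receptor (TCR) V(D)J repertoire analysis for the
domestic cat (*Felis catus*).

Feline immunology lacks the reagent toolbox available for mouse and human,
so 5' single-cell RNA-seq with V(D)J enrichment is one of the few ways to
resolve feline T-cell subsets and their receptors. `felTCR` provides the
repertoire half of such a study: it consumes CellRanger-style contig
annotation tables (or AIRR Rearrangement TSVs) plus per-cell subset labels
produced by an upstream transcriptome clustering, and answers questions
like: which combinations of the four TCR loci (TRA, TRB, TRG, TRD) does
each subset transcribe? Which V/J genes and junctional motifs dominate?
Which clonotypes are public across animals, and do any γδ populations carry
an invariant receptor?

## What it computes

* **Contig QC** — retains productive contigs whose V, J and C genes are all
  identified and belong to the same locus, excluding incomplete contigs and
  inter-locus chimeras, with a per-rule removal log.
* **Chain-combination profiles** — each cell is labelled by the set of loci
  with retained productive contigs (e.g. `TRA/TRB/TRG`), and frequencies
  are tabulated per transcriptome subset.
* **Clonotypes** — a clonotype is a unique amino-acid junction (CDR3)
  sequence at one locus; cells sharing it are presumed clonally related.
  Per-locus V/J usage, junctional-length spectra, position weight matrices
  (PWMs) over modal-length junctions, and per-cell TRA×TRB V/J pairing
  tables quantify repertoire focusing.
* **Clonal networks** — per-locus graphs whose nodes are clonotypes and
  whose edges join equal-length junctions at Hamming distance 1. Connected
  components of ≥ 2 nodes are clusters, characterised by mean degree
  ("mean centrality") and density 2E / (n(n−1)). Clonotype sharing across
  subjects ("publicity") is counted per locus.
* **Invariant clone detection** — among cells with a single productive TRD
  and TRG rearrangement each, V-gene pairing strata are crossed with the
  transcriptome phenotype; mutually exclusive V–V pairings are flagged and
  characterised (consensus junctions, exact-match counts, subject coverage,
  J-gene entropy).
* **Ortholog symbol mapping** — cat ENSEMBL ids are renamed to human
  symbols: one-to-one orthologs map directly, one-to-many/many-to-many are
  resolved by a lexicographic comparison over
  `[orthology_confidence, gene_order_confidence, whole_genome_alignment,
  %query_identical_target, %target_identical_query]`, with manual
  overrides and collision uniquification.
* **Synthetic repertoires** — a generator with a bundled feline preset
  (per-subset chain co-expression probabilities, skewed V/J pools,
  restricted junction lengths, an invariant public γδ spike-in, and
  configurable noise) provides ground-truth data for every stage.

## Worked example

```r
library(felTCR)

## simulate four cats under the feline preset and run the pipeline
sim <- generateRepertoire(felinePreset(seed = 7L))
cs  <- attachMetadata(filterContigs(sim$contigs), sim$annotations)
cs
#> ContigSet with 6362 contigs
#>   loci: TRA=2755 TRB=2795 TRG=574 TRD=238
#>   cells: 3139  subjects: 4
#>   filtered: not_cell=0 low_confidence=0 non_productive=316
#>             missing_vjc=126 undetermined_locus=0 interlocus_chimera=63

freq <- chainComboFrequencies(profileCells(cs))
subset(freq, subset_label == "CD8+ cytotoxic")
#>      subset_label combo_label count percent
#> 10 CD8+ cytotoxic TRA/TRB/TRG   191 59.6875
#> 11 CD8+ cytotoxic     TRA/TRB    96 30.0000
#> 12 CD8+ cytotoxic         TRB    17  5.3125
#> 13 CD8+ cytotoxic         TRA    16  5.0000
```

Most CD8+ cytotoxic cells co-transcribe a TRG chain on top of their
TRA/TRB receptor — the hallmark this preset encodes. Defining γδ T cells
by their receptor (one productive TRD and TRG each) and crossing V-gene
pairing with phenotype recovers the planted invariant clone:

```r
cells  <- selectSinglePairCells(profileCells(cs), c("TRD", "TRG"))
strata <- trdTrgPairingMap(cells, cs)
detectExclusivePairings(strata, min_cells = 5)
#>   trd_v   trg_v cell_count
#> 1 TRDV4 TRGV5-3         19

inv <- invariantCloneReport(cells[cells$barcode %in%
         sim$manifest$spikes$invariant_gd$barcodes, ], cs, total_subjects = 4)
inv
#> Invariant clone report
#>   TRD: TRDV4 / TRDJ3  consensus CASDIGGSSWDTRQMFF (19/19 exact)
#>   TRG: TRGV5-3 / TRGJ5-1  consensus CACWDESGWIKIF (16/19 exact)
#>   subjects: 4 (coverage 1.00)  dominant phenotype: CD4+ TEM (94.7%)
#>   divergent junctions:
#>   locus    junction_aa n_cells dist_to_consensus
#> 1   TRG  CACWDGSGWIKIF       1                 1
#> 2   TRG CACWDHESGWIKIF       1                 1
#> 3   TRG  CACWDKSGWIKIF       1                 1

head(sharedClonotypes(defineClonotypes(cs)), 3)
#>   locus       junction_aa n_subjects            subjects cell_count
#> 1   TRD CASDIGGSSWDTRQMFF          4 cat1,cat2,cat3,cat4         19
#> 2   TRG     CACWDESGWIKIF          4 cat1,cat2,cat3,cat4         16
```

The invariant TRD and TRG junctions are public across all four animals
while carrying a CD4+ TEM-like transcriptome label — exactly the situation
in which receptor-level analysis corrects a transcriptome-only lineage
call.

## Scope

The package starts from annotated contig tables; contig assembly and IMGT
alignment (CellRanger's job), transcriptome clustering, doublet removal
and cross-species integration are upstream and out of scope. The subset
labels those analyses produce are consumed here as plain metadata.
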