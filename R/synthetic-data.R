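## Synthetic multi-subject V(D)J repertoire generator with spike-in ground
## truth, plus homology-table fixtures for the ortholog mapper.

#' @rdname felinePreset
#' @format NULL
#' @export
GD_LABEL <- "\u03b3\u03b4 T cell"

.DNA <- c("A", "C", "G", "T")

#' The feline repertoire preset
#'
#' A [RepertoireConfig] describing four subjects with the per-subset chain
#' co-expression frequencies, skewed V/J usage, restricted junctional
#' lengths and the public invariant TRDV4/TRGV5-3 clone observed in feline
#' peripheral blood. The stated frequencies are the study conditions this
#' generator emulates: 60.6\% of CD8+ cytotoxic cells co-express
#' TRA/TRB/TRG; gamma-delta-labelled cells split 49.7\% TRG/TRD, 16.4\%
#' TRG/TRD+TRB, 11.5\% TRA/TRB/TRG, with the remaining 22.4\% split between
#' TRA/TRB (12.4\%) and single-chain TRG dropout (10\%). The invariant
#' clone spike-in carries the 17-aa TRD junction CASDIGGSSWDTRQMFF
#' (TRDV4/TRDJ3) and the 13-aa TRG junction CACWDESGWIKIF (TRGV5-3/TRGJ5-1)
#' in all four subjects, with 16/19 cells exact for TRG and three
#' near-variants, 18/19 cells labelled CD4+ TEM.
#'
#' @param subjects subject identifiers (default four cats).
#' @param cells_per_subset named integer: cells per subset per subject.
#' @param noise noise rates as fractions of the productive contig count:
#'   \code{non_productive}, \code{missing_c}, \code{chimera}.
#' @param include_spikes include the invariant public clone spike-in.
#' @param seed RNG seed stored in the config.
#' @return A list of class \code{"RepertoireConfig"}.
#' @export
felinePreset <- function(subjects = paste0("cat", 1:4),
                         cells_per_subset = c(
                           "CD4+ naive" = 300L, "CD8+ naive" = 200L,
                           "CD4+ TEM" = 120L, "CD8+ cytotoxic" = 80L,
                           "\u03b3\u03b4 T cell" = 80L),
                         noise = c(non_productive = 0.05, missing_c = 0.02,
                                   chimera = 0.01),
                         include_spikes = TRUE,
                         seed = 20240101L) {
  ab_probs <- c("TRA/TRB" = 0.88, "TRA" = 0.05, "TRB" = 0.04,
                "TRA/TRB/TRG" = 0.03)
  cfg <- list(
    subjects = subjects,
    cells_per_subset = cells_per_subset,
    combo_probs = list(
      "CD4+ naive" = ab_probs,
      "CD8+ naive" = ab_probs,
      "CD4+ TEM" = ab_probs,
      ## CD8+ cytotoxic cells additionally transcribe TRG in 60.6% of cells
      "CD8+ cytotoxic" = c("TRA/TRB/TRG" = 0.606, "TRA/TRB" = 0.30,
                           "TRA" = 0.05, "TRB" = 0.044),
      ## gamma-delta-labelled cells: stated splits 49.7/16.4/11.5; the
      ## unreported remainder is assigned to TRA/TRB cells and TRG dropout
      "\u03b3\u03b4 T cell" = c("TRG/TRD" = 0.497, "TRB/TRG/TRD" = 0.164,
                           "TRA/TRB/TRG" = 0.115, "TRA/TRB" = 0.124,
                           "TRG" = 0.10)
    ),
    gene_pools = list(
      TRA = list(
        V = c("TRAV23" = 4, "TRAV25" = 3, "TRAV8-6" = 3, "TRAV12-1" = 2,
              "TRAV19" = 2, "TRAV38-1" = 1, "TRAV4" = 1),
        J = c("TRAJ25" = 3, "TRAJ41" = 3, "TRAJ30" = 2, "TRAJ43" = 2,
              "TRAJ33" = 1, "TRAJ49" = 1),
        C = c("TRAC" = 1)),
      TRB = list(
        V = c("TRBV25" = 4, "TRBV4-2" = 3, "TRBV28" = 2, "TRBV20-1" = 2,
              "TRBV5-1" = 1, "TRBV11-2" = 1),
        J = c("TRBJ2-6" = 4, "TRBJ1-2" = 2, "TRBJ2-1" = 2, "TRBJ1-5" = 1),
        C = c("TRBC2" = 2, "TRBC1" = 1)),
      TRG = list(
        ## TRGV2-2/TRGJ2-2 dominates the gamma repertoire
        V = c("TRGV2-2" = 6, "TRGV2-1" = 2, "TRGV2-4" = 2),
        J = c("TRGJ2-2" = 6, "TRGJ1-1" = 2, "TRGJ2-1" = 1),
        C = c("TRGC1" = 1)),
      TRD = list(
        V = c("TRDV3" = 3, "TRDV5-1" = 2, "TRDV5-2" = 2, "TRDV5-3" = 2),
        J = c("TRDJ1" = 3, "TRDJ2" = 2, "TRDJ4" = 1),
        C = c("TRDC" = 1))
    ),
    junction_lengths = list(
      TRA = c("11" = 1, "12" = 2, "13" = 3, "14" = 3, "15" = 2, "16" = 1),
      TRB = c("12" = 1, "13" = 2, "14" = 3, "15" = 2, "16" = 1),
      ## TRG junctions skew to 16 aa in the TRG-expressing cytotoxic subset
      TRG = c("13" = 2, "14" = 2, "15" = 2, "16" = 4, "17" = 1),
      TRD = c("14" = 1, "15" = 2, "16" = 3, "17" = 3, "18" = 2, "19" = 1)
    ),
    junction_length_overrides = list(
      "CD8+ cytotoxic" = list(TRG = c("16" = 8, "15" = 1, "17" = 1))
    ),
    noise = noise,
    spike_ins = if (include_spikes) list(invariantGdCloneSpec()) else list(),
    seed = as.integer(seed)
  )
  class(cfg) <- "RepertoireConfig"
  validateRepertoireConfig(cfg)
  cfg
}

#' The invariant public gamma-delta clone spike-in specification
#'
#' 19 cells across four subjects (5/5/5/4) with TRDV4/TRDJ3 and
#' TRGV5-3/TRGJ5-1 rearrangements: all 19 share the TRD junction
#' CASDIGGSSWDTRQMFF; 16 share the TRG junction CACWDESGWIKIF, two carry a
#' single substitution at position 6 and one carries an extra histidine
#' inserted after position 5 (CACWDHESGWIKIF). 18 cells are labelled
#' CD4+ TEM and one gamma-delta.
#'
#' @return A spike-in specification list for [spikePublicClone()].
#' @export
invariantGdCloneSpec <- function() {
  trg <- c(rep("CACWDESGWIKIF", 16L),
           "CACWDGSGWIKIF", "CACWDKSGWIKIF",  # position-6 substitutions
           "CACWDHESGWIKIF")                  # histidine insertion
  list(
    name = "invariant_gd",
    subject_counts = c(cat1 = 5L, cat2 = 5L, cat3 = 5L, cat4 = 4L),
    labels = c(rep("CD4+ TEM", 18L), GD_LABEL),
    chains = list(
      list(locus = "TRD", v_gene = "TRDV4", d_gene = "TRDD3",
           j_gene = "TRDJ3", c_gene = "TRDC",
           junctions = "CASDIGGSSWDTRQMFF"),
      list(locus = "TRG", v_gene = "TRGV5-3", d_gene = NA_character_,
           j_gene = "TRGJ5-1", c_gene = "TRGC1",
           junctions = trg)
    )
  )
}

#' Validate a repertoire configuration
#'
#' @param cfg A \code{RepertoireConfig} list.
#' @return \code{cfg}, invisibly; errors on the first violated constraint.
#' @export
validateRepertoireConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  need <- c("subjects", "cells_per_subset", "combo_probs", "gene_pools",
            "junction_lengths", "noise", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    stop("config lacks field(s): ", paste(missing, collapse = ", "))
  }
  if (any(cfg$cells_per_subset < 0L)) stop("cell counts must be >= 0")
  extra <- setdiff(names(cfg$cells_per_subset), names(cfg$combo_probs))
  if (length(extra) > 0L) {
    stop("no combination probabilities for subset(s): ",
         paste(extra, collapse = ", "))
  }
  for (subset in names(cfg$combo_probs)) {
    p <- cfg$combo_probs[[subset]]
    if (any(p < 0 | p > 1) || sum(p) > 1 + 1e-9) {
      stop("combination probabilities for '", subset,
           "' must lie in [0,1] and sum to <= 1")
    }
    for (combo in names(p)) {
      loci <- strsplit(combo, "/", fixed = TRUE)[[1L]]
      if (!all(loci %in% TR_LOCI) || is.unsorted(match(loci, TR_LOCI))) {
        stop("combo label '", combo, "' is not canonical (TRA/TRB/TRG/TRD order)")
      }
    }
  }
  if (any(cfg$noise < 0 | cfg$noise > 1)) stop("noise rates must lie in [0,1]")
  if (!all(TR_LOCI %in% names(cfg$gene_pools))) stop("gene pool missing a locus")
  if (!all(TR_LOCI %in% names(cfg$junction_lengths))) {
    stop("junction length distribution missing a locus")
  }
  invisible(cfg)
}

.randomBarcodes <- function(n, avoid = character()) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    fresh <- vapply(seq_len(need * 2L), function(i)
      paste(sample(.DNA, 16L, replace = TRUE), collapse = ""), character(1L))
    fresh <- setdiff(unique(fresh), c(avoid, out))
    out <- c(out, head(fresh, need))
  }
  paste0(out, "-1")
}

.sampleWeighted <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

.randomJunction <- function(len) {
  paste0("C", paste(sample(AA_STANDARD, len - 2L, replace = TRUE),
                    collapse = ""), "F")
}

.randomNt <- function(len_aa) {
  paste(sample(.DNA, 3L * len_aa, replace = TRUE), collapse = "")
}

.makeContig <- function(subject, barcode, id, locus, pools, len_weights,
                        productive = TRUE, c_gene = NULL) {
  len <- as.integer(.sampleWeighted(1L, len_weights))
  data.frame(
    contig_id = id, barcode = barcode, subject_id = subject, locus = locus,
    v_gene = .sampleWeighted(1L, pools[[locus]]$V),
    d_gene = NA_character_,
    j_gene = .sampleWeighted(1L, pools[[locus]]$J),
    c_gene = if (is.null(c_gene)) .sampleWeighted(1L, pools[[locus]]$C) else c_gene,
    junction_aa = .randomJunction(len),
    junction_nt = .randomNt(len),
    productive = productive, is_cell = TRUE, high_confidence = TRUE,
    umis = rpois(1L, 3L) + 1L,
    stringsAsFactors = FALSE
  )
}

#' Generate a multi-subject synthetic V(D)J repertoire
#'
#' Draws, per subject and subset, the configured number of cells; each
#' cell's chain combination is sampled from the subset's probabilities and
#' one productive contig is emitted per expressed locus, with V/J/C genes
#' drawn from the weighted pools and junctions sampled as C + random
#' residues + F at the configured lengths. Noise contigs (non-productive,
#' missing C gene, inter-locus chimera) are appended to random cells at the
#' configured rates, each violating exactly one filter rule, and their
#' counts recorded in the manifest. Spike-in clones from the config are
#' injected last. Fully reproducible for a fixed config seed.
#'
#' @param cfg A \code{RepertoireConfig}, e.g. from [felinePreset()].
#' @return list with \code{contigs} (a [ContigSet-class]),
#'   \code{annotations} (barcode/subject_id/subset_label data.frame) and
#'   \code{manifest} (noise counts and spike-in ground truth).
#' @export
generateRepertoire <- function(cfg) {
  validateRepertoireConfig(cfg)
  set.seed(cfg$seed)
  contig_rows <- list()
  ann_rows <- list()
  for (subject in cfg$subjects) {
    n_cells <- sum(cfg$cells_per_subset)
    barcodes <- .randomBarcodes(n_cells)
    bc_i <- 0L
    for (subset in names(cfg$cells_per_subset)) {
      n <- cfg$cells_per_subset[[subset]]
      if (n == 0L) next
      probs <- cfg$combo_probs[[subset]]
      combos <- sample(names(probs), n, replace = TRUE, prob = probs)
      for (ci in seq_len(n)) {
        bc_i <- bc_i + 1L
        bc <- barcodes[bc_i]
        loci <- strsplit(combos[ci], "/", fixed = TRUE)[[1L]]
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          barcode = bc, subject_id = subject, subset_label = subset,
          stringsAsFactors = FALSE)
        for (k in seq_along(loci)) {
          locus <- loci[k]
          lw <- cfg$junction_lengths[[locus]]
          ov <- cfg$junction_length_overrides[[subset]]
          if (!is.null(ov) && !is.null(ov[[locus]])) lw <- ov[[locus]]
          contig_rows[[length(contig_rows) + 1L]] <- .makeContig(
            subject, bc, paste0(bc, "_contig_", k), locus,
            cfg$gene_pools, lw)
        }
      }
    }
  }
  contig_df <- do.call(rbind, contig_rows)
  ann <- do.call(rbind, ann_rows)
  ## noise contigs: extra contigs on existing cells, one rule violated each
  n_real <- nrow(contig_df)
  noise_counts <- vapply(cfg$noise, function(r) as.integer(round(r * n_real)),
                         integer(1L))
  noise_rows <- list()
  add_noise <- function(type, n) {
    if (n == 0L) return(invisible(NULL))
    pick <- sample.int(nrow(ann), n, replace = TRUE)
    for (i in seq_len(n)) {
      subject <- ann$subject_id[pick[i]]
      bc <- ann$barcode[pick[i]]
      locus <- sample(TR_LOCI, 1L)
      id <- paste0(bc, "_noise_", type, "_", i)
      row <- switch(type,
        non_productive = .makeContig(subject, bc, id, locus, cfg$gene_pools,
                                     cfg$junction_lengths[[locus]],
                                     productive = FALSE),
        missing_c = .makeContig(subject, bc, id, locus, cfg$gene_pools,
                                cfg$junction_lengths[[locus]],
                                c_gene = NA_character_),
        chimera = {
          other <- sample(setdiff(TR_LOCI, locus), 1L)
          .makeContig(subject, bc, id, locus, cfg$gene_pools,
                      cfg$junction_lengths[[locus]],
                      c_gene = names(cfg$gene_pools[[other]]$C)[1L])
        })
      noise_rows[[length(noise_rows) + 1L]] <<- row
    }
  }
  add_noise("non_productive", noise_counts[["non_productive"]])
  add_noise("missing_c", noise_counts[["missing_c"]])
  add_noise("chimera", noise_counts[["chimera"]])
  if (length(noise_rows) > 0L) {
    contig_df <- rbind(contig_df, do.call(rbind, noise_rows))
  }
  cs <- ContigSet(contig_df, sources = "synthetic repertoire generator")
  result <- list(contigs = cs, annotations = ann,
                 manifest = list(noise = as.list(noise_counts),
                                 spikes = list()))
  for (spec in cfg$spike_ins) {
    result <- spikePublicClone(result$contigs, result$annotations, spec,
                               manifest = result$manifest)
  }
  result
}

#' Inject a public clone into a synthetic repertoire
#'
#' Appends cells carrying a defined clone (fixed V/D/J/C genes and junction
#' sequences per chain) to the named subjects, with fresh barcodes, and
#' records exactly what was injected in the manifest -- the ground truth for
#' recovery tests. Junctions may be given per chain as a single sequence or
#' as a per-cell vector (e.g. to plant near-variants of a consensus).
#'
#' @param cs A [ContigSet-class] to extend.
#' @param ann the matching cell-annotation data.frame.
#' @param spec spike specification: \code{name}, \code{subject_counts}
#'   (named integer), \code{labels} (length = total cells), \code{chains}
#'   (list of locus/v_gene/d_gene/j_gene/c_gene/junctions).
#' @param manifest manifest list to append to (default fresh).
#' @return list with updated \code{contigs}, \code{annotations},
#'   \code{manifest}.
#' @export
spikePublicClone <- function(cs, ann, spec,
                             manifest = list(noise = list(), spikes = list())) {
  stopifnot(is(cs, "ContigSet"), is.data.frame(ann))
  total <- sum(spec$subject_counts)
  if (total == 0L) {
    manifest$spikes[[spec$name]] <- list(spec = spec, barcodes = character())
    return(list(contigs = cs, annotations = ann, manifest = manifest))
  }
  unknown <- setdiff(names(spec$subject_counts)[spec$subject_counts > 0L],
                     unique(ann$subject_id))
  if (length(unknown) > 0L) {
    stop("spike-in subject(s) not in dataset: ", paste(unknown, collapse = ", "))
  }
  stopifnot(length(spec$labels) == total)
  df <- contigs(cs)
  new_contigs <- list()
  new_ann <- list()
  cell_i <- 0L
  for (subject in names(spec$subject_counts)) {
    n <- spec$subject_counts[[subject]]
    if (n == 0L) next
    existing <- ann$barcode[ann$subject_id == subject]
    bcs <- .randomBarcodes(n, avoid = sub("-1$", "", existing))
    for (i in seq_len(n)) {
      cell_i <- cell_i + 1L
      new_ann[[length(new_ann) + 1L]] <- data.frame(
        barcode = bcs[i], subject_id = subject,
        subset_label = spec$labels[cell_i], stringsAsFactors = FALSE)
      for (ch in spec$chains) {
        junc <- if (length(ch$junctions) == 1L) ch$junctions else ch$junctions[cell_i]
        new_contigs[[length(new_contigs) + 1L]] <- data.frame(
          contig_id = paste0(bcs[i], "_", spec$name, "_", ch$locus),
          barcode = bcs[i], subject_id = subject, locus = ch$locus,
          v_gene = ch$v_gene, d_gene = ch$d_gene, j_gene = ch$j_gene,
          c_gene = ch$c_gene, junction_aa = junc,
          junction_nt = .randomNt(nchar(junc)),
          productive = TRUE, is_cell = TRUE, high_confidence = TRUE,
          umis = rpois(1L, 3L) + 1L, subset_label = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- rbind(df, do.call(rbind, new_contigs))
  ann <- rbind(ann, do.call(rbind, new_ann))
  out_cs <- ContigSet(df, sources = c(provenance(cs)$sources,
                                      paste0("spike:", spec$name)))
  manifest$spikes[[spec$name]] <- list(
    spec = spec,
    barcodes = vapply(new_ann, function(a) a$barcode, character(1L)),
    subjects = vapply(new_ann, function(a) a$subject_id, character(1L))
  )
  list(contigs = out_cs, annotations = ann, manifest = manifest)
}

#' Single-substitution neighbours of a junction
#'
#' Samples \code{n_variants} distinct sequences, each differing from the
#' input at exactly one position (same length). The full neighbourhood has
#' \code{19 * nchar(junction_aa)} members.
#'
#' @param junction_aa the seed junction.
#' @param n_variants number of variants, at most \code{19 * length}.
#' @param seed optional RNG seed for reproducibility.
#' @return character vector of distinct variants.
#' @export
mutateJunctionNeighborhood <- function(junction_aa, n_variants, seed = NULL) {
  stopifnot(is.character(junction_aa), length(junction_aa) == 1L,
            nchar(junction_aa) >= 1L, n_variants >= 1L)
  L <- nchar(junction_aa)
  if (n_variants > 19L * L) {
    stop("n_variants exceeds the single-substitution neighbourhood size (",
         19L * L, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(junction_aa, "")[[1L]]
  ## enumerate the full neighbourhood, then sample without replacement
  all_variants <- unlist(lapply(seq_len(L), function(p) {
    vapply(setdiff(AA_STANDARD, chars[p]), function(aa) {
      v <- chars; v[p] <- aa; paste(v, collapse = "")
    }, character(1L))
  }))
  if (n_variants == length(all_variants)) return(unname(all_variants))
  unname(sample(all_variants, n_variants))
}

## Field-by-field record comparison used by the brute-force resolver:
## TRUE if record row a beats row b under the priority ordering.
.recordBeats <- function(records, a, b) {
  for (f in .PRIORITY_FIELDS) {
    va <- records[[f]][a]; vb <- records[[f]][b]
    if (is.na(va) && is.na(vb)) next
    if (is.na(vb)) return(TRUE)
    if (is.na(va)) return(FALSE)
    if (va > vb) return(TRUE)
    if (va < vb) return(FALSE)
  }
  records$source_gene_id[a] < records$source_gene_id[b]
}

## Independent brute-force symbol resolution (reference oracle for the
## fixture generator): explicit loops and pairwise comparisons.
.bruteResolveSymbols <- function(records, features) {
  entries <- character(0)
  in_feat <- records$source_gene_id %in% features
  for (sym in sort(unique(records$target_symbol))) {
    rows <- which(records$target_symbol == sym & in_feat)
    if (length(rows) == 0L) next
    o2o <- rows[records$homology_class[rows] == "one2one"]
    if (length(o2o) > 0L) {
      for (r in o2o) {
        src <- records$source_gene_id[r]
        if (!src %in% names(entries)) entries[src] <- sym
      }
      next
    }
    best <- rows[1L]
    for (r in rows[-1L]) if (.recordBeats(records, r, best)) best <- r
    src <- records$source_gene_id[best]
    if (!src %in% names(entries)) entries[src] <- sym
  }
  entries <- entries[order(names(entries))]
  if (length(entries) > 0L) {
    entries <- setNames(make.unique(unname(entries)), names(entries))
  }
  entries
}

#' Generate a homology-table fixture with its expected resolution
#'
#' Builds \code{n_one2one} one-to-one records plus \code{n_contested}
#' groups of 2-4 source genes competing for one target symbol, with random
#' (occasionally absent) homology-quality scores. The expected symbol map
#' is computed at generation time by an independent brute-force resolver,
#' so fixtures serve as ground truth for [resolveSymbols()].
#'
#' @param n_one2one number of one-to-one records.
#' @param n_contested number of contested symbol groups.
#' @param seed RNG seed.
#' @return list with \code{records} (data.frame), \code{features}
#'   (character) and \code{expected} (named character, the expected map).
#' @export
generateHomologyFixture <- function(n_one2one, n_contested, seed = 1L) {
  stopifnot(n_one2one >= 0L, n_contested >= 0L)
  set.seed(seed)
  rows <- list()
  src_i <- 0L
  next_src <- function() {
    src_i <<- src_i + 1L
    sprintf("ENSFCAG%011d", src_i)
  }
  rand_row <- function(src, tgt_i, sym, class) {
    data.frame(
      source_gene_id = src,
      target_gene_id = sprintf("ENSG%011d", tgt_i),
      target_symbol = sym,
      homology_class = class,
      orthology_confidence = sample(c(0, 1), 1L),
      gene_order_confidence = sample(c(NA, round(runif(1L, 0, 100), 1L)), 1L,
                                     prob = c(0.2, 0.8)),
      whole_genome_alignment = round(runif(1L, 0, 100), 1L),
      pct_query_identical_target = round(runif(1L, 0, 100), 1L),
      pct_target_identical_query = round(runif(1L, 0, 100), 1L),
      stringsAsFactors = FALSE
    )
  }
  tgt_i <- 0L
  for (i in seq_len(n_one2one)) {
    tgt_i <- tgt_i + 1L
    rows[[length(rows) + 1L]] <-
      rand_row(next_src(), tgt_i, sprintf("O2O%04d", i), "one2one")
  }
  for (g in seq_len(n_contested)) {
    tgt_i <- tgt_i + 1L
    k <- sample(2:4, 1L)
    class <- sample(c("one2many", "many2many"), 1L)
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <-
        rand_row(next_src(), tgt_i, sprintf("CON%04d", g), class)
    }
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(source_gene_id = character(), target_gene_id = character(),
               target_symbol = character(), homology_class = character(),
               orthology_confidence = numeric(),
               gene_order_confidence = numeric(),
               whole_genome_alignment = numeric(),
               pct_query_identical_target = numeric(),
               pct_target_identical_query = numeric())
  features <- records$source_gene_id
  list(records = records, features = features,
       expected = .bruteResolveSymbols(records, features))
}
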