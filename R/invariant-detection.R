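## TRD/TRG pairing strata, exclusive V-gene pairing detection, and
## invariant public clone characterisation.

.shannonEntropy <- function(x) {
  p <- table(x)
  p <- p / sum(p)
  -sum(p * log2(p))
}

## For each selected single-pair cell, extract its unique TRD and TRG
## contig rows (one each, by construction).
.pairContigs <- function(cells, cs, loci = c("TRD", "TRG")) {
  df <- contigs(cs)
  key <- .cellKey(df$subject_id, df$barcode)
  sel <- .cellKey(cells$subject_id, cells$barcode)
  a <- df[key %in% sel & df$locus == loci[1L], , drop = FALSE]
  b <- df[key %in% sel & df$locus == loci[2L], , drop = FALSE]
  a <- a[match(sel, .cellKey(a$subject_id, a$barcode)), , drop = FALSE]
  b <- b[match(sel, .cellKey(b$subject_id, b$barcode)), , drop = FALSE]
  list(a = a, b = b)
}

#' TRD/TRG V-gene pairing strata with phenotype breakdown
#'
#' For cells with a single productive TRD and TRG rearrangement each, builds
#' one stratum per observed (TRD V gene, TRG V gene) pair with its cell
#' count, the J genes each side rearranged to, the subjects carrying it and
#' the transcriptome-derived phenotype counts. The J-gene entropy per side
#' is reported so single-J restriction (e.g. TRDV4/TRDJ3, TRGV5-3/TRGJ5-1)
#' is checkable rather than enforced.
#'
#' @param cells selected cells, from
#'   \code{selectSinglePairCells(profiles, c("TRD","TRG"))}.
#' @param cs the filtered [ContigSet-class].
#' @return data.frame with one row per stratum: \code{trd_v}, \code{trg_v},
#'   \code{cell_count}, \code{trd_j}, \code{trg_j} (comma-separated sets),
#'   \code{trd_j_entropy}, \code{trg_j_entropy}, \code{n_subjects},
#'   \code{subjects}, and a list-column \code{phenotype_counts} of named
#'   integer vectors.
#' @export
trdTrgPairingMap <- function(cells, cs) {
  stopifnot(is.data.frame(cells), is(cs, "ContigSet"))
  if (nrow(cells) == 0L) {
    return(data.frame(trd_v = character(), trg_v = character(),
                      cell_count = integer()))
  }
  pc <- .pairContigs(cells, cs, c("TRD", "TRG"))
  strat_key <- paste(pc$a$v_gene, pc$b$v_gene, sep = "\r")
  idx <- split(seq_len(nrow(cells)), strat_key)
  collapse_set <- function(x) paste(sort(unique(x[!is.na(x)])), collapse = ",")
  lab <- cells$subset_label
  lab[is.na(lab)] <- "(unlabelled)"
  out <- data.frame(
    trd_v = vapply(idx, function(i) pc$a$v_gene[i[1L]], character(1L)),
    trg_v = vapply(idx, function(i) pc$b$v_gene[i[1L]], character(1L)),
    cell_count = lengths(idx),
    trd_j = vapply(idx, function(i) collapse_set(pc$a$j_gene[i]), character(1L)),
    trg_j = vapply(idx, function(i) collapse_set(pc$b$j_gene[i]), character(1L)),
    trd_j_entropy = vapply(idx, function(i) .shannonEntropy(pc$a$j_gene[i]), numeric(1L)),
    trg_j_entropy = vapply(idx, function(i) .shannonEntropy(pc$b$j_gene[i]), numeric(1L)),
    n_subjects = vapply(idx, function(i)
      length(unique(cells$subject_id[i])), integer(1L)),
    subjects = vapply(idx, function(i) collapse_set(cells$subject_id[i]), character(1L)),
    stringsAsFactors = FALSE
  )
  out$phenotype_counts <- lapply(idx, function(i) {
    tab <- table(lab[i])
    setNames(as.integer(tab), names(tab))
  })
  out <- out[order(-out$cell_count, out$trd_v, out$trg_v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect exclusive V-gene pairings
#'
#' A pairing (a, b) is exclusive when gene a occurs with no TRG partner
#' other than b AND gene b occurs with no TRD partner other than a (mutual
#' exclusivity), and the stratum carries at least \code{min_cells} cells.
#' With \code{one_sided = TRUE}, exclusivity of either side suffices.
#'
#' @param strata output of [trdTrgPairingMap()].
#' @param min_cells minimum stratum size; the default of 5 avoids calling
#'   exclusivity from singletons.
#' @param one_sided relax the mutual rule to one-sided exclusivity.
#' @return data.frame (trd_v, trg_v, cell_count) of exclusive pairings.
#' @export
detectExclusivePairings <- function(strata, min_cells = 5L, one_sided = FALSE) {
  stopifnot(is.data.frame(strata))
  if (nrow(strata) == 0L) {
    return(data.frame(trd_v = character(), trg_v = character(),
                      cell_count = integer()))
  }
  n_partners_a <- tapply(strata$trg_v, strata$trd_v,
                         function(x) length(unique(x)))
  n_partners_b <- tapply(strata$trd_v, strata$trg_v,
                         function(x) length(unique(x)))
  excl_a <- n_partners_a[strata$trd_v] == 1L
  excl_b <- n_partners_b[strata$trg_v] == 1L
  keep <- if (one_sided) excl_a | excl_b else excl_a & excl_b
  keep <- keep & strata$cell_count >= min_cells
  out <- strata[as.vector(keep), c("trd_v", "trg_v", "cell_count"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Characterise an invariant clone stratum
#'
#' For the cells of one pairing stratum, derives the consensus junction per
#' locus (plurality; ties broken lexicographically and flagged), the number
#' of cells carrying the consensus exactly, the divergent junctions with
#' their edit distance to the consensus, the subject coverage, and the
#' dominant transcriptome phenotype.
#'
#' @param cells the cells of one stratum (rows of the single-pair cell
#'   table restricted to the stratum of interest).
#' @param cs the filtered [ContigSet-class].
#' @param total_subjects total number of subjects in the study.
#' @return A list of class \code{"invariantCloneReport"}: per-locus V/J
#'   usage, consensus junctions, \code{n_cells}, \code{n_exact_trd},
#'   \code{n_exact_trg}, \code{subject_coverage}, \code{dominant_phenotype},
#'   \code{dominant_fraction}, and a \code{divergent} table (locus,
#'   junction_aa, n_cells, dist_to_consensus).
#' @export
invariantCloneReport <- function(cells, cs, total_subjects) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0L, is(cs, "ContigSet"),
            total_subjects >= 1L)
  pc <- .pairContigs(cells, cs, c("TRD", "TRG"))
  consensus_of <- function(junc) {
    tab <- table(junc)
    winners <- names(tab)[tab == max(tab)]
    list(consensus = sort(winners)[1L], tie = length(winners) > 1L)
  }
  ctrd <- consensus_of(pc$a$junction_aa)
  ctrg <- consensus_of(pc$b$junction_aa)
  divergent_of <- function(junc, consensus, locus) {
    div <- junc[junc != consensus]
    if (length(div) == 0L) return(NULL)
    tab <- table(div)
    data.frame(locus = locus, junction_aa = names(tab),
               n_cells = as.integer(tab),
               dist_to_consensus = editDistance(names(tab), consensus),
               stringsAsFactors = FALSE)
  }
  divergent <- rbind(divergent_of(pc$a$junction_aa, ctrd$consensus, "TRD"),
                     divergent_of(pc$b$junction_aa, ctrg$consensus, "TRG"))
  if (is.null(divergent)) {
    divergent <- data.frame(locus = character(), junction_aa = character(),
                            n_cells = integer(), dist_to_consensus = integer())
  }
  rownames(divergent) <- NULL
  lab <- cells$subset_label
  lab[is.na(lab)] <- "(unlabelled)"
  ptab <- sort(table(lab), decreasing = TRUE)
  collapse_set <- function(x) paste(sort(unique(x[!is.na(x)])), collapse = ",")
  out <- list(
    trd_v = collapse_set(pc$a$v_gene), trd_j = collapse_set(pc$a$j_gene),
    trg_v = collapse_set(pc$b$v_gene), trg_j = collapse_set(pc$b$j_gene),
    consensus_trd_junction = ctrd$consensus, consensus_trd_tie = ctrd$tie,
    consensus_trg_junction = ctrg$consensus, consensus_trg_tie = ctrg$tie,
    n_cells = nrow(cells),
    n_exact_trd = sum(pc$a$junction_aa == ctrd$consensus),
    n_exact_trg = sum(pc$b$junction_aa == ctrg$consensus),
    n_subjects = length(unique(cells$subject_id)),
    subject_coverage = length(unique(cells$subject_id)) / total_subjects,
    dominant_phenotype = names(ptab)[1L],
    dominant_fraction = as.integer(ptab[1L]) / nrow(cells),
    divergent = divergent
  )
  class(out) <- "invariantCloneReport"
  out
}

#' @export
print.invariantCloneReport <- function(x, ...) {
  cat("Invariant clone report\n")
  cat(sprintf("  TRD: %s / %s  consensus %s (%d/%d exact)\n",
              x$trd_v, x$trd_j, x$consensus_trd_junction,
              x$n_exact_trd, x$n_cells))
  cat(sprintf("  TRG: %s / %s  consensus %s (%d/%d exact)\n",
              x$trg_v, x$trg_j, x$consensus_trg_junction,
              x$n_exact_trg, x$n_cells))
  cat(sprintf("  subjects: %d (coverage %.2f)  dominant phenotype: %s (%.1f%%)\n",
              x$n_subjects, x$subject_coverage,
              x$dominant_phenotype, 100 * x$dominant_fraction))
  if (nrow(x$divergent) > 0L) {
    cat("  divergent junctions:\n")
    print(x$divergent)
  }
  invisible(x)
}
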