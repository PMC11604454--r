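## Per-cell chain-combination profiling and TCR-vs-transcriptome
## lineage concordance.

.cellKey <- function(subject_id, barcode) paste(subject_id, barcode, sep = "\r")

#' Classify each cell by its combination of expressed TCR loci
#'
#' One profile per (subject_id, barcode) with at least one retained contig.
#' The chain-combination label lists the loci present in the fixed canonical
#' order TRA/TRB/TRG/TRD joined by "/", so e.g. a cell with TRG and TRD
#' contigs is labelled \code{"TRG/TRD"} and a cell with TRB, TRG and TRD
#' contigs \code{"TRB/TRG/TRD"} (see [displayCombo()] for the conventional
#' gamma-delta-first display aliases). Cells with more than two contigs of
#' one locus are profiled normally but flagged \code{multi_chain}; doublet
#' removal belongs to the upstream transcriptome pipeline.
#'
#' @param cs A filtered [ContigSet-class].
#' @return data.frame with one row per cell: \code{subject_id},
#'   \code{barcode}, \code{subset_label}, per-locus contig counts
#'   (\code{n_TRA} .. \code{n_TRD}), \code{combo_label}, \code{multi_chain}.
#' @export
profileCells <- function(cs) {
  stopifnot(is(cs, "ContigSet"))
  df <- contigs(cs)
  df <- df[!is.na(df$locus), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(subject_id = character(), barcode = character(),
                      subset_label = character(),
                      n_TRA = integer(), n_TRB = integer(),
                      n_TRG = integer(), n_TRD = integer(),
                      combo_label = character(), multi_chain = logical(),
                      stringsAsFactors = FALSE))
  }
  key <- .cellKey(df$subject_id, df$barcode)
  counts <- table(key, factor(df$locus, levels = TR_LOCI))
  keys <- rownames(counts)
  first <- match(keys, key)
  mat <- matrix(as.integer(counts), nrow = nrow(counts),
                dimnames = dimnames(counts))
  combo <- apply(mat > 0L, 1L, function(p) paste(TR_LOCI[p], collapse = "/"))
  out <- data.frame(
    subject_id = df$subject_id[first],
    barcode = df$barcode[first],
    subset_label = df$subset_label[first],
    n_TRA = mat[, "TRA"], n_TRB = mat[, "TRB"],
    n_TRG = mat[, "TRG"], n_TRD = mat[, "TRD"],
    combo_label = unname(combo),
    multi_chain = apply(mat, 1L, max) > 2L,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Display aliases for chain-combination labels
#'
#' Canonical labels order loci TRA/TRB/TRG/TRD; gamma-delta biology is
#' conventionally written gamma-first (e.g. \code{"TRG/TRD/TRB"} rather than
#' the canonical \code{"TRB/TRG/TRD"}). Returns the display form of each
#' canonical label.
#'
#' @param combo character vector of canonical combo labels.
#' @return character vector of display labels.
#' @export
displayCombo <- function(combo) {
  alias <- c("TRB/TRG/TRD" = "TRG/TRD/TRB",
             "TRA/TRG/TRD" = "TRG/TRD/TRA",
             "TRA/TRB/TRG/TRD" = "TRA/TRB/TRG/TRD")
  out <- unname(ifelse(combo %in% names(alias), alias[combo], combo))
  out
}

#' Chain-combination frequencies per group
#'
#' @param profiles output of [profileCells()].
#' @param group_key grouping column, default \code{"subset_label"}.
#' @return data.frame of (group, combo_label, count, percent); percentages
#'   are per group over cells with at least one retained contig and sum to
#'   100 up to rounding.
#' @export
chainComboFrequencies <- function(profiles, group_key = "subset_label") {
  stopifnot(is.data.frame(profiles))
  if (!group_key %in% names(profiles)) {
    stop("unknown group key: ", group_key)
  }
  if (nrow(profiles) == 0L) stop("no cell profiles supplied")
  grp <- profiles[[group_key]]
  grp[is.na(grp)] <- "(unlabelled)"
  tab <- as.data.frame(table(group = grp, combo_label = profiles$combo_label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  totals <- tapply(tab$count, tab$group, sum)
  tab$percent <- 100 * tab$count / as.vector(totals[tab$group])
  names(tab)[1L] <- group_key
  tab <- tab[order(tab[[group_key]], -tab$count, tab$combo_label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Select cells with exactly one productive contig for each of two loci
#'
#' Used to define gamma-delta T cells by their receptor: cells with a single
#' productive TRD and a single productive TRG rearrangement. Presence of
#' contigs from other loci does not exclude a cell by default, because cells
#' of interest may also carry alpha/beta transcripts; set
#' \code{exclude_other_loci = TRUE} for the strict definition.
#'
#' @param profiles output of [profileCells()].
#' @param loci pair of distinct loci, default \code{c("TRD", "TRG")}.
#' @param exclude_other_loci if TRUE, cells with any contig of a locus
#'   outside \code{loci} are excluded.
#' @return the selected rows of \code{profiles}.
#' @export
selectSinglePairCells <- function(profiles, loci = c("TRD", "TRG"),
                                  exclude_other_loci = FALSE) {
  stopifnot(is.data.frame(profiles), length(loci) == 2L,
            loci[1L] != loci[2L], all(loci %in% TR_LOCI))
  ncol_a <- paste0("n_", loci[1L])
  ncol_b <- paste0("n_", loci[2L])
  keep <- profiles[[ncol_a]] == 1L & profiles[[ncol_b]] == 1L
  if (exclude_other_loci) {
    others <- paste0("n_", setdiff(TR_LOCI, loci))
    keep <- keep & rowSums(profiles[, others, drop = FALSE]) == 0L
  }
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate a TCR-defined population against transcriptome labels
#'
#' For a TCR-defined cell population (e.g. single-pair TRD/TRG cells) counts
#' how the transcriptome clustering had classified those cells, with
#' percentages to one decimal.
#'
#' @param cells data.frame of selected cells carrying \code{subset_label}
#'   (e.g. from [selectSinglePairCells()]).
#' @return data.frame (subset_label, count, percent) sorted by count,
#'   with the population size as attribute \code{"total"}.
#' @export
lineageConcordance <- function(cells) {
  stopifnot(is.data.frame(cells), "subset_label" %in% names(cells))
  lab <- cells$subset_label
  lab[is.na(lab)] <- "(unlabelled)"
  tab <- sort(table(lab), decreasing = TRUE)
  out <- data.frame(
    subset_label = names(tab),
    count = as.integer(tab),
    percent = round(100 * as.integer(tab) / nrow(cells), 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- nrow(cells)
  out
}
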