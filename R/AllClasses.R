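#' @import methods
#' @importFrom stats setNames aggregate rbinom rpois runif
#' @importFrom utils adist read.csv read.delim write.table head
NULL

## The four T-cell receptor loci, in the canonical order used for
## chain-combination labels throughout the package.
TR_LOCI <- c("TRA", "TRB", "TRG", "TRD")

## Internal contig table columns and their types. subject_id and
## subset_label may be all-NA until attachMetadata() is called.
.CONTIG_COLS <- c(
  contig_id       = "character",
  barcode         = "character",
  subject_id      = "character",
  locus           = "character",
  v_gene          = "character",
  d_gene          = "character",
  j_gene          = "character",
  c_gene          = "character",
  junction_aa     = "character",
  junction_nt     = "character",
  productive      = "logical",
  is_cell         = "logical",
  high_confidence = "logical",
  umis            = "integer",
  subset_label    = "character"
)

#' ContigSet: a validated collection of V(D)J contigs
#'
#' An S4 container holding one row per assembled V(D)J contig together with
#' provenance: the source file(s) it was read from and a log of every filter
#' rule applied with the number of contigs each removed.
#'
#' @slot contigs data.frame with columns \code{contig_id}, \code{barcode},
#'   \code{subject_id}, \code{locus} (one of TRA/TRB/TRG/TRD or \code{NA}),
#'   \code{v_gene}, \code{d_gene}, \code{j_gene}, \code{c_gene},
#'   \code{junction_aa}, \code{junction_nt}, \code{productive},
#'   \code{is_cell}, \code{high_confidence}, \code{umis},
#'   \code{subset_label}.
#' @slot provenance list with elements \code{sources} (character),
#'   \code{filter_log} (data.frame of rule/removed) and
#'   \code{unmatched_barcodes} (integer).
#'
#' @seealso [readContigTable()], [filterContigs()], [attachMetadata()]
#' @export
setClass("ContigSet",
  representation(contigs = "data.frame", provenance = "list"),
  prototype(
    contigs = data.frame(),
    provenance = list(
      sources = character(),
      filter_log = data.frame(rule = character(), removed = integer()),
      unmatched_barcodes = 0L
    )
  )
)

setValidity("ContigSet", function(object) {
  df <- object@contigs
  msgs <- character()
  missing <- setdiff(names(.CONTIG_COLS), names(df))
  if (length(missing) > 0L) {
    return(paste0("missing contig column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in names(.CONTIG_COLS)) {
    want <- .CONTIG_COLS[[col]]
    if (!is(df[[col]], want)) {
      msgs <- c(msgs, sprintf("column '%s' must be %s", col, want))
    }
  }
  if (length(msgs) > 0L) return(msgs)
  bad_locus <- !is.na(df$locus) & !(df$locus %in% TR_LOCI)
  if (any(bad_locus)) {
    msgs <- c(msgs, paste0("invalid locus value(s): ",
                           paste(unique(df$locus[bad_locus]), collapse = ", ")))
  }
  if (any(!is.na(df$umis) & df$umis < 0L)) {
    msgs <- c(msgs, "umis must be non-negative")
  }
  both <- !is.na(df$junction_aa) & !is.na(df$junction_nt)
  if (any(nchar(df$junction_aa[both]) * 3L > nchar(df$junction_nt[both]))) {
    msgs <- c(msgs, "junction_aa longer than junction_nt allows")
  }
  ## contig ids must be unique within a subject (barcode collisions across
  ## separately sequenced libraries are expected, id collisions are not)
  key <- paste(df$subject_id, df$contig_id, sep = "\r")
  if (anyDuplicated(key)) {
    msgs <- c(msgs, "duplicated contig_id within a subject")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a ContigSet from a contig data.frame
#'
#' Fills in optional columns (\code{subject_id}, \code{subset_label},
#' \code{is_cell}, \code{high_confidence}, \code{umis}, \code{d_gene},
#' \code{c_gene}, \code{junction_nt}) with defaults, coerces types, and
#' validates the result.
#'
#' @param contigs data.frame with at least \code{contig_id}, \code{barcode},
#'   \code{locus}, \code{v_gene}, \code{j_gene}, \code{junction_aa},
#'   \code{productive}.
#' @param sources character vector of source descriptions for provenance.
#' @return A [ContigSet-class] object.
#' @export
ContigSet <- function(contigs, sources = character()) {
  stopifnot(is.data.frame(contigs))
  n <- nrow(contigs)
  defaults <- list(
    subject_id = NA_character_, subset_label = NA_character_,
    d_gene = NA_character_, c_gene = NA_character_,
    junction_nt = NA_character_, is_cell = TRUE, high_confidence = TRUE,
    umis = 1L
  )
  for (col in names(defaults)) {
    if (!col %in% names(contigs)) contigs[[col]] <- rep(defaults[[col]], length.out = n)
  }
  for (col in names(.CONTIG_COLS)) {
    want <- .CONTIG_COLS[[col]]
    contigs[[col]] <- switch(want,
      character = as.character(contigs[[col]]),
      logical   = as.logical(contigs[[col]]),
      integer   = as.integer(contigs[[col]])
    )
  }
  contigs <- contigs[, names(.CONTIG_COLS)]
  rownames(contigs) <- NULL
  new("ContigSet", contigs = contigs, provenance = list(
    sources = as.character(sources),
    filter_log = data.frame(rule = character(), removed = integer(),
                            stringsAsFactors = FALSE),
    unmatched_barcodes = 0L
  ))
}

#' @describeIn ContigSet-class Extract the contig table.
#' @param x A \code{ContigSet}.
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname ContigSet-class
#' @export
setMethod("contigs", "ContigSet", function(x) x@contigs)

#' @describeIn ContigSet-class Provenance list (sources, filter log,
#'   unmatched barcode count).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ContigSet-class
#' @export
setMethod("provenance", "ContigSet", function(x) x@provenance)

#' @describeIn ContigSet-class The filter log: one row per applied rule with
#'   the number of contigs removed.
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname ContigSet-class
#' @export
setMethod("filterLog", "ContigSet", function(x) x@provenance$filter_log)

#' @rdname ContigSet-class
#' @export
setMethod("length", "ContigSet", function(x) nrow(x@contigs))

setMethod("show", "ContigSet", function(object) {
  df <- object@contigs
  cat("ContigSet with", nrow(df), "contigs\n")
  if (nrow(df) > 0L) {
    tab <- table(factor(df$locus, levels = TR_LOCI), useNA = "ifany")
    cat("  loci:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cells <- unique(paste(df$subject_id, df$barcode))
    cat("  cells:", length(cells),
        " subjects:", length(unique(df$subject_id[!is.na(df$subject_id)])), "\n")
  }
  fl <- object@provenance$filter_log
  if (nrow(fl) > 0L) {
    cat("  filtered:", paste(sprintf("%s=%d", fl$rule, fl$removed), collapse = " "), "\n")
  }
})

#' ClonotypeGraph: a per-locus clonotype similarity network
#'
#' Nodes are clonotypes (unique amino-acid junctions at one locus); an edge
#' joins two clonotypes of identical junction length that differ at exactly
#' one position (Hamming distance 1). Clusters are connected components with
#' at least two nodes; singletons carry an \code{NA} cluster id.
#'
#' @slot locus character, one of TRA/TRB/TRG/TRD.
#' @slot graph the underlying \pkg{igraph} graph.
#' @slot nodes data.frame with \code{junction_aa}, \code{cell_count},
#'   \code{n_subjects}, \code{degree}, \code{cluster_id}.
#'
#' @seealso [buildNetwork()], [clusterMetrics()]
#' @export
setClass("ClonotypeGraph",
  representation(locus = "character", graph = "ANY", nodes = "data.frame"))

setValidity("ClonotypeGraph", function(object) {
  if (length(object@locus) != 1L || !(object@locus %in% TR_LOCI)) {
    return("locus must be one of TRA/TRB/TRG/TRD")
  }
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  TRUE
})

setMethod("show", "ClonotypeGraph", function(object) {
  g <- object@graph
  n_clust <- length(unique(object@nodes$cluster_id[!is.na(object@nodes$cluster_id)]))
  cat("ClonotypeGraph (", object@locus, "): ",
      igraph::vcount(g), " clonotypes, ", igraph::ecount(g), " edges, ",
      n_clust, " clusters (size >= 2)\n", sep = "")
})

#' SymbolMap: a resolved source-gene to target-symbol mapping
#'
#' @slot entries named character vector: source gene id -> assigned symbol
#'   (unique after collision suffixing).
#' @slot report list of diagnostic counts (input features, already-symboled,
#'   newly mapped, unresolved).
#'
#' @seealso [resolveSymbols()], [renameFeatures()]
#' @export
setClass("SymbolMap", representation(entries = "character", report = "list"))

setValidity("SymbolMap", function(object) {
  if (length(object@entries) > 0L && is.null(names(object@entries))) {
    return("entries must be named by source gene id")
  }
  if (anyDuplicated(names(object@entries))) {
    return("a source gene may appear at most once")
  }
  if (anyDuplicated(object@entries)) return("assigned symbols must be unique")
  TRUE
})

#' @describeIn SymbolMap-class The named source-id -> symbol vector.
#' @param x A \code{SymbolMap}.
#' @export
setGeneric("symbolEntries", function(x) standardGeneric("symbolEntries"))

#' @rdname SymbolMap-class
#' @export
setMethod("symbolEntries", "SymbolMap", function(x) x@entries)

#' @describeIn SymbolMap-class Mapping report counts.
#' @export
setGeneric("mappingReport", function(x) standardGeneric("mappingReport"))

#' @rdname SymbolMap-class
#' @export
setMethod("mappingReport", "SymbolMap", function(x) x@report)

setMethod("show", "SymbolMap", function(object) {
  cat("SymbolMap with", length(object@entries), "entries\n")
  r <- object@report
  if (length(r) > 0L) {
    cat(" ", paste(sprintf("%s=%s", names(r), unlist(r)), collapse = " "), "\n")
  }
})
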