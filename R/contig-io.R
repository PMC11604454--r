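## Reading, filtering and annotating V(D)J contig tables.

.TENX_REQUIRED <- c("barcode", "is_cell", "contig_id", "high_confidence",
                    "chain", "v_gene", "d_gene", "j_gene", "c_gene",
                    "productive", "cdr3", "cdr3_nt", "umis")
.AIRR_REQUIRED <- c("locus", "v_call", "j_call", "junction_aa", "productive",
                    "cell_id")

.parseBool <- function(x) {
  low <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1")] <- TRUE
  out[low %in% c("false", "f", "0", "none")] <- FALSE
  as.logical(out)
}

.parseGene <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "None", "NA", "nan")] <- NA_character_
  x
}

.parseLocus <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!(x %in% TR_LOCI)] <- NA_character_
  x
}

#' Read a V(D)J contig annotation table
#'
#' Parses a 10x Genomics \code{all_contig_annotations.csv}-style file or an
#' AIRR Rearrangement TSV into a [ContigSet-class]. Boolean columns are
#' parsed case-insensitively; gene calls of \code{"None"} or empty become
#' absent (\code{NA}); amino-acid junctions are upper-cased on read. Rows
#' whose chain/locus is not one of TRA/TRB/TRG/TRD (e.g. \code{"Multi"}) are
#' retained with locus absent so that downstream filters can count them.
#'
#' @param path path to the input file.
#' @param dialect \code{"tenx_csv"} for the 10x contig annotation CSV,
#'   \code{"airr_tsv"} for an AIRR Rearrangement TSV.
#' @param subject_id optional subject identifier attached to every contig
#'   (10x files are per-library, i.e. per-subject).
#' @return A [ContigSet-class]; empty (with a warning) for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' df <- data.frame(barcode = "AAAC-1", is_cell = "True", contig_id = "c1",
#'   high_confidence = "True", chain = "TRB", v_gene = "TRBV25",
#'   d_gene = "None", j_gene = "TRBJ2-6", c_gene = "TRBC2",
#'   productive = "True", cdr3 = "CASSLGQGF", cdr3_nt = "", umis = 4)
#' write.csv(df, tf, row.names = FALSE)
#' cs <- readContigTable(tf, "tenx_csv", subject_id = "cat1")
#' contigs(cs)$locus
#' @export
readContigTable <- function(path, dialect = c("tenx_csv", "airr_tsv"),
                            subject_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (dialect == "tenx_csv") {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  required <- if (dialect == "tenx_csv") .TENX_REQUIRED else .AIRR_REQUIRED
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s) for dialect '", dialect, "': ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("empty contig table: ", path)
    return(ContigSet(data.frame(
      contig_id = character(), barcode = character(), locus = character(),
      v_gene = character(), j_gene = character(), junction_aa = character(),
      productive = logical()), sources = path))
  }
  df <- if (dialect == "tenx_csv") {
    data.frame(
      contig_id = as.character(raw$contig_id),
      barcode = as.character(raw$barcode),
      subject_id = if ("subject_id" %in% names(raw)) as.character(raw$subject_id) else subject_id,
      locus = .parseLocus(raw$chain),
      v_gene = .parseGene(raw$v_gene),
      d_gene = .parseGene(raw$d_gene),
      j_gene = .parseGene(raw$j_gene),
      c_gene = .parseGene(raw$c_gene),
      junction_aa = toupper(.parseGene(raw$cdr3)),
      junction_nt = toupper(.parseGene(raw$cdr3_nt)),
      productive = .parseBool(raw$productive),
      is_cell = .parseBool(raw$is_cell),
      high_confidence = .parseBool(raw$high_confidence),
      umis = as.integer(raw$umis),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      contig_id = as.character(if ("sequence_id" %in% names(raw)) raw$sequence_id else seq_len(nrow(raw))),
      barcode = as.character(raw$cell_id),
      subject_id = if ("subject_id" %in% names(raw)) as.character(raw$subject_id) else subject_id,
      locus = .parseLocus(raw$locus),
      v_gene = .parseGene(raw$v_call),
      d_gene = if ("d_call" %in% names(raw)) .parseGene(raw$d_call) else NA_character_,
      j_gene = .parseGene(raw$j_call),
      c_gene = if ("c_call" %in% names(raw)) .parseGene(raw$c_call) else NA_character_,
      junction_aa = toupper(.parseGene(raw$junction_aa)),
      junction_nt = if ("junction" %in% names(raw)) toupper(.parseGene(raw$junction)) else NA_character_,
      productive = .parseBool(raw$productive),
      is_cell = if ("is_cell" %in% names(raw)) .parseBool(raw$is_cell) else TRUE,
      high_confidence = if ("high_confidence" %in% names(raw)) .parseBool(raw$high_confidence) else TRUE,
      umis = if ("duplicate_count" %in% names(raw)) as.integer(raw$duplicate_count) else 1L,
      stringsAsFactors = FALSE
    )
  }
  if ("subset_label" %in% names(raw)) df$subset_label <- .parseGene(raw$subset_label)
  ContigSet(df, sources = path)
}

#' Write a ContigSet as an AIRR Rearrangement TSV
#'
#' Standard AIRR column names (\code{sequence_id}, \code{cell_id},
#' \code{locus}, \code{v_call}, \code{d_call}, \code{j_call}, \code{c_call},
#' \code{junction}, \code{junction_aa}, \code{productive},
#' \code{duplicate_count}) plus \code{subject_id} and \code{subset_label}
#' extension columns; booleans are written as \code{T}/\code{F}.
#'
#' @param cs A [ContigSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAirr <- function(cs, path) {
  stopifnot(is(cs, "ContigSet"))
  df <- contigs(cs)
  fmtB <- function(b) ifelse(is.na(b), "", ifelse(b, "T", "F"))
  out <- data.frame(
    sequence_id = df$contig_id,
    cell_id = df$barcode,
    subject_id = ifelse(is.na(df$subject_id), "", df$subject_id),
    subset_label = ifelse(is.na(df$subset_label), "", df$subset_label),
    locus = ifelse(is.na(df$locus), "", df$locus),
    v_call = ifelse(is.na(df$v_gene), "", df$v_gene),
    d_call = ifelse(is.na(df$d_gene), "", df$d_gene),
    j_call = ifelse(is.na(df$j_gene), "", df$j_gene),
    c_call = ifelse(is.na(df$c_gene), "", df$c_gene),
    junction = ifelse(is.na(df$junction_nt), "", df$junction_nt),
    junction_aa = ifelse(is.na(df$junction_aa), "", df$junction_aa),
    productive = fmtB(df$productive),
    is_cell = fmtB(df$is_cell),
    high_confidence = fmtB(df$high_confidence),
    duplicate_count = df$umis,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the filter report as JSON
#'
#' @param cs A filtered [ContigSet-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(cs, path) {
  stopifnot(is(cs, "ContigSet"))
  pv <- provenance(cs)
  rep <- list(
    sources = as.list(pv$sources),
    retained = nrow(contigs(cs)),
    removed = as.list(setNames(as.integer(pv$filter_log$removed),
                               pv$filter_log$rule)),
    unmatched_barcodes = pv$unmatched_barcodes
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Filter contigs to productive, complete, locus-concordant rearrangements
#'
#' Applies, in order: an optional cell/confidence pre-filter (10x files
#' contain contigs from non-cell barcodes), removal of non-productive
#' contigs, removal of contigs lacking a V, J or C gene call, removal of
#' contigs with an undetermined locus, and removal of inter-locus chimeras
#' (contigs whose V, J or C gene prefix disagrees with the contig locus).
#' Every rule's removal count is appended to the filter log, so that
#' retained + removed reconstructs the input count.
#'
#' The D gene is deliberately not required: TRA and TRG rearrangements have
#' none, and D segments are frequently untrimmed in annotation output.
#'
#' @param cs A [ContigSet-class].
#' @param requireCell drop contigs whose barcode was not called a cell.
#' @param requireHighConfidence drop low-confidence contigs.
#' @return The filtered [ContigSet-class]. Idempotent.
#' @export
filterContigs <- function(cs, requireCell = TRUE, requireHighConfidence = TRUE) {
  stopifnot(is(cs, "ContigSet"))
  df <- contigs(cs)
  log <- data.frame(rule = character(), removed = integer(),
                    stringsAsFactors = FALSE)
  drop_rule <- function(df, keep, rule) {
    keep[is.na(keep)] <- FALSE
    log <<- rbind(log, data.frame(rule = rule, removed = sum(!keep)))
    df[keep, , drop = FALSE]
  }
  if (requireCell) {
    df <- drop_rule(df, df$is_cell, "not_cell")
  }
  if (requireHighConfidence) {
    df <- drop_rule(df, df$high_confidence, "low_confidence")
  }
  df <- drop_rule(df, df$productive, "non_productive")
  df <- drop_rule(df, !is.na(df$v_gene) & !is.na(df$j_gene) & !is.na(df$c_gene),
                  "missing_vjc")
  df <- drop_rule(df, !is.na(df$locus), "undetermined_locus")
  same_locus <- substr(df$v_gene, 1L, 3L) == df$locus &
    substr(df$j_gene, 1L, 3L) == df$locus &
    substr(df$c_gene, 1L, 3L) == df$locus
  df <- drop_rule(df, same_locus, "interlocus_chimera")
  pv <- cs@provenance
  pv$filter_log <- rbind(pv$filter_log, log)
  rownames(df) <- NULL
  new("ContigSet", contigs = df, provenance = pv)
}

#' Attach subject and subset metadata to contigs
#'
#' Joins a cell-annotation table (barcode, subject_id, subset_label) onto the
#' contigs. If the contigs already carry subject ids the join key is
#' (subject_id, barcode); otherwise barcode alone is used and the subject id
#' is attached from the annotations. Cells are keyed by (subject_id, barcode)
#' because the subjects were sequenced as separate libraries and 10x barcodes
#' collide across libraries.
#'
#' @param cs A [ContigSet-class].
#' @param ann data.frame with columns \code{barcode}, \code{subject_id},
#'   \code{subset_label}; one row per (subject_id, barcode).
#' @return The annotated [ContigSet-class]; unmatched barcodes keep an absent
#'   label and are counted in \code{provenance(cs)$unmatched_barcodes}.
#' @export
attachMetadata <- function(cs, ann) {
  stopifnot(is(cs, "ContigSet"), is.data.frame(ann))
  need <- c("barcode", "subject_id", "subset_label")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0L) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  akey <- paste(ann$subject_id, ann$barcode, sep = "\r")
  if (anyDuplicated(akey)) {
    stop("duplicate (subject_id, barcode) in annotations")
  }
  df <- contigs(cs)
  if (all(is.na(df$subject_id))) {
    if (anyDuplicated(ann$barcode)) {
      stop("contigs carry no subject_id and annotation barcodes are not unique")
    }
    idx <- match(df$barcode, ann$barcode)
    df$subject_id <- ann$subject_id[idx]
  } else {
    idx <- match(paste(df$subject_id, df$barcode, sep = "\r"), akey)
  }
  df$subset_label <- ann$subset_label[idx]
  pv <- cs@provenance
  pv$unmatched_barcodes <- sum(is.na(idx))
  new("ContigSet", contigs = df, provenance = pv)
}
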