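## Cross-species ortholog gene-symbol transfer: one-to-one orthologs map
## directly; one-to-many/many-to-many are resolved by a lexicographic
## descending comparison over homology-quality fields, in order:
## orthology confidence, gene order conservation score, whole-genome
## alignment score, % query identical to target, % target identical to
## query. Absent values rank below any present value; residual ties break
## on the source gene id so resolution is deterministic.

.HOMOLOGY_REQUIRED <- c("source_gene_id", "target_gene_id", "target_symbol",
                        "homology_class", "orthology_confidence",
                        "gene_order_confidence", "whole_genome_alignment",
                        "pct_query_identical_target",
                        "pct_target_identical_query")
.HOMOLOGY_CLASSES <- c("one2one", "one2many", "many2many")
.PRIORITY_FIELDS <- c("orthology_confidence", "gene_order_confidence",
                      "whole_genome_alignment", "pct_query_identical_target",
                      "pct_target_identical_query")

#' Load a BioMart-style homology export table
#'
#' @param path TSV (or CSV, by extension) with columns
#'   \code{source_gene_id}, \code{target_gene_id}, \code{target_symbol},
#'   \code{homology_class} (one2one/one2many/many2many),
#'   \code{orthology_confidence} (0/1), \code{gene_order_confidence},
#'   \code{whole_genome_alignment}, \code{pct_query_identical_target},
#'   \code{pct_target_identical_query}; \code{source_symbol} optional.
#'   Empty priority fields are retained as absent and rank lowest during
#'   resolution.
#' @return data.frame of homology records.
#' @export
loadHomologyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(.HOMOLOGY_REQUIRED, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw$source_gene_id <- as.character(raw$source_gene_id)
  raw$target_gene_id <- as.character(raw$target_gene_id)
  raw$target_symbol <- as.character(raw$target_symbol)
  raw$homology_class <- as.character(raw$homology_class)
  for (f in .PRIORITY_FIELDS) raw[[f]] <- as.numeric(raw[[f]])
  validateHomologyRecords(raw)
  raw
}

#' Validate homology records
#'
#' @param records data.frame of homology records.
#' @return \code{records}, invisibly; errors name the offending row.
#' @export
validateHomologyRecords <- function(records) {
  bad_class <- !(records$homology_class %in% .HOMOLOGY_CLASSES)
  if (any(bad_class)) {
    stop("invalid homology_class in row(s): ",
         paste(which(bad_class), collapse = ", "))
  }
  for (f in c("pct_query_identical_target", "pct_target_identical_query")) {
    bad <- !is.na(records[[f]]) & (records[[f]] < 0 | records[[f]] > 100)
    if (any(bad)) {
      stop(f, " outside [0, 100] in row(s): ",
           paste(which(bad), collapse = ", "))
    }
  }
  bad_conf <- !is.na(records$orthology_confidence) &
    !(records$orthology_confidence %in% c(0, 1))
  if (any(bad_conf)) {
    stop("orthology_confidence must be 0 or 1 in row(s): ",
         paste(which(bad_conf), collapse = ", "))
  }
  invisible(records)
}

## Rank record rows best-first under the lexicographic priority rule.
.rankRecords <- function(records) {
  keys <- lapply(.PRIORITY_FIELDS, function(f) {
    v <- records[[f]]
    v[is.na(v)] <- -Inf
    -v
  })
  do.call(order, c(keys, list(records$source_gene_id)))
}

#' Resolve source-gene to target-symbol assignments
#'
#' Pass 1 assigns every one-to-one ortholog its target symbol directly.
#' Pass 2 resolves one-to-many and many-to-many records: by default each
#' contested target symbol is won by the source gene whose record is the
#' lexicographic maximum over the five homology-quality fields (see
#' [loadHomologyTable()]); losing genes keep their original identifier.
#' \code{direction = "per_source"} instead picks, for each source gene with
#' multiple targets, its best target symbol. Symbol collisions are
#' uniquified by ".1", ".2" suffixes (count-matrix feature names must be
#' unique).
#'
#' @param records homology records, from [loadHomologyTable()].
#' @param features character vector of feature identifiers to map.
#' @param unmapped_pattern regex identifying features still carrying a bare
#'   gene id (candidates for mapping); non-matching features are counted as
#'   already symboled and left alone.
#' @param direction \code{"per_symbol"} (default) or \code{"per_source"}.
#' @return A [SymbolMap-class].
#' @export
resolveSymbols <- function(records, features, unmapped_pattern = "^ENS",
                           direction = c("per_symbol", "per_source")) {
  direction <- match.arg(direction)
  validateHomologyRecords(records)
  features <- as.character(features)
  candidates <- features[grepl(unmapped_pattern, features)]
  rec <- records[records$source_gene_id %in% candidates &
                   !is.na(records$target_symbol) & records$target_symbol != "",
                 , drop = FALSE]
  rec <- rec[.rankRecords(rec), , drop = FALSE]
  entries <- character(0)
  ## pass 1: one-to-one orthologs map directly (best record per source)
  o2o <- rec[rec$homology_class == "one2one", , drop = FALSE]
  o2o <- o2o[!duplicated(o2o$source_gene_id), , drop = FALSE]
  entries[o2o$source_gene_id] <- o2o$target_symbol
  ## pass 2: contested assignments resolved by the priority ordering
  multi <- rec[rec$homology_class != "one2one", , drop = FALSE]
  multi <- multi[!(multi$source_gene_id %in% names(entries)), , drop = FALSE]
  if (nrow(multi) > 0L) {
    if (direction == "per_symbol") {
      multi <- multi[!(multi$target_symbol %in% entries), , drop = FALSE]
      win <- multi[!duplicated(multi$target_symbol), , drop = FALSE]
      ## a source gene can win at most one symbol: keep its best win
      win <- win[!duplicated(win$source_gene_id), , drop = FALSE]
    } else {
      win <- multi[!duplicated(multi$source_gene_id), , drop = FALSE]
    }
    entries[win$source_gene_id] <- win$target_symbol
  }
  ## deterministic uniquification, independent of input row order
  entries <- entries[order(names(entries))]
  if (length(entries) > 0L) entries <- setNames(make.unique(unname(entries)),
                                                names(entries))
  report <- list(
    input_features = length(features),
    already_symboled = length(features) - length(candidates),
    newly_mapped = sum(candidates %in% names(entries)),
    unresolved = sum(!(candidates %in% names(entries)))
  )
  new("SymbolMap", entries = entries, report = report)
}

#' Rename a feature list using a symbol map plus manual overrides
#'
#' Automatic mapping is applied first; overrides are applied on top of it.
#' Override actions are \code{"rename:<symbol>"}, \code{"drop"} and
#' \code{"keep"} (retain the original identifier). Feature order is
#' preserved; dropped features are removed.
#'
#' @param features character vector of feature identifiers.
#' @param map A [SymbolMap-class].
#' @param overrides optional data.frame with columns \code{source_gene_id}
#'   and \code{action}. Overrides naming unknown features warn, not error.
#' @return list with \code{features} (renamed vector) and \code{report}
#'   (action counts).
#' @export
renameFeatures <- function(features, map, overrides = NULL) {
  stopifnot(is(map, "SymbolMap"))
  features <- as.character(features)
  entries <- symbolEntries(map)
  hit <- features %in% names(entries)
  renamed <- ifelse(hit, unname(entries[features]), features)
  drop <- rep(FALSE, length(features))
  n_over <- c(rename = 0L, drop = 0L, keep = 0L)
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    stopifnot(all(c("source_gene_id", "action") %in% names(overrides)))
    unknown <- setdiff(overrides$source_gene_id, features)
    if (length(unknown) > 0L) {
      warning("override(s) reference unknown feature(s): ",
              paste(unknown, collapse = ", "))
    }
    for (r in seq_len(nrow(overrides))) {
      idx <- which(features == overrides$source_gene_id[r])
      if (length(idx) == 0L) next
      action <- overrides$action[r]
      if (action == "drop") {
        drop[idx] <- TRUE
        n_over["drop"] <- n_over["drop"] + length(idx)
      } else if (action == "keep") {
        renamed[idx] <- features[idx]
        n_over["keep"] <- n_over["keep"] + length(idx)
      } else if (startsWith(action, "rename:")) {
        renamed[idx] <- sub("^rename:", "", action)
        n_over["rename"] <- n_over["rename"] + length(idx)
      } else {
        stop("unknown override action: ", action)
      }
    }
  }
  out <- renamed[!drop]
  list(
    features = out,
    report = list(
      input = length(features),
      auto_renamed = sum(hit & !drop),
      override_renamed = unname(n_over["rename"]),
      dropped = unname(n_over["drop"]),
      kept = unname(n_over["keep"]),
      output = length(out)
    )
  )
}
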