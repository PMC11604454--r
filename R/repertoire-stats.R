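## Clonotype definition, gene usage, junctional statistics, PWMs and
## cross-chain pairing diversity.

#' Define amino-acid junction clonotypes
#'
#' A clonotype is a unique amino-acid junction sequence at one locus; its
#' cell count is the number of distinct cells (subject, barcode) carrying
#' it. Junctions are used as reported, including the conserved C...F/W
#' anchors. Contigs lacking an amino-acid junction are excluded and counted
#' in the \code{"n_excluded"} attribute.
#'
#' @param cs A filtered [ContigSet-class].
#' @return data.frame with one row per (locus, junction_aa): \code{locus},
#'   \code{junction_aa}, \code{junction_length}, \code{cell_count},
#'   \code{n_subjects}, \code{subjects} (comma-separated), \code{v_genes},
#'   \code{j_genes} (comma-separated sets).
#' @export
defineClonotypes <- function(cs) {
  stopifnot(is(cs, "ContigSet"))
  df <- contigs(cs)
  no_junc <- is.na(df$junction_aa) | df$junction_aa == ""
  df <- df[!no_junc & !is.na(df$locus), , drop = FALSE]
  key <- paste(df$locus, df$junction_aa, sep = "\r")
  cell <- .cellKey(df$subject_id, df$barcode)
  collapse_set <- function(x) {
    paste(sort(unique(x[!is.na(x)])), collapse = ",")
  }
  idx <- split(seq_len(nrow(df)), key)
  out <- data.frame(
    locus = vapply(idx, function(i) df$locus[i[1L]], character(1L)),
    junction_aa = vapply(idx, function(i) df$junction_aa[i[1L]], character(1L)),
    cell_count = vapply(idx, function(i) length(unique(cell[i])), integer(1L)),
    n_subjects = vapply(idx, function(i)
      length(unique(df$subject_id[i][!is.na(df$subject_id[i])])), integer(1L)),
    subjects = vapply(idx, function(i) collapse_set(df$subject_id[i]), character(1L)),
    v_genes = vapply(idx, function(i) collapse_set(df$v_gene[i]), character(1L)),
    j_genes = vapply(idx, function(i) collapse_set(df$j_gene[i]), character(1L)),
    stringsAsFactors = FALSE
  )
  out$junction_length <- nchar(out$junction_aa)
  out <- out[order(out$locus, -out$cell_count, out$junction_aa),
             c("locus", "junction_aa", "junction_length", "cell_count",
               "n_subjects", "subjects", "v_genes", "j_genes")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(no_junc)
  out
}

#' Junctional length in amino acids
#'
#' @param junction_aa character vector of amino-acid junction sequences.
#' @return integer vector of lengths.
#' @examples
#' junctionLength("CASDIGGSSWDTRQMFF")  # 17
#' @export
junctionLength <- function(junction_aa) {
  junction_aa <- as.character(junction_aa)
  if (length(junction_aa) == 0L || any(is.na(junction_aa) | junction_aa == "")) {
    stop("empty junction sequence")
  }
  nchar(junction_aa)
}

#' Levenshtein edit distance between junction sequences
#'
#' Unit-cost insertions, deletions and substitutions; vectorised with the
#' usual recycling.
#'
#' @param a,b character vectors of amino-acid sequences.
#' @return integer vector of distances.
#' @examples
#' editDistance("CACWDESGWIKIF", "CACWDHESGWIKIF")  # 1
#' @export
editDistance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(is.na(a) | a == "") || any(is.na(b) | b == "")) {
    stop("empty sequence")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1L))
}

#' V or J gene usage per group
#'
#' @param cs A filtered [ContigSet-class].
#' @param segment \code{"V"} or \code{"J"}.
#' @param locus one of TRA/TRB/TRG/TRD.
#' @param group_key contig grouping column, default \code{"subset_label"};
#'   \code{NULL} pools all contigs.
#' @param complete if TRUE, every gene observed anywhere is reported in
#'   every group (zero counts included).
#' @return data.frame (group, gene, count, percent); percentages are per
#'   group over contigs of the locus.
#' @export
geneUsage <- function(cs, segment = c("V", "J"), locus,
                      group_key = "subset_label", complete = FALSE) {
  stopifnot(is(cs, "ContigSet"), locus %in% TR_LOCI)
  segment <- match.arg(segment)
  df <- contigs(cs)
  df <- df[!is.na(df$locus) & df$locus == locus, , drop = FALSE]
  col <- if (segment == "V") "v_gene" else "j_gene"
  df <- df[!is.na(df[[col]]), , drop = FALSE]
  grp <- if (is.null(group_key)) rep("all", nrow(df)) else df[[group_key]]
  grp[is.na(grp)] <- "(unlabelled)"
  if (nrow(df) == 0L) {
    return(data.frame(group = character(), gene = character(),
                      count = integer(), percent = numeric()))
  }
  tab <- as.data.frame(table(group = grp, gene = df[[col]]),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  if (!complete) tab <- tab[tab$count > 0L, , drop = FALSE]
  totals <- tapply(tab$count, tab$group, sum)
  tab$percent <- 100 * tab$count / as.vector(totals[tab$group])
  tab <- tab[order(tab$group, -tab$count, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' V/J gene combination counts for one locus
#'
#' @inheritParams geneUsage
#' @return data.frame (group, v_gene, j_gene, count) sorted by count.
#' @export
vjCombinations <- function(cs, locus, group_key = NULL) {
  stopifnot(is(cs, "ContigSet"), locus %in% TR_LOCI)
  df <- contigs(cs)
  df <- df[!is.na(df$locus) & df$locus == locus &
             !is.na(df$v_gene) & !is.na(df$j_gene), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(group = character(), v_gene = character(),
                      j_gene = character(), count = integer()))
  }
  grp <- if (is.null(group_key)) rep("all", nrow(df)) else df[[group_key]]
  grp[is.na(grp)] <- "(unlabelled)"
  key <- paste(grp, df$v_gene, df$j_gene, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)
  out <- data.frame(
    group = vapply(idx, function(i) grp[i[1L]], character(1L)),
    v_gene = vapply(idx, function(i) df$v_gene[i[1L]], character(1L)),
    j_gene = vapply(idx, function(i) df$j_gene[i[1L]], character(1L)),
    count = lengths(idx),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$group, -out$count, out$v_gene, out$j_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## The 20 standard amino acids, alphabetical one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position weight matrix of equal-length junctions
#'
#' A PWM requires equal-length sequences, so only sequences of the modal
#' length are included; the number excluded is reported as an attribute.
#' Modal-length ties are broken toward the shorter length and flagged.
#'
#' @param junctions character vector of amino-acid junctions.
#' @return 20 x L numeric matrix (rows: standard amino acids, columns:
#'   junction positions); every column sums to 1. Attributes:
#'   \code{"modal_length"}, \code{"n_used"}, \code{"n_excluded"},
#'   \code{"length_tie"}.
#' @examples
#' pwm <- buildPWM(c("AY", "AW"))
#' pwm["Y", 2]  # 0.5
#' @export
buildPWM <- function(junctions) {
  junctions <- as.character(junctions)
  junctions <- junctions[!is.na(junctions) & junctions != ""]
  if (length(junctions) == 0L) stop("no junction sequences supplied")
  len_tab <- table(nchar(junctions))
  lens <- as.integer(names(len_tab))
  modal <- lens[order(-as.integer(len_tab), lens)][1L]
  tie <- sum(len_tab == max(len_tab)) > 1L
  used <- junctions[nchar(junctions) == modal]
  counts <- Biostrings::consensusMatrix(Biostrings::AAStringSet(used))
  mat <- matrix(0, nrow = length(AA_STANDARD), ncol = modal,
                dimnames = list(AA_STANDARD, seq_len(modal)))
  common <- intersect(rownames(counts), AA_STANDARD)
  mat[common, ] <- counts[common, , drop = FALSE]
  mat <- sweep(mat, 2L, colSums(mat), "/")
  attr(mat, "modal_length") <- modal
  attr(mat, "n_used") <- length(used)
  attr(mat, "n_excluded") <- length(junctions) - length(used)
  attr(mat, "length_tie") <- tie
  mat
}

#' Per-cell pairing of two chains' V/J combinations
#'
#' For every cell with at least one retained contig of both loci, pairs the
#' left-locus key with the right-locus key. Cells with multiple contigs of
#' one locus contribute all their pairings (each distinct pairing counted
#' once per cell) and are flagged. Pairings are ranked by cell count.
#'
#' @param profiles output of [profileCells()].
#' @param cs the filtered [ContigSet-class] behind \code{profiles}.
#' @param locus_a,locus_b the two loci (left and right keys).
#' @param key \code{"VJ"} (e.g. \code{"TRAV23/TRAJ25"}) or \code{"V"}.
#' @return data.frame (key_a, key_b, cell_count) sorted by cell count, with
#'   attributes \code{"n_cells"} (contributing cells) and
#'   \code{"n_multi_chain"} (cells contributing more than one pairing).
#' @export
crossChainPairing <- function(profiles, cs, locus_a = "TRA", locus_b = "TRB",
                              key = c("VJ", "V")) {
  stopifnot(is(cs, "ContigSet"), all(c(locus_a, locus_b) %in% TR_LOCI),
            locus_a != locus_b)
  key <- match.arg(key)
  df <- contigs(cs)
  df <- df[!is.na(df$locus) & df$locus %in% c(locus_a, locus_b) &
             !is.na(df$v_gene), , drop = FALSE]
  mk_key <- function(d) {
    if (key == "VJ") paste(d$v_gene, d$j_gene, sep = "/") else d$v_gene
  }
  cell <- .cellKey(df$subject_id, df$barcode)
  pairs_by_cell <- lapply(split(seq_len(nrow(df)), cell), function(i) {
    d <- df[i, , drop = FALSE]
    ka <- unique(mk_key(d[d$locus == locus_a, , drop = FALSE]))
    kb <- unique(mk_key(d[d$locus == locus_b, , drop = FALSE]))
    if (length(ka) == 0L || length(kb) == 0L) return(NULL)
    expand.grid(key_a = ka, key_b = kb, stringsAsFactors = FALSE)
  })
  pairs_by_cell <- Filter(Negate(is.null), pairs_by_cell)
  if (length(pairs_by_cell) == 0L) {
    out <- data.frame(key_a = character(), key_b = character(),
                      cell_count = integer())
    attr(out, "n_cells") <- 0L
    attr(out, "n_multi_chain") <- 0L
    return(out)
  }
  all_pairs <- do.call(rbind, pairs_by_cell)
  tab <- table(paste(all_pairs$key_a, all_pairs$key_b, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    key_a = vapply(parts, `[`, character(1L), 1L),
    key_b = vapply(parts, `[`, character(1L), 2L),
    cell_count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$cell_count, out$key_a, out$key_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_cells") <- length(pairs_by_cell)
  attr(out, "n_multi_chain") <- sum(vapply(pairs_by_cell, nrow, integer(1L)) > 1L)
  out
}
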