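# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk except temp files written here.

GD <- GD_LABEL

# One contig row with sensible defaults; gene calls follow the locus.
contigRow <- function(contig_id, barcode, subject = "cat1", locus = "TRB",
                      v = paste0(locus, "V1"), d = NA_character_,
                      j = paste0(locus, "J1"), cg = paste0(locus, "C1"),
                      junc = "CASSLGQGAF", junc_nt = NA_character_,
                      productive = TRUE, is_cell = TRUE, high_conf = TRUE,
                      umis = 2L, subset = NA_character_) {
  data.frame(contig_id = contig_id, barcode = barcode, subject_id = subject,
             locus = locus, v_gene = v, d_gene = d, j_gene = j, c_gene = cg,
             junction_aa = junc, junction_nt = junc_nt,
             productive = productive, is_cell = is_cell,
             high_confidence = high_conf, umis = umis, subset_label = subset,
             stringsAsFactors = FALSE)
}

makeContigSet <- function(...) {
  ContigSet(do.call(rbind, list(...)))
}

# A single-pair (1 TRD + 1 TRG) cell: two contigs.
pairCell <- function(barcode, subject, trd_v, trg_v, trd_junc, trg_junc,
                     trd_j = "TRDJ1", trg_j = "TRGJ1-1", subset = GD) {
  rbind(
    contigRow(paste0(barcode, "_d"), barcode, subject, "TRD", v = trd_v,
              j = trd_j, cg = "TRDC", junc = trd_junc, subset = subset),
    contigRow(paste0(barcode, "_g"), barcode, subject, "TRG", v = trg_v,
              j = trg_j, cg = "TRGC1", junc = trg_junc, subset = subset)
  )
}

randomJunctions <- function(n, len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  unique(vapply(seq_len(n * 2L), function(i)
    paste(c("C", sample(aa, len - 2L, replace = TRUE), "F"), collapse = ""),
    character(1L)))[seq_len(n)]
}

# The TCR-defined gamma-delta cohort: 154 cells with a single productive
# TRD and TRG rearrangement each (127 labelled gamma-delta, 20 CD4+ TEM,
# 7 CD8+ cytotoxic; among them the 19-cell TRDV4/TRGV5-3 invariant stratum
# with 18 CD4+ TEM labels), plus 40 non-qualifying cells.
makeConcordanceFixture <- function() {
  subjects <- paste0("cat", 1:4)
  rows <- list()
  trg_inv <- c(rep("CACWDESGWIKIF", 16L),
               "CACWDGSGWIKIF", "CACWDKSGWIKIF", "CACWDHESGWIKIF")
  inv_labels <- c(rep("CD4+ TEM", 18L), GD)
  for (i in 1:19) {
    rows[[length(rows) + 1L]] <- pairCell(
      sprintf("INV%03d-1", i), subjects[(i - 1L) %% 4L + 1L],
      "TRDV4", "TRGV5-3", "CASDIGGSSWDTRQMFF", trg_inv[i],
      trd_j = "TRDJ3", trg_j = "TRGJ5-1", subset = inv_labels[i])
  }
  bg_labels <- c(rep(GD, 126L), rep("CD4+ TEM", 2L),
                 rep("CD8+ cytotoxic", 7L))
  trd_vs <- c("TRDV3", "TRDV5-1", "TRDV5-2", "TRDV5-3")
  trg_vs <- c("TRGV2-1", "TRGV2-2", "TRGV2-4")
  set.seed(42L)
  trd_juncs <- randomJunctions(135L, 15L)
  trg_juncs <- randomJunctions(135L, 14L)
  for (i in 1:135) {
    rows[[length(rows) + 1L]] <- pairCell(
      sprintf("BG%03d-1", i), subjects[(i - 1L) %% 4L + 1L],
      trd_vs[(i - 1L) %% 4L + 1L], trg_vs[(i - 1L) %% 3L + 1L],
      trd_juncs[i], trg_juncs[i], subset = bg_labels[i])
  }
  # non-qualifying: 20 cells with 2 TRG + 1 TRD, 10 TRD-only, 10 TRA/TRB
  for (i in 1:20) {
    bc <- sprintf("NQ2G%03d-1", i)
    rows[[length(rows) + 1L]] <- rbind(
      pairCell(bc, subjects[(i - 1L) %% 4L + 1L], "TRDV3", "TRGV2-1",
               randomJunctions(1L, 15L), randomJunctions(1L, 14L)),
      contigRow(paste0(bc, "_g2"), bc, subjects[(i - 1L) %% 4L + 1L], "TRG",
                v = "TRGV2-2", cg = "TRGC1", junc = randomJunctions(1L, 13L),
                subset = GD))
  }
  for (i in 1:10) {
    rows[[length(rows) + 1L]] <- contigRow(
      sprintf("NQD%03d-1_d", i), sprintf("NQD%03d-1", i),
      subjects[(i - 1L) %% 4L + 1L], "TRD", cg = "TRDC",
      junc = randomJunctions(1L, 16L), subset = GD)
  }
  for (i in 1:10) {
    bc <- sprintf("NQAB%03d-1", i)
    s <- subjects[(i - 1L) %% 4L + 1L]
    rows[[length(rows) + 1L]] <- rbind(
      contigRow(paste0(bc, "_a"), bc, s, "TRA", cg = "TRAC",
                junc = randomJunctions(1L, 13L), subset = "CD4+ naive"),
      contigRow(paste0(bc, "_b"), bc, s, "TRB", cg = "TRBC1",
                junc = randomJunctions(1L, 14L), subset = "CD4+ naive"))
  }
  ContigSet(do.call(rbind, rows))
}

# Alpha/beta cells reproducing the three dominant TRA/TRB V-J pairings
# (51, 35 and 27 cells) over a small diverse background.
makePairingFixture <- function() {
  mk <- function(n, prefix, av, aj, bv, bj) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      bc <- sprintf("%s%03d-1", prefix, i)
      rbind(
        contigRow(paste0(bc, "_a"), bc, "cat1", "TRA", v = av, j = aj,
                  cg = "TRAC", junc = randomJunctions(1L, 13L),
                  subset = "CD8+ cytotoxic"),
        contigRow(paste0(bc, "_b"), bc, "cat1", "TRB", v = bv, j = bj,
                  cg = "TRBC1", junc = randomJunctions(1L, 14L),
                  subset = "CD8+ cytotoxic"))
    }))
  }
  set.seed(7L)
  bg <- do.call(rbind, lapply(1:15, function(i) {
    mk(1L, sprintf("BGP%02d", i), sprintf("TRAV%d", i), sprintf("TRAJ%d", i),
       sprintf("TRBV%d", i), sprintf("TRBJ1-%d", i %% 6L + 1L))
  }))
  ContigSet(rbind(
    mk(51L, "P1C", "TRAV23", "TRAJ25", "TRBV25", "TRBJ2-6"),
    mk(35L, "P2C", "TRAV25", "TRAJ41", "TRBV25", "TRBJ2-6"),
    mk(27L, "P3C", "TRAV8-6", "TRAJ30", "TRBV4-2", "TRBJ2-6"),
    bg))
}

# Minimal clonotype table for network tests.
clonoDf <- function(junctions, locus = "TRA") {
  data.frame(locus = locus, junction_aa = junctions,
             junction_length = nchar(junctions),
             cell_count = 1L, n_subjects = 1L, subjects = "cat1",
             v_genes = "", j_genes = "", stringsAsFactors = FALSE)
}

# Brute-force O(n^2) Hamming-1 edge oracle.
bruteForceEdges <- function(junctions) {
  junctions <- sort(unique(junctions))
  n <- length(junctions)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      a <- junctions[i]; b <- junctions[j]
      if (nchar(a) != nchar(b)) next
      d <- sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
      if (d == 1L) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = character(), to = character()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(from = pmin(m[, 1L], m[, 2L]),
                   to = pmax(m[, 1L], m[, 2L]), stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), ]
  rownames(df) <- NULL
  df
}

# Canonicalise an edge data.frame for comparison.
sortedEdges <- function(df) {
  out <- data.frame(from = pmin(df$from, df$to), to = pmax(df$from, df$to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  out
}

# Minimal 10x all_contig_annotations.csv writer.
writeTenxCsv <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE)
  path
}

tenxRow <- function(barcode, contig_id, chain, v, d, j, cg, cdr3, cdr3_nt = "",
                    productive = "True", is_cell = "True", high_conf = "True",
                    umis = 3L) {
  data.frame(barcode = barcode, is_cell = is_cell, contig_id = contig_id,
             high_confidence = high_conf, length = 500L, chain = chain,
             v_gene = v, d_gene = d, j_gene = j, c_gene = cg,
             full_length = "True", productive = productive, cdr3 = cdr3,
             cdr3_nt = cdr3_nt, reads = 100L, umis = umis,
             raw_clonotype_id = "clonotype1", stringsAsFactors = FALSE)
}
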