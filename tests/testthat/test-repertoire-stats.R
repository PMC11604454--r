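test_that("clonotypes are keyed by (locus, junction)", {
  cs <- makeContigSet(
    contigRow("c1", "b1", subject = "cat1", locus = "TRB", junc = "CASSF"),
    contigRow("c2", "b2", subject = "cat2", locus = "TRB", junc = "CASSF"),
    contigRow("c3", "b3", subject = "cat1", locus = "TRA", cg = "TRAC",
              junc = "CASSF"),  # same junction, other locus
    contigRow("c4", "b4", subject = "cat1", locus = "TRB", junc = "CASRF"),
    contigRow("c5", "b5", subject = "cat1", locus = "TRB", junc = NA)
  )
  cl <- defineClonotypes(cs)
  expect_equal(nrow(cl), 3L)
  shared <- cl[cl$junction_aa == "CASSF" & cl$locus == "TRB", ]
  expect_equal(shared$cell_count, 2L)
  expect_equal(shared$n_subjects, 2L)
  expect_equal(nrow(cl[cl$junction_aa == "CASSF", ]), 2L)
  expect_equal(attr(cl, "n_excluded"), 1L)
  # cell counts per locus sum to distinct (cell, junction) pairs
  df <- contigs(cs)
  df <- df[!is.na(df$junction_aa), ]
  pairs <- unique(paste(df$subject_id, df$barcode, df$locus, df$junction_aa))
  expect_equal(sum(cl$cell_count), length(pairs))
})

test_that("junction lengths match the printed invariant sequences", {
  expect_equal(junctionLength("CASDIGGSSWDTRQMFF"), 17L)
  expect_equal(junctionLength("CACWDESGWIKIF"), 13L)
  expect_equal(junctionLength("CAAWDPRGYGWAHKVF"), 16L)
  expect_error(junctionLength(""), "empty")
  expect_error(junctionLength(character(0)), "empty")
})

test_that("edit distance is unit-cost Levenshtein", {
  expect_equal(editDistance("CACWDESGWIKIF", "CACWDHESGWIKIF"), 1L)
  expect_equal(editDistance("CACWDESGWIKIF", "CACWDESGWIKIF"), 0L)
  expect_equal(editDistance("AAA", "TTT"), 3L)
  expect_equal(editDistance(c("AB", "AB"), c("AB", "BA")), c(0L, 2L))
  expect_error(editDistance("", "A"), "empty")
})

test_that("gene usage percentages are per group over locus contigs", {
  cs <- makeContigSet(
    contigRow("c1", "b1", locus = "TRB", v = "TRBV25", subset = "S"),
    contigRow("c2", "b2", locus = "TRB", v = "TRBV25", subset = "S"),
    contigRow("c3", "b3", locus = "TRB", v = "TRBV25", subset = "S"),
    contigRow("c4", "b4", locus = "TRB", v = "TRBV4-2", subset = "S"),
    contigRow("c5", "b5", locus = "TRA", v = "TRAV23", cg = "TRAC", subset = "S")
  )
  u <- geneUsage(cs, "V", "TRB")
  expect_equal(setNames(u$percent, u$gene), c("TRBV25" = 75, "TRBV4-2" = 25))
  # one contig -> 100% for its gene; TRA contigs not in the TRB denominator
  ua <- geneUsage(cs, "V", "TRA")
  expect_equal(ua$percent, 100)
  # zero-count reporting when completing over the gene universe
  uc <- geneUsage(cs, "V", "TRB", complete = TRUE)
  expect_true(all(c("TRBV25", "TRBV4-2") %in% uc$gene))
  sums <- tapply(u$percent, u$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("usage recovery tracks the configured V-gene skew", {
  cfg <- felinePreset(cells_per_subset = setNames(1000L, "CD4+ naive"),
                      noise = c(non_productive = 0, missing_c = 0, chimera = 0),
                      include_spikes = FALSE, seed = 5L)
  res <- generateRepertoire(cfg)
  cs <- attachMetadata(filterContigs(res$contigs), res$annotations)
  u <- geneUsage(cs, "V", "TRA", group_key = NULL)
  w <- cfg$gene_pools$TRA$V
  expected <- 100 * w / sum(w)
  got <- setNames(u$percent, u$gene)[names(expected)]
  n <- sum(u$count)
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n)
  expect_true(all(abs(got - expected) <= 3 * se))
})

test_that("V/J combination tables enumerate observed pairs", {
  cs <- makeContigSet(
    contigRow("c1", "b1", locus = "TRG", v = "TRGV2-2", j = "TRGJ2-2", cg = "TRGC1"),
    contigRow("c2", "b2", locus = "TRG", v = "TRGV2-2", j = "TRGJ2-2", cg = "TRGC1"),
    contigRow("c3", "b3", locus = "TRG", v = "TRGV2-2", j = "TRGJ2-2", cg = "TRGC1")
  )
  vj <- vjCombinations(cs, "TRG")
  expect_equal(nrow(vj), 1L)
  expect_equal(vj$count, 3L)
  expect_equal(vj$v_gene, "TRGV2-2")
  expect_equal(nrow(vjCombinations(cs, "TRD")), 0L)
  # six contigs against exhaustive enumeration
  set.seed(2L)
  rows <- do.call(rbind, lapply(1:6, function(i)
    contigRow(paste0("x", i), paste0("bb", i), locus = "TRB",
              v = sample(c("TRBV1", "TRBV2"), 1L),
              j = sample(c("TRBJ1", "TRBJ2"), 1L))))
  vj2 <- vjCombinations(ContigSet(rows), "TRB")
  manual <- table(paste(rows$v_gene, rows$j_gene))
  got <- setNames(vj2$count, paste(vj2$v_gene, vj2$j_gene))
  expect_equal(got[names(manual)], setNames(as.integer(manual), names(manual)))
  expect_equal(sum(vj2$count), 6L)
})

test_that("PWMs are per-position frequencies over modal-length junctions", {
  p1 <- buildPWM(c("AC", "AC"))
  expect_equal(p1["A", 1], 1)
  expect_equal(p1["C", 2], 1)
  p2 <- buildPWM(c("AY", "AW"))
  expect_equal(p2["Y", 2], 0.5)
  expect_equal(p2["W", 2], 0.5)
  expect_true(all(abs(colSums(p2) - 1) < 1e-9))
  # the insertion variant is excluded as off-modal-length
  juncs <- c(rep("CACWDESGWIKIF", 16L), "CACWDHESGWIKIF")
  p3 <- buildPWM(juncs)
  expect_equal(attr(p3, "modal_length"), 13L)
  expect_equal(attr(p3, "n_used"), 16L)
  expect_equal(attr(p3, "n_excluded"), 1L)
  # a single sequence yields a unit entry per column
  p4 <- buildPWM("CASDIGGSSWDTRQMFF")
  expect_true(all(apply(p4, 2, max) == 1))
  expect_true(all(colSums(p4) == 1))
  expect_error(buildPWM(character(0)), "no junction")
})

test_that("cross-chain pairing ranks the dominant TRA/TRB combinations", {
  cs <- makePairingFixture()
  p <- profileCells(cs)
  pairs <- crossChainPairing(p, cs, "TRA", "TRB", key = "VJ")
  expect_equal(pairs$key_a[1], "TRAV23/TRAJ25")
  expect_equal(pairs$key_b[1], "TRBV25/TRBJ2-6")
  expect_equal(pairs$cell_count[1], 51L)
  expect_equal(pairs$cell_count[2:3], c(35L, 27L))
  # one cell with one TRA and one TRB -> a single row of count 1
  solo <- makeContigSet(
    contigRow("s1", "z1", locus = "TRA", v = "TRAV9", j = "TRAJ9", cg = "TRAC"),
    contigRow("s2", "z1", locus = "TRB", v = "TRBV9", j = "TRBJ9"))
  ps <- crossChainPairing(profileCells(solo), solo, "TRA", "TRB")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$cell_count, 1L)
})

test_that("pairing equals the brute-force per-cell cross product", {
  set.seed(9L)
  rows <- list()
  for (i in 1:20) {
    bc <- sprintf("rc%02d", i)
    n_a <- sample(1:2, 1L)
    n_b <- sample(1:2, 1L)
    for (k in seq_len(n_a)) {
      rows[[length(rows) + 1L]] <- contigRow(
        paste0(bc, "_a", k), bc, locus = "TRA",
        v = sample(c("TRAV1", "TRAV2", "TRAV3"), 1L),
        j = sample(c("TRAJ1", "TRAJ2"), 1L), cg = "TRAC",
        junc = randomJunctions(1L, 12L))
    }
    for (k in seq_len(n_b)) {
      rows[[length(rows) + 1L]] <- contigRow(
        paste0(bc, "_b", k), bc, locus = "TRB",
        v = sample(c("TRBV1", "TRBV2"), 1L),
        j = sample(c("TRBJ1", "TRBJ2"), 1L),
        junc = randomJunctions(1L, 13L))
    }
  }
  df <- do.call(rbind, rows)
  cs <- ContigSet(df)
  got <- crossChainPairing(profileCells(cs), cs, "TRA", "TRB", key = "VJ")
  # oracle: per-cell cross product of unique VJ keys, counted over cells
  oracle <- new.env()
  for (bc in unique(df$barcode)) {
    d <- df[df$barcode == bc, ]
    ka <- unique(paste(d$v_gene[d$locus == "TRA"], d$j_gene[d$locus == "TRA"],
                       sep = "/"))
    kb <- unique(paste(d$v_gene[d$locus == "TRB"], d$j_gene[d$locus == "TRB"],
                       sep = "/"))
    for (a in ka) for (b in kb) {
      key <- paste(a, b)
      oracle[[key]] <- (if (is.null(oracle[[key]])) 0L else oracle[[key]]) + 1L
    }
  }
  got_keys <- paste(got$key_a, got$key_b)
  expect_setequal(got_keys, ls(oracle))
  for (k in got_keys) {
    expect_equal(got$cell_count[got_keys == k], oracle[[k]], info = k)
  }
  # when every cell has one contig per locus, total equals cell count
  cs2 <- makePairingFixture()
  p2 <- crossChainPairing(profileCells(cs2), cs2, "TRA", "TRB")
  expect_equal(sum(p2$cell_count), attr(p2, "n_cells"))
})
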