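test_that("10x contig tables parse with per-chain locus outcomes", {
  rows <- rbind(
    tenxRow("AAAA-1", "c1", "TRA", "TRAV23", "None", "TRAJ25", "TRAC", "CAVNTGGFKTIF"),
    tenxRow("AAAA-1", "c2", "TRB", "TRBV25", "TRBD1", "TRBJ2-6", "TRBC1", "casslgqgaf"),
    tenxRow("AAAB-1", "c3", "TRG", "TRGV2-2", "None", "TRGJ2-2", "TRGC1", "CAAWDPRGYGWAHKVF"),
    tenxRow("AAAB-1", "c4", "TRD", "TRDV4", "TRDD3", "TRDJ3", "TRDC", "CASDIGGSSWDTRQMFF"),
    tenxRow("AAAC-1", "c5", "Multi", "TRAV1", "None", "TRBJ1-1", "TRBC1", "None"),
    tenxRow("AAAC-1", "c6", "None", "None", "None", "None", "None", "None",
            productive = "False", is_cell = "false", high_conf = "TRUE")
  )
  tf <- writeTenxCsv(tempfile(fileext = ".csv"), rows)
  cs <- readContigTable(tf, "tenx_csv", subject_id = "cat1")
  df <- contigs(cs)
  expect_s4_class(cs, "ContigSet")
  expect_equal(nrow(df), 6L)
  expect_equal(provenance(cs)$sources, tf)
  expect_equal(df$locus, c("TRA", "TRB", "TRG", "TRD", NA, NA))
  # junctions upper-cased, "None" becomes absent
  expect_equal(df$junction_aa[2], "CASSLGQGAF")
  expect_true(is.na(df$junction_aa[5]))
  # booleans parsed case-insensitively
  expect_false(df$productive[6])
  expect_false(df$is_cell[6])
  expect_true(df$high_confidence[6])
  # the Multi-chain row survives reading but not filtering
  kept <- contigs(filterContigs(cs, requireCell = FALSE))
  expect_false("c5" %in% kept$contig_id)
})

test_that("schema violations and empty files are reported", {
  rows <- tenxRow("AAAA-1", "c1", "TRA", "TRAV1", "None", "TRAJ1", "TRAC", "CAF")
  rows$chain <- NULL
  tf <- writeTenxCsv(tempfile(fileext = ".csv"), rows)
  expect_error(readContigTable(tf, "tenx_csv"), "chain")
  tf2 <- tempfile(fileext = ".csv")
  writeLines(paste(names(tenxRow("x", "c", "TRA", "V", "D", "J", "C", "CAF")),
                   collapse = ","), tf2)
  expect_warning(cs <- readContigTable(tf2, "tenx_csv"), "empty")
  expect_equal(length(cs), 0L)
  expect_error(readContigTable(tempfile(), "tenx_csv"), "not found")
})

test_that("filter retains productive, complete, locus-concordant contigs", {
  # 10 contigs: 2 non-productive, 1 missing C, 1 inter-locus chimera
  rows <- rbind(
    contigRow("k1", "b1", locus = "TRB"),
    contigRow("k2", "b1", locus = "TRA", cg = "TRAC", junc = "CAVF"),
    contigRow("k3", "b2", locus = "TRG", cg = "TRGC1", junc = "CACWDF"),
    contigRow("k4", "b2", locus = "TRD", cg = "TRDC", junc = "CASDF"),
    contigRow("k5", "b3", locus = "TRB"),
    contigRow("k6", "b3", locus = "TRB"),
    contigRow("np1", "b4", locus = "TRB", productive = FALSE),
    contigRow("np2", "b4", locus = "TRA", cg = "TRAC", productive = FALSE),
    contigRow("mc1", "b5", locus = "TRB", cg = NA),
    contigRow("ch1", "b5", locus = "TRB", v = "TRAV2", cg = "TRBC1")
  )
  cs <- ContigSet(rows)
  out <- filterContigs(cs)
  log <- filterLog(out)
  expect_equal(length(out), 6L)
  expect_equal(log$removed[log$rule == "non_productive"], 2L)
  expect_equal(log$removed[log$rule == "missing_vjc"], 1L)
  expect_equal(log$removed[log$rule == "interlocus_chimera"], 1L)
  # conservation: retained + removed = input
  expect_equal(length(out) + sum(log$removed), length(cs))
  # idempotence
  twice <- filterContigs(out)
  expect_identical(contigs(twice), contigs(out))
  expect_equal(sum(filterLog(twice)$removed), sum(log$removed))
})

test_that("productive chimeras with mixed-locus calls are removed", {
  cs <- makeContigSet(
    contigRow("ok", "b1", locus = "TRB", v = "TRBV2", j = "TRBJ1", cg = "TRBC1"),
    contigRow("chi", "b2", locus = "TRB", v = "TRAV2", j = "TRBJ1", cg = "TRBC1")
  )
  out <- filterContigs(cs)
  expect_equal(contigs(out)$contig_id, "ok")
})

test_that("tenx -> AIRR -> internal round-trip preserves contig calls", {
  rows <- rbind(
    tenxRow("AAAA-1", "c1", "TRD", "TRDV4", "TRDD3", "TRDJ3", "TRDC",
            "CASDIGGSSWDTRQMFF", cdr3_nt = paste(rep("TGC", 17), collapse = "")),
    tenxRow("AAAB-1", "c2", "TRG", "TRGV5-3", "None", "TRGJ5-1", "TRGC1",
            "CACWDESGWIKIF"),
    tenxRow("AAAC-1", "c3", "Multi", "TRAV1", "None", "TRBJ1-1", "None", "None",
            productive = "False")
  )
  tf <- writeTenxCsv(tempfile(fileext = ".csv"), rows)
  cs1 <- readContigTable(tf, "tenx_csv", subject_id = "cat2")
  airr <- tempfile(fileext = ".tsv")
  writeAirr(cs1, airr)
  cs2 <- readContigTable(airr, "airr_tsv")
  for (col in c("locus", "v_gene", "j_gene", "c_gene", "junction_aa",
                "productive", "barcode", "subject_id")) {
    expect_equal(contigs(cs2)[[col]], contigs(cs1)[[col]], info = col)
  }
})

test_that("metadata attachment joins on cell identity and counts misses", {
  cs <- makeContigSet(
    contigRow("c1", "b1", subject = "cat1"),
    contigRow("c2", "b2", subject = "cat1"),
    contigRow("c3", "b1", subject = "cat2")  # same barcode, other subject
  )
  ann <- data.frame(
    barcode = c("b1", "b1"), subject_id = c("cat1", "cat2"),
    subset_label = c("CD4+ naive", GD), stringsAsFactors = FALSE)
  out <- attachMetadata(cs, ann)
  expect_equal(contigs(out)$subset_label, c("CD4+ naive", NA, GD))
  expect_equal(provenance(out)$unmatched_barcodes, 1L)
  dup <- rbind(ann, ann[1, ])
  expect_error(attachMetadata(cs, dup), "duplicate")
})

test_that("filter report serialises the provenance as JSON", {
  cs <- filterContigs(makeContigSet(
    contigRow("c1", "b1"),
    contigRow("c2", "b2", productive = FALSE)))
  out <- tempfile(fileext = ".json")
  writeFilterReport(cs, out)
  rep <- jsonlite::read_json(out)
  expect_equal(rep$retained, 1L)
  expect_equal(rep$removed$non_productive, 1L)
})

test_that("contig sets validate their invariants", {
  expect_error(ContigSet(contigRow("c1", "b1", locus = "TRX")), "locus")
  expect_error(ContigSet(contigRow("c1", "b1", umis = -1L)), "umis")
  expect_error(
    ContigSet(rbind(contigRow("c1", "b1"), contigRow("c1", "b2"))),
    "duplicated contig_id")
  # junction_aa longer than its nucleotide sequence allows is inconsistent
  expect_error(ContigSet(contigRow("c1", "b1", junc = "CASSF",
                                   junc_nt = "TGCGCA")), "junction")
})
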