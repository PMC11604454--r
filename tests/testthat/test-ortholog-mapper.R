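homologyRow <- function(src, sym, class = "one2one", conf = 1,
                        goc = NA_real_, wga = 50, pq = 50, pt = 50,
                        tgt = "ENSG00000000001") {
  data.frame(source_gene_id = src, target_gene_id = tgt, target_symbol = sym,
             homology_class = class, orthology_confidence = conf,
             gene_order_confidence = goc, whole_genome_alignment = wga,
             pct_query_identical_target = pq, pct_target_identical_query = pt,
             stringsAsFactors = FALSE)
}

writeHomologyTsv <- function(records) {
  tf <- tempfile(fileext = ".tsv")
  write.table(records, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf
}

test_that("homology tables load, validate and keep absent fields absent", {
  recs <- rbind(
    homologyRow("ENSFCAG01", "TP53"),
    homologyRow("ENSFCAG02", "MYC", class = "one2many", goc = 75),
    homologyRow("ENSFCAG03", "MYC", class = "one2many")
  )
  loaded <- loadHomologyTable(writeHomologyTsv(recs))
  expect_equal(nrow(loaded), 3L)
  expect_true(is.na(loaded$gene_order_confidence[1]))
  expect_equal(loaded$gene_order_confidence[2], 75)
  bad_col <- recs[, setdiff(names(recs), "homology_class")]
  expect_error(loadHomologyTable(writeHomologyTsv(bad_col)), "homology_class")
  bad_pct <- homologyRow("ENSFCAG04", "X", pq = 120)
  expect_error(loadHomologyTable(writeHomologyTsv(rbind(recs, bad_pct))),
               "row\\(s\\): 4")
  bad_class <- homologyRow("ENSFCAG05", "X", class = "paralog")
  expect_error(validateHomologyRecords(rbind(recs, bad_class)), "homology_class")
})

test_that("one-to-one orthologs map directly", {
  recs <- homologyRow("ENSFCAG01", "TP53")
  map <- resolveSymbols(recs, c("ENSFCAG01", "GAPDH"))
  expect_equal(symbolEntries(map), c(ENSFCAG01 = "TP53"))
  rep <- mappingReport(map)
  expect_equal(rep$already_symboled, 1L)  # GAPDH is left alone
  expect_equal(rep$newly_mapped, 1L)
  expect_equal(rep$unresolved, 0L)
})

test_that("contested symbols are resolved by the priority field order", {
  # first field decides: orthology confidence 1 beats 0
  recs <- rbind(
    homologyRow("ENSFCAG01", "MYC", class = "many2many", conf = 0,
                goc = 99, wga = 99, pq = 99, pt = 99),
    homologyRow("ENSFCAG02", "MYC", class = "many2many", conf = 1,
                goc = 1, wga = 1, pq = 1, pt = 1))
  map <- resolveSymbols(recs, recs$source_gene_id)
  expect_equal(symbolEntries(map), c(ENSFCAG02 = "MYC"))
  # tie on the first two fields: whole-genome alignment 90 beats 70
  recs2 <- rbind(
    homologyRow("ENSFCAG03", "FOS", class = "one2many", conf = 1, goc = 50,
                wga = 90, pq = 1, pt = 1),
    homologyRow("ENSFCAG04", "FOS", class = "one2many", conf = 1, goc = 50,
                wga = 70, pq = 99, pt = 99))
  map2 <- resolveSymbols(recs2, recs2$source_gene_id)
  expect_equal(symbolEntries(map2), c(ENSFCAG03 = "FOS"))
  # absent values rank below any present value
  recs3 <- rbind(
    homologyRow("ENSFCAG05", "JUN", class = "one2many", conf = 1, goc = NA),
    homologyRow("ENSFCAG06", "JUN", class = "one2many", conf = 1, goc = 0.5))
  map3 <- resolveSymbols(recs3, recs3$source_gene_id)
  expect_equal(symbolEntries(map3), c(ENSFCAG06 = "JUN"))
  # full tie breaks on the source gene id, deterministically
  recs4 <- rbind(
    homologyRow("ENSFCAG08", "ATF4", class = "one2many", conf = 1, goc = 5),
    homologyRow("ENSFCAG07", "ATF4", class = "one2many", conf = 1, goc = 5))
  map4 <- resolveSymbols(recs4, recs4$source_gene_id)
  expect_equal(symbolEntries(map4), c(ENSFCAG07 = "ATF4"))
})

test_that("resolution matches the brute-force oracle and ignores row order", {
  for (seed in c(1L, 2L, 3L)) {
    fx <- generateHomologyFixture(20L, 15L, seed = seed)
    map <- resolveSymbols(fx$records, fx$features)
    expect_identical(symbolEntries(map), fx$expected)
    # order independence: shuffled rows and shuffled features
    set.seed(seed + 100L)
    shuffled <- fx$records[sample.int(nrow(fx$records)), ]
    map2 <- resolveSymbols(shuffled, sample(fx$features))
    expect_identical(symbolEntries(map2), fx$expected)
  }
})

test_that("symbol collisions are uniquified by suffixing", {
  recs <- rbind(
    homologyRow("ENSFCAG01", "DUP", tgt = "ENSG01"),
    homologyRow("ENSFCAG02", "DUP", tgt = "ENSG02"))
  map <- resolveSymbols(recs, recs$source_gene_id)
  entries <- symbolEntries(map)
  expect_equal(sort(unname(entries)), c("DUP", "DUP.1"))
  expect_false(anyDuplicated(entries) > 0L)
})

test_that("per-source direction assigns each gene its best target symbol", {
  recs <- rbind(
    homologyRow("ENSFCAG01", "A1", class = "one2many", conf = 0),
    homologyRow("ENSFCAG01", "A2", class = "one2many", conf = 1))
  map <- resolveSymbols(recs, "ENSFCAG01", direction = "per_source")
  expect_equal(symbolEntries(map), c(ENSFCAG01 = "A2"))
})

test_that("feature renaming applies the map, then manual overrides", {
  fx <- generateHomologyFixture(60L, 0L, seed = 4L)
  extra <- sprintf("ENSFCAG9%010d", 1:40)  # unmappable gene ids
  features <- c(fx$features, extra)
  map <- resolveSymbols(fx$records, features)
  rep <- mappingReport(map)
  expect_equal(rep$input_features, 100L)
  expect_equal(rep$newly_mapped, 60L)
  expect_equal(rep$unresolved, 40L)
  expect_equal(rep$already_symboled + rep$newly_mapped + rep$unresolved, 100L)
  overrides <- data.frame(
    source_gene_id = c(extra[1], extra[2], fx$features[1], "ENSFCAG_MISSING"),
    action = c("rename:MANUAL1", "drop", "keep", "drop"),
    stringsAsFactors = FALSE)
  expect_warning(out <- renameFeatures(features, map, overrides), "unknown")
  expect_equal(out$report$dropped, 1L)
  expect_equal(out$report$override_renamed, 1L)
  expect_equal(out$report$kept, 1L)
  expect_equal(length(out$features), 99L)
  expect_true("MANUAL1" %in% out$features)
  expect_true(fx$features[1] %in% out$features)    # kept original id
  expect_false(extra[2] %in% out$features)          # dropped
  # order preserved for untouched features
  expect_equal(out$features[length(out$features)], extra[40])
})
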