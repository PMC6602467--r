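## Constructed predictor files covering every reconciliation branch.

write_scan_a <- function(rows) {
  hdr <- c("Sequence\t\ttRNA\tBounds", "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
           "--------\t------\t-----")
  tmp <- tempfile(fileext = ".out")
  writeLines(c(hdr, rows), tmp)
  tmp
}

write_scan_b <- function(rows) {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c(">genome", sprintf("%d genes found", length(rows)), rows), tmp)
  tmp
}

test_that("tRNAscan-SE tabular parsing handles strand and introns", {
  p <- parse_trnascan(write_scan_a(c(
    "g\t1\t100\t172\tHis\tGTG\t0\t0\t55.0",
    "g\t2\t400\t320\tGln\tTTG\t380\t350\t60.2")))
  expect_equal(nrow(p), 2L)
  expect_equal(p$strand, c("+", "-"))
  expect_equal(p$name, c("trnH-GUG", "trnQ-UUG"))
  expect_equal(p$start[2L], 320L)                 # coordinates normalized
  expect_equal(c(p$intron_start[2L], p$intron_end[2L]), c(350L, 380L))
  expect_true(is.na(p$intron_start[1L]))
})

test_that("ARAGORN batch parsing handles complement and intron tokens", {
  p <- parse_aragorn(write_scan_b(c(
    "1   tRNA-Ala(tgc)   [1000,1233]   33   (tgc)   i(39,160)",
    "2   tRNA-Ile(gat)   c[2000,2251]   33   (gat)")))
  expect_equal(p$name, c("trnA-UGC", "trnI-GAU"))
  expect_equal(p$strand, c("+", "-"))
  expect_equal(p$intron_start[1L], 1038L)
  expect_equal(p$intron_end[1L], 1197L)
  expect_true(is.na(p$intron_start[2L]))
})

test_that("the reconciliation truth table holds on constructed inputs", {
  a <- parse_trnascan(write_scan_a(c(
    "g\t1\t100\t172\tHis\tGTG\t0\t0\t55.0",     # intronless, no b: kept from a
    "g\t2\t1000\t1233\tAla\tTGC\t0\t0\t50.0",   # same locus as b's intron form
    "g\t3\t5000\t5100\tLeu\tTAA\t5040\t5060\t45.0"))) # a intron, no b: dropped
  b <- parse_aragorn(write_scan_b(c(
    "1   tRNA-Ala(tgc)   [1000,1233]   33   (tgc)   i(39,160)",  # intron: kept
    "2   tRNA-Gly(gcc)   [3000,3071]   33   (gcc)")))            # b intronless: not kept
  models <- reconcile_trna(a, b)
  nms <- vapply(models, function(m) m$name, character(1L))
  expect_setequal(nms, c("trnH-GUG", "trnA-UGC"))
  ala <- models[[which(nms == "trnA-UGC")]]
  expect_equal(attr(ala, "pred_source"), "scanner_b")    # intron => b wins
  expect_length(ala$exons, 2L)
  expect_equal(ala$exons[[1L]]$interval$end, 1037L)
  expect_equal(ala$exons[[2L]]$interval$start, 1198L)
  his <- models[[which(nms == "trnH-GUG")]]
  expect_length(his$exons, 1L)
  expect_equal(attr(his, "pred_source"), "scanner_a")
  ## the dropped scanner-a intron prediction left a warning
  w <- attr(models, "warnings")
  expect_true(any(grepl("trnL-UAA", w$subject)))
  ## no model ever carries an intron sourced from scanner a
  for (m in models) {
    if (length(m$exons) > 1L) expect_equal(attr(m, "pred_source"), "scanner_b")
  }
})

test_that("reconciliation is order-independent and total on empty input", {
  a <- parse_trnascan(write_scan_a(c(
    "g\t1\t100\t172\tHis\tGTG\t0\t0\t55.0",
    "g\t2\t1000\t1233\tAla\tTGC\t0\t0\t50.0")))
  b <- parse_aragorn(write_scan_b(
    "1   tRNA-Ala(tgc)   [1000,1233]   33   (tgc)   i(39,160)"))
  m1 <- reconcile_trna(a, b)
  m2 <- reconcile_trna(a[rev(seq_len(nrow(a))), ], b)
  expect_identical(vapply(m1, model_key, character(1L)),
                   vapply(m2, model_key, character(1L)))
  expect_length(reconcile_trna(plastannot:::empty_trna_predictions(),
                               plastannot:::empty_trna_predictions()), 0L)
})

test_that("fixture predictor files reconcile to the planted tRNA roster", {
  tr <- default_fixture()
  ff <- default_fixture_files()
  models <- reconcile_trna(parse_trnascan(ff$a), parse_aragorn(ff$b))
  truth <- Filter(function(m) m$kind == "tRNA", tr$annotation$models)
  strip_copy <- function(m) { m$copy <- 1L; model_key(m) }
  expect_setequal(vapply(models, strip_copy, character(1L)),
                  vapply(truth, strip_copy, character(1L)))
})

test_that("name validation flags mismatches against reference tRNAs", {
  tr <- default_fixture()
  db <- default_db()
  ff <- default_fixture_files()
  models <- reconcile_trna(parse_trnascan(ff$a), parse_aragorn(ff$b))
  ## correct names: silent
  expect_equal(nrow(validate_trna_names(models, db, tr$genome)), 0L)
  ## break one name
  models[[1L]]$name <- "trnI-GAU"
  w <- validate_trna_names(models[1L], db, tr$genome)
  expect_equal(nrow(w), 1L)
  expect_match(w$message, "trnI-GAU.*differs from best reference hit")
  ## no reference tRNAs: info record, not an error
  db2 <- db
  db2$genes <- Filter(function(g) g$kind != "tRNA", db2$genes)
  w2 <- validate_trna_names(models[1L], db2, tr$genome)
  expect_equal(w2$severity, "info")
  ## empty models: empty warnings
  expect_equal(nrow(validate_trna_names(list(), db, tr$genome)), 0L)
})
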