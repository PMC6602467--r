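test_that("plastome construction validates its invariants", {
  g <- plastome("p1", "acgtn")
  expect_equal(g$sequence, "ACGTN")
  expect_equal(g$length, 5L)
  expect_true(g$circular)
  expect_error(plastome("", "ACGT"))
  expect_error(plastome("p1", "ACGTX"), "alphabet|characters")
  expect_error(plastome("p1", ""))
})

test_that("intervals enforce coordinate sanity and span arithmetic", {
  iv <- interval(10, 20, "-")
  expect_equal(interval_span(iv), 11L)
  expect_error(interval(20, 10), "start > end")
  w <- interval(95, 5, "+", wraps_origin = TRUE)
  expect_equal(interval_span(w, genome_length = 100L), 11L)
})

test_that("extract_seq honours strand and origin wrap", {
  g <- plastome("p", "AACCGGTTAA")
  expect_equal(extract_seq(g, interval(3, 6)), "CCGG")
  expect_equal(extract_seq(g, interval(3, 6, "-")), "CCGG")
  expect_equal(extract_seq(g, interval(1, 4, "-")), "GGTT")
  expect_equal(extract_seq(g, interval(9, 2, "+", wraps_origin = TRUE)), "AAAA")
})

test_that("translate_cds handles the documented cases", {
  expect_equal(as.character(translate_cds("ATGAGTTAA")), "MS")
  ## printed rpl16 exon-1 consensus translates MLS
  expect_equal(as.character(translate_cds("ATGCTTAGT")), "MLS")
  p <- translate_cds("ATGTAAATG")
  expect_true(attr(p, "internal_stop"))
  expect_equal(substr(as.character(p), 1L, 1L), "M")
  ## non-multiple-of-3 lengths translate the whole codons and flag partial
  p2 <- translate_cds("ATGAGTT")
  expect_true(attr(p2, "partial"))
  expect_equal(as.character(p2), "MS")
  ## N in a codon yields X
  expect_equal(as.character(translate_cds("ATGANT")), "MX")
})

test_that("planted inverted repeats are detected at exact boundaries", {
  tr <- default_fixture()
  lay <- detect_inverted_repeats(tr$genome)
  expect_equal(lay$ira$start, tr$layout$ira$start)
  expect_equal(lay$ira$end, tr$layout$ira$end)
  expect_equal(lay$irb$start, tr$layout$irb$start)
  expect_equal(lay$irb$end, tr$layout$irb$end)
  expect_equal(lay$lsc$start, 1L)
  expect_equal(lay$ssc$start, tr$layout$ssc$start)
  ## revcomp identity invariant
  expect_identical(extract_seq(tr$genome, lay$irb),
                   revcomp_chr(extract_seq(tr$genome,
                     interval(lay$ira$start, lay$ira$end))))
  ## LSC is the longer single-copy region
  expect_gte(interval_span(lay$lsc), interval_span(lay$ssc))
})

test_that("random sequence without inverted repeats yields absent, not error", {
  s <- rand_seq(20000, 42)
  g <- plastome("noir", s)
  expect_warning(lay <- detect_inverted_repeats(g, 1000L), "no.*inverted repeat")
  expect_null(lay)
  ## brute-force confirmation at tiny scale: no revcomp match >= 60 in 600 bp
  s2 <- rand_seq(600, 43)
  rc <- revcomp_chr(s2)
  found <- FALSE
  for (i in seq_len(600 - 59)) {
    if (grepl(substr(s2, i, i + 59), rc, fixed = TRUE)) found <- TRUE
  }
  expect_false(found)
  expect_warning(expect_null(detect_inverted_repeats(plastome("t", s2), 60L)))
})

test_that("short sequences warn and return absent", {
  g <- plastome("tiny", rand_seq(500, 1))
  expect_warning(expect_null(detect_inverted_repeats(g, 1000L)), "shorter")
})

test_that("IR detection is rotation-equivariant and handles origin wrap", {
  withr::with_seed(11, {
    filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ir <- filler(1500)
    s <- paste0(filler(4000), ir, filler(1200), revcomp_chr(ir), filler(800))
  })
  g <- plastome("rot", s)
  lay0 <- detect_inverted_repeats(g, 1000L)
  n <- g$length
  ## rotate so IRb wraps the origin: shift by k places coordinates -k mod n
  k <- lay0$irb$start + 700L
  rot <- paste0(substr(s, k + 1L, n), substr(s, 1L, k))
  lay1 <- detect_inverted_repeats(plastome("rot1", rot), 1000L)
  shift <- function(p) ((p - k - 1L) %% n) + 1L
  irs0 <- sort(c(shift(lay0$ira$start), shift(lay0$irb$start)))
  irs1 <- sort(c(lay1$ira$start, lay1$irb$start))
  expect_equal(irs0, irs1)
  expect_true(lay1$ira$wraps_origin || lay1$irb$wraps_origin)
  wrapped <- if (lay1$ira$wraps_origin) lay1$ira else lay1$irb
  expect_equal(interval_span(wrapped, n), 1500L)
})
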