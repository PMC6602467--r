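rps12_models <- function(ann) {
  Filter(function(m) m$name == "rps12", ann$models)
}

test_that("a two-IR genome yields two transcripts sharing exon 1", {
  tr <- default_fixture()
  db <- default_db()
  out <- assemble_rps12(tr$genome, db, tr$layout)
  expect_length(out, 2L)
  for (m in out) {
    expect_true(m$trans_spliced)
    expect_length(m$exons, 3L)
  }
  e1a <- out[[1L]]$exons[[1L]]$interval
  e1b <- out[[2L]]$exons[[1L]]$interval
  expect_equal(c(e1a$start, e1a$end), c(e1b$start, e1b$end))
  ## matches planted truth exactly
  truth <- rps12_models(tr$annotation)
  expect_setequal(vapply(out, model_key, character(1L)),
                  vapply(truth, model_key, character(1L)))
})

test_that("assembled transcripts are clean ORFs with a 26-bp last exon", {
  tr <- default_fixture()
  db <- default_db()
  out <- assemble_rps12(tr$genome, db, tr$layout)
  for (m in out) {
    cds <- gene_model_cds(m, tr$genome)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substr(cds, 1L, 3L), "ATG")
    expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(interval_span(m$exons[[3L]]$interval), 26L)
  }
  ## the two transcripts' IR-resident parts are reverse-complement twins
  s2a <- extract_seq(tr$genome, out[[1L]]$exons[[2L]]$interval)
  s2b <- extract_seq(tr$genome, out[[2L]]$exons[[2L]]$interval)
  expect_identical(s2a, s2b)   # both on their own coding strand
  expect_identical(
    extract_seq(tr$genome, interval(out[[1L]]$exons[[2L]]$interval$start,
                                    out[[1L]]$exons[[2L]]$interval$end)),
    revcomp_chr(extract_seq(tr$genome,
                            interval(out[[2L]]$exons[[2L]]$interval$start,
                                     out[[2L]]$exons[[2L]]$interval$end))))
})

test_that("deleting the IRb cassette leaves a single transcript", {
  tr <- default_fixture()
  db <- default_db()
  truth <- rps12_models(tr$annotation)
  irb_t <- Filter(function(m) m$transcript_id == "rps12.t2", truth)[[1L]]
  ## overwrite the IRb copy of exon 2 with random sequence
  iv <- irb_t$exons[[2L]]$interval
  s <- tr$genome$sequence
  substr(s, iv$start, iv$end) <- rand_seq(iv$end - iv$start + 1L, 500)
  g <- plastome("oneir", s)
  out <- suppressWarnings(assemble_rps12(g, db, NULL))
  expect_length(out, 1L)
  expect_length(out[[1L]]$exons, 3L)
  expect_equal(model_key(out[[1L]]),
               model_key(Filter(function(m) m$transcript_id == "rps12.t1",
                                truth)[[1L]]))
})

test_that("two-exon rps12 references assemble without exon-3 warnings", {
  ## genuinely two-exon case: a 375-bp ORF split 114 + 261, exon 1 on the
  ## minus strand far from the plus-strand exon 2
  cds <- withr::with_seed(77, {
    codons <- setdiff(as.vector(outer(as.vector(outer(
      c("A","C","G","T"), c("A","C","G","T"), paste0)),
      c("A","C","G","T"), paste0)), c("TAA","TAG","TGA"))
    paste0("ATG", paste(sample(codons, 123, TRUE), collapse = ""), "TAA")
  })
  e1 <- substr(cds, 1, 114); e2 <- substr(cds, 115, 375)
  g <- plastome("mini12", paste0(rand_seq(600, 78), revcomp_chr(e1),
                                 rand_seq(900, 79), e2, rand_seq(500, 80)))
  db <- structure(list(
    genes = list(list(name = "rps12", kind = "CDS",
                      exons = list(list(sequence = e1, ordinal = 1L),
                                   list(sequence = e2, ordinal = 2L)),
                      cds = cds, protein = NA_character_,
                      internal_stop = FALSE, trans_spliced = TRUE,
                      source_accession = "mini", product = NULL)),
    genomes = list()), class = "reference_db")
  out <- expect_no_warning(assemble_rps12(g, db, NULL))
  expect_length(out, 1L)
  m <- out[[1L]]
  expect_length(m$exons, 2L)
  expect_false(m$partial_3p)
  cds_got <- gene_model_cds(m, g)
  expect_equal(cds_got, cds)
})

test_that("a missing exon 3 demotes the transcript to a 2-exon partial", {
  tr <- default_fixture()
  db <- default_db()
  ## remove the 3' anchor match by mutating both IR copies of the anchor
  truth <- rps12_models(tr$annotation)
  s <- tr$genome$sequence
  for (m in truth) {
    e3 <- m$exons[[3L]]$interval
    if (e3$strand == "+") {
      substr(s, e3$end + 1L, e3$end + 50L) <- rand_seq(50L, 501)
    } else {
      substr(s, e3$start - 50L, e3$start - 1L) <- rand_seq(50L, 502)
    }
  }
  g <- plastome("noanchor", s)
  w <- testthat::capture_warnings(out <- assemble_rps12(g, db, NULL))
  expect_true(any(grepl("exon 3 not found", w)))
  expect_gte(length(out), 1L)
  for (m in out) {
    expect_length(m$exons, 2L)
    expect_true(m$partial_3p)
  }
})
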