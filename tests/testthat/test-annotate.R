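## Helpers to fabricate chains against a fixture gene.
chain_for <- function(hsps) list(hsps = hsps, score = sum(hsps$score),
                                 strand = hsps$strand[1L])

test_that("refinement recovers a start codon the chain missed", {
  ## chain begins 3 codons (9 bp) downstream of the true ATG; the
  ## reference projection walks it back
  tr <- default_fixture()
  db <- default_db()
  ref <- plastannot:::db_genes(db, "psbA")[[1L]]
  truth <- Filter(function(m) m$name == "psbA", tr$annotation$models)[[1L]]
  iv <- truth$exons[[1L]]$interval
  h <- data.frame(query_gene = "psbA", q_start = 4L,
                  q_end = nchar(ref$protein),
                  t_start = iv$start + 9L, t_end = iv$end - 3L,
                  strand = "+", frame = 0L, score = 500, identity = 1,
                  evalue = 1e-50, stringsAsFactors = FALSE)
  m <- refine_gene_model(chain_for(h), tr$genome, ref, "translated")
  expect_equal(m$exons[[1L]]$interval$start, iv$start)
  expect_equal(m$exons[[1L]]$interval$end, iv$end)
  expect_false(m$partial_5p)
  expect_false(m$partial_3p)
})

test_that("a mis-set internal boundary snaps back to reference phase", {
  ## the two-exon atpF gene with its exon-1/exon-2 HSPs shifted so the
  ## naive boundary would sit 19 bp 3'-ward of the true junction: the
  ## projection restores the reference exon lengths exactly
  tr <- default_fixture()
  db <- default_db()
  ref <- plastannot:::db_genes(db, "atpF")[[1L]]
  truth <- Filter(function(m) m$name == "atpF", tr$annotation$models)[[1L]]
  iv1 <- truth$exons[[1L]]$interval; iv2 <- truth$exons[[2L]]$interval
  aa1 <- nchar(ref$exons[[1L]]$sequence) / 3          # 137 aa
  h <- rbind(
    data.frame(query_gene = "atpF", q_start = 1L, q_end = aa1 + 6L,
               t_start = iv1$start, t_end = iv1$end + 19L, strand = "+",
               frame = 0L, score = 250, identity = 0.95, evalue = 1e-40,
               stringsAsFactors = FALSE),
    data.frame(query_gene = "atpF", q_start = aa1 + 3L,
               q_end = nchar(ref$protein),
               t_start = iv2$start + 6L, t_end = iv2$end - 3L, strand = "+",
               frame = 0L, score = 250, identity = 0.95, evalue = 1e-40,
               stringsAsFactors = FALSE))
  m <- refine_gene_model(chain_for(h), tr$genome, ref, "translated")
  expect_equal(m$exons[[1L]]$interval$end, iv1$end)    # moved back 19 bp
  expect_equal(m$exons[[2L]]$interval$start, iv2$start)
  expect_equal(model_key(m), model_key(truth))
})

test_that("a CDS truncated by the genome edge gets partial_3p", {
  tr <- default_fixture()
  db <- default_db()
  ref <- plastannot:::db_genes(db, "psbA")[[1L]]
  truth <- Filter(function(m) m$name == "psbA", tr$annotation$models)[[1L]]
  iv <- truth$exons[[1L]]$interval
  cut <- plastome("cut", substr(tr$genome$sequence, 1L, iv$end - 30L))
  h <- data.frame(query_gene = "psbA", q_start = 1L,
                  q_end = nchar(ref$protein) - 20L,
                  t_start = iv$start, t_end = iv$end - 63L, strand = "+",
                  frame = 0L, score = 400, identity = 1, evalue = 1e-40,
                  stringsAsFactors = FALSE)
  m <- refine_gene_model(chain_for(h), cut, ref, "translated")
  expect_true(m$partial_3p)
})

test_that("self-annotation reproduces every CDS and rRNA exactly", {
  tr <- default_fixture()
  ann <- default_annotation()
  truth_keys <- vapply(Filter(function(m) m$kind != "tRNA",
                              tr$annotation$models), model_key, character(1L))
  got_keys <- vapply(ann$models, model_key, character(1L))
  expect_setequal(got_keys, truth_keys)
  ## genes inside both IRs are reported twice, with copy numbering
  rrn <- Filter(function(m) m$name == "rrn16", ann$models)
  expect_length(rrn, 2L)
  expect_setequal(vapply(rrn, function(m) m$copy, integer(1L)), 1:2)
  ## overlapping genes on opposite strands are both present
  expect_length(Filter(function(m) m$name %in% c("psbD", "psbN"), ann$models), 2L)
  ## no validation warnings on the clean fixture
  expect_equal(sum(ann$warnings$category == "validation"), 0L)
})

test_that("complete emitted CDS models translate cleanly or carry notes", {
  tr <- default_fixture()
  ann <- default_annotation()
  for (m in ann$models) {
    if (m$kind != "CDS" || m$partial_5p || m$partial_3p) next
    cds <- gene_model_cds(m, tr$genome)
    expect_equal(nchar(cds) %% 3L, 0L, info = m$name)
    p <- translate_cds(cds)
    expect_true(!attr(p, "internal_stop") ||
                  any(grepl("internal stop", m$notes)), info = m$name)
  }
})

test_that("annotation survives 2% point mutations (recovery >= 95%)", {
  ## fixed-seed robustness check: mutate the query genome at 2% outside
  ## the micro-exon anchors, keep the clean reference, re-annotate
  tr <- generate_plastome(7, fixture_config(divergence = 0.02))
  d <- withr::local_tempdir()
  fw <- fixture_write(tr, d)
  db <- suppressWarnings(load_reference(fw$reference))
  ann <- suppressWarnings(annotate_genome(tr$genome, db))
  truth <- Filter(function(m) m$kind != "tRNA", tr$annotation$models)
  n_ok <- 0L
  for (tm in truth) {
    hit <- Filter(function(m) m$name == tm$name &&
                    (m$copy %||% 1L) == (tm$copy %||% 1L) &&
                    identical(m$transcript_id, tm$transcript_id), ann$models)
    if (length(hit) == 1L && length(hit[[1L]]$exons) == length(tm$exons)) {
      n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / length(truth), 0.95)
})

test_that("a genome with no similarity yields an empty set with warning", {
  g <- plastome("bare", rand_seq(4000, 77))
  db <- default_db()
  ann <- suppressWarnings(annotate_genome(g, db))
  expect_length(ann$models, 0L)
  expect_true(any(grepl("empty annotation|not found", ann$warnings$message)))
})
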