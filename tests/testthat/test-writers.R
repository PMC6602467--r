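test_that("a single-exon CDS writes the 4-line GFF3 hierarchy", {
  g <- plastome("g1", rand_seq(500, 81))
  ## make a real ORF so nothing complains downstream
  m <- gene_model("psbZ", "CDS", list(exon(interval(101L, 130L, "+"))),
                  partial_5p = TRUE, partial_3p = TRUE)
  lines <- write_gff3(annotation_set("g1", list(m)), g)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 4L)
  types <- vapply(strsplit(body, "\t"), `[[`, character(1L), 3L)
  expect_equal(types, c("gene", "mRNA", "exon", "CDS"))
  ## Parent chain is consistent
  attrs <- vapply(strsplit(body, "\t"), `[[`, character(1L), 9L)
  expect_match(attrs[2L], "Parent=gene:psbZ")
  expect_match(attrs[3L], "Parent=transcript:psbZ")
})

test_that("trans-spliced rps12 exon 1 carries both transcript parents", {
  tr <- default_fixture()
  lines <- write_gff3(tr$annotation, tr$genome)
  shared <- grep("exon:rps12\\.shared", lines, value = TRUE)
  expect_equal(length(shared), 1L)
  expect_match(shared, "Parent=transcript:rps12\\.t1,transcript:rps12\\.t2")
})

test_that("GFF3 round-trips the full fixture annotation", {
  tr <- default_fixture()
  back <- read_gff3(write_gff3(tr$annotation, tr$genome))
  expect_setequal(vapply(back$models, model_key, character(1L)),
                  vapply(tr$annotation$models, model_key, character(1L)))
})

test_that("annotation coordinates in every writer stay within bounds", {
  tr <- default_fixture()
  lines <- write_gff3(tr$annotation, tr$genome)
  body <- strsplit(lines[!startsWith(lines, "#")], "\t")
  starts <- as.integer(vapply(body, `[[`, character(1L), 4L))
  ends <- as.integer(vapply(body, `[[`, character(1L), 5L))
  expect_true(all(starts >= 1L & ends <= tr$genome$length & starts <= ends))
  ## complete CDS models have exon lengths summing to 0 mod 3
  for (m in tr$annotation$models) {
    if (m$kind == "CDS" && !m$partial_5p && !m$partial_3p) {
      expect_equal(gene_model_length(m, tr$genome$length) %% 3L, 0L,
                   info = m$name)
    }
  }
})

test_that("feature table output matches the reviewed golden file", {
  tr <- default_fixture()
  base <- file.path(withr::local_tempdir(), "plastome")
  write_feature_table(tr$annotation, tr$genome, base)
  got <- readLines(paste0(base, ".tbl"))
  golden <- readLines(test_path("golden", "fixture7.tbl"))
  expect_identical(got, golden)
  ## .fsa carries the full sequence
  fsa <- readLines(paste0(base, ".fsa"))
  expect_equal(paste(fsa[-1L], collapse = ""), tr$genome$sequence)
})

test_that("partial CDS ends carry < and > markers in the feature table", {
  g <- plastome("g1", rand_seq(400, 82))
  m <- gene_model("orf1", "CDS", list(exon(interval(50L, 150L, "+"))),
                  partial_5p = TRUE, partial_3p = TRUE)
  base <- file.path(withr::local_tempdir(), "p")
  write_feature_table(annotation_set("g1", list(m)), g, base)
  tbl <- readLines(paste0(base, ".tbl"))
  expect_true(any(grepl("^<50\t>150\tCDS", tbl)))
})

test_that("the SVG map is deterministic and reflects its inputs", {
  tr <- default_fixture()
  reps <- list(ssr = find_ssrs(tr$genome),
               tandem = tr$repeats$tandem,
               dispersed = tr$repeats$dispersed)
  s1 <- render_map(tr$annotation, reps, tr$genome)
  s2 <- render_map(tr$annotation, reps, tr$genome)
  expect_identical(s1, s2)
  ## one red arc per forward pair, one green per palindromic
  expect_equal(sum(grepl('class="dispersed-forward"', s1)), 1L)
  expect_equal(sum(grepl('class="dispersed-palindromic"', s1)), 1L)
  ## empty annotation still renders a valid 4-ring SVG
  empty <- render_map(annotation_set("e", list()),
                      list(ssr = NULL, tandem = NULL, dispersed = NULL),
                      plastome("e", rand_seq(1000, 83)))
  expect_equal(sum(grepl("<g id=\"ring-", empty)), 4L)
  expect_true(startsWith(empty[1L], "<svg"))
  expect_equal(empty[length(empty)], "</svg>")
  xml2::read_xml(paste(empty, collapse = "\n"))   # well-formed
})
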