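## Hand-built SAM lines over a tiny genome exercise the pileup contract.
tiny_genome <- function() plastome("tiny", paste0(strrep("ACGT", 50)))

sam_lines <- function(genome, recs) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length),
    recs)
}

rec <- function(genome, pos, seq, flag = 0L, mapq = 60L, cigar = NULL,
                qual = NULL) {
  cigar <- cigar %||% paste0(nchar(seq), "M")
  qual <- qual %||% strrep("I", nchar(seq))
  sprintf("r%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          paste0(pos, "x", flag, "x", substr(seq, 1, 4)), flag, genome$id,
          pos, mapq, cigar, seq, qual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical perfect reads pile up to full depth at ref base", {
  g <- tiny_genome()
  reads <- vapply(1:10, function(i) rec(g, 41L, substr(g$sequence, 41, 90)),
                  character(1L))
  ## unique QNAMEs required: tweak
  reads <- sprintf("q%02d%s", 1:10, sub("^[^\t]*", "", reads))
  pu <- build_pileup(sam_lines(g, reads), g)
  row <- pu[pu$position == 60L, ]
  expect_equal(row$depth, 10L)
  expect_equal(pileup_base_count(row, row$ref_base), 10L)
})

test_that("deletions, low MAPQ and flagged reads are excluded correctly", {
  g <- tiny_genome()
  reads <- c(
    rec(g, 11L, paste0(substr(g$sequence, 11, 30), substr(g$sequence, 33, 42)),
        cigar = "20M2D10M"),
    rec(g, 11L, substr(g$sequence, 11, 40)),
    rec(g, 11L, substr(g$sequence, 11, 40), mapq = 5L),       # below min_mapq
    rec(g, 11L, substr(g$sequence, 11, 40), flag = 4L),       # unmapped
    rec(g, 11L, substr(g$sequence, 11, 40), flag = 256L),     # secondary
    rec(g, 11L, substr(g$sequence, 11, 40), flag = 1024L))    # duplicate
  pu <- build_pileup(sam_lines(g, reads), g)
  ## at a deleted position only the intact read contributes
  expect_equal(pu$depth[pu$position == 31L], 1L)
  expect_equal(pu$depth[pu$position == 20L], 2L)
  ## depth always equals the sum of the base counts
  cnt <- rowSums(pu[, paste0(rep(c("A", "C", "G", "T"), each = 2L),
                             c("_fwd", "_rev"))])
  expect_equal(pu$depth, cnt)
})

test_that("SNP calling applies depth, fraction, count and strand rules", {
  g <- tiny_genome()
  mk_reads <- function(pos, n_ref, n_alt, alt, split_strand = TRUE) {
    base <- substr(g$sequence, pos - 10L, pos + 10L)
    alt_read <- base
    substr(alt_read, 11L, 11L) <- alt
    flags <- function(k) if (split_strand) rep(c(0L, 16L), length.out = k) else rep(0L, k)
    c(vapply(seq_len(n_ref), function(i)
        sprintf("ref%d_%d%s", pos, i, sub("^[^\t]*", "",
          rec(g, pos - 10L, base, flag = flags(n_ref)[i]))), character(1L)),
      vapply(seq_len(n_alt), function(i)
        sprintf("alt%d_%d%s", pos, i, sub("^[^\t]*", "",
          rec(g, pos - 10L, alt_read, flag = flags(n_alt)[i]))), character(1L)))
  }
  ## 20/100 alt on both strands: PASS at fraction 0.2
  reads <- mk_reads(100L, 80L, 20L, "T")    # ref at 100 is ...? ensure != T
  ref_base <- substr(g$sequence, 100L, 100L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  reads <- mk_reads(100L, 80L, 20L, alt)
  pu <- build_pileup(sam_lines(g, reads), g)
  calls <- call_snps(pu)
  hit <- calls[calls$position == 100L & calls$alt_base == alt, ]
  expect_equal(hit$filter, "PASS")
  expect_equal(hit$alt_fraction, 0.2)
  ## 2/100 alt: below min_alt_count, no call
  reads2 <- mk_reads(60L, 98L, 2L, setdiff(c("A", "C", "G", "T"),
                                           substr(g$sequence, 60L, 60L))[1L])
  calls2 <- call_snps(build_pileup(sam_lines(g, reads2), g))
  expect_false(60L %in% calls2$position)
  ## qualifying alt at depth < min_depth: flagged low_depth
  alt3 <- setdiff(c("A", "C", "G", "T"), substr(g$sequence, 80L, 80L))[1L]
  calls3 <- call_snps(build_pileup(sam_lines(g, mk_reads(80L, 4L, 4L, alt3)), g))
  expect_equal(calls3$filter[calls3$position == 80L], "low_depth")
  ## >= 10 alt reads all on one strand: strand_bias
  alt4 <- setdiff(c("A", "C", "G", "T"), substr(g$sequence, 120L, 120L))[1L]
  calls4 <- call_snps(build_pileup(
    sam_lines(g, mk_reads(120L, 30L, 12L, alt4, split_strand = FALSE)), g))
  expect_equal(calls4$filter[calls4$position == 120L], "strand_bias")
})

test_that("planted heteroplasmy is recovered exactly (simulator truth)", {
  tr <- default_fixture()
  sim <- simulate_reads(tr, "dna", depth = 40L, seed = 11L)
  pu <- build_pileup(sim$sam, tr$genome)
  calls <- call_snps(pu)
  pass <- calls[calls$filter == "PASS", ]
  expect_setequal(pass$position, tr$variants$position)
  ## re-running on the same SAM is bit-identical (pure function)
  pu2 <- build_pileup(sim$sam, tr$genome)
  expect_identical(call_snps(pu2), calls)
})

test_that("editing sites are detected with correct codon effects", {
  tr <- default_fixture()
  sim <- simulate_reads(tr, "rna", depth = 40L, seed = 5L)
  pu <- build_pileup(sim$sam, tr$genome)
  ed <- call_editing_sites(pu, tr$annotation, tr$genome)
  expect_setequal(ed$position, tr$editing$position)
  expect_true(all(ed$codon_before == "TCA"))
  expect_true(all(ed$codon_after == "TTA"))
  expect_true(all(ed$aa_before == "S" & ed$aa_after == "L"))
  ## hard invariant: the sense-strand genomic base at a reported site is C
  for (i in seq_len(nrow(ed))) {
    b <- substr(tr$genome$sequence, ed$position[i], ed$position[i])
    expect_equal(if (ed$strand[i] == "+") b else comp_base[[b]], "C")
  }
})

test_that("minus-strand genes report editing through the antisense mirror", {
  ## build a tiny minus-strand CDS with a TCA codon and A-reads at the
  ## mirrored genomic G
  withr::with_seed(9, {
    cds <- paste0("ATG", "TCA", "GGG", "CCT", "TAA")
    flank1 <- rand_seq(60, 91); flank2 <- rand_seq(60, 92)
    g <- plastome("mini", paste0(flank1, revcomp_chr(cds), flank2))
  })
  m <- gene_model("ndhX", "CDS", list(exon(interval(61L, 75L, "-"))))
  ann <- annotation_set("mini", list(m))
  ## editing at CDS position 5 (codon 2, pos 2): genomic position?
  gpos <- 75L - 5L + 1L   # minus strand mapping
  base <- substr(g$sequence, gpos, gpos)
  expect_equal(base, "G")
  reads <- character(0)
  win <- substr(g$sequence, 56L, 95L)
  edited <- win; substr(edited, gpos - 55L, gpos - 55L) <- "A"
  for (i in 1:12) {
    reads <- c(reads, sprintf("e%d\t0\tmini\t56\t60\t40M\t*\t0\t0\t%s\t%s",
                              i, if (i <= 6) edited else win, strrep("I", 40)))
  }
  pu <- build_pileup(c("@HD\tVN:1.6", sprintf("@SQ\tSN:mini\tLN:%d", g$length),
                       reads), g)
  ed <- call_editing_sites(pu, ann, g, min_depth = 5L, min_level = 0.2)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$position, gpos)
  expect_equal(ed$strand, "-")
  expect_equal(ed$codon_before, "TCA")
  expect_equal(ed$aa_after, "L")
})

test_that("read prefiltering keeps matching reads and mate pairs", {
  tr <- default_fixture()
  gene <- gene_model_cds(tr$annotation$models[[1L]], tr$genome)
  good <- substr(gene, 101L, 200L)
  bad <- rand_seq(100L, 93)
  fq <- function(ids, seqs) as.vector(rbind(paste0("@", ids), seqs, "+",
                                            strrep("I", 100L)))
  f1 <- withr::local_tempfile(lines = fq(c("a", "b"), c(good, bad)))
  out <- withr::local_tempfile()
  res <- prefilter_reads(f1, gene, out = out)
  expect_equal(res$n_in, 2L)
  expect_equal(res$n_out, 1L)
  kept <- readLines(out)
  expect_equal(kept[1L], "@a")
  ## reverse-complement reads also pass
  f2 <- withr::local_tempfile(lines = fq("rc", revcomp_chr(good)))
  expect_equal(prefilter_reads(f2, gene, out = out)$n_out, 1L)
  ## pairing: pair passes when either mate passes
  fa <- withr::local_tempfile(lines = fq(c("p1", "p2"), c(bad, bad)))
  fb <- withr::local_tempfile(lines = fq(c("p1", "p2"), c(good, bad)))
  res2 <- prefilter_reads(fa, gene, mate = fb, out = out)
  expect_equal(res2$n_out, 1L)
  expect_equal(readLines(res2$paths[1L])[1L], "@p1")
  ## malformed record is skipped and counted
  f3 <- withr::local_tempfile(lines = c("@x", good, "+", "III",
                                        fq("ok", good)))
  res3 <- prefilter_reads(f3, gene, out = out)
  expect_gte(res3$n_malformed, 1L)
  expect_equal(res3$n_out, 1L)
})
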