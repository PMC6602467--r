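test_that("exact substrings align at identity 1.0 on both strands", {
  s <- rand_seq(8000, 21)
  g <- plastome("t", s)
  q <- substr(s, 3001, 3060)
  h <- similarity_search(q, g, "nucleotide", 1e-10)
  expect_gt(nrow(h), 0L)
  expect_equal(h$t_start[1L], 3001L)
  expect_equal(h$t_end[1L], 3060L)
  expect_equal(h$identity[1L], 1)
  expect_equal(h$strand[1L], "+")
  hr <- similarity_search(revcomp_chr(q), g, "nucleotide", 1e-10)
  expect_equal(hr$strand[1L], "-")
  expect_equal(c(hr$t_start[1L], hr$t_end[1L]), c(3001L, 3060L))
})

test_that("HSP scores match an exhaustive Smith-Waterman oracle", {
  ## 56-bp query with one planted mismatch: identity 55/56 and the
  ## package score equals the plain-DP local alignment score
  s <- rand_seq(3000, 33)
  q <- substr(s, 1001, 1056)
  substr(q, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(q, 25, 25))[1L]
  g <- plastome("t", s)
  h <- similarity_search(q, g, "nucleotide", 1e-4)
  expect_equal(h$identity[1L], 55 / 56)
  win <- substr(s, 900, 1150)
  expect_equal(h$score[1L], sw_oracle(q, win))
})

test_that("translated search maps protein hits back to nucleotide frames", {
  tr <- default_fixture()
  db <- default_db()
  psbA <- plastannot:::db_genes(db, "psbA")[[1L]]
  truth <- Filter(function(m) m$name == "psbA", tr$annotation$models)[[1L]]
  h <- similarity_search(psbA$protein, tr$genome, "translated", 1e-6)
  iv <- truth$exons[[1L]]$interval
  expect_equal(h$t_start[1L], iv$start)
  ## protein has no stop codon: hit ends one codon short of the CDS end
  expect_equal(h$t_end[1L], iv$end - 3L)
  ## minus-strand gene
  matK <- plastannot:::db_genes(db, "matK")[[1L]]
  truthK <- Filter(function(m) m$name == "matK", tr$annotation$models)[[1L]]
  hk <- similarity_search(matK$protein, tr$genome, "translated", 1e-6)
  expect_equal(hk$strand[1L], "-")
  expect_equal(hk$t_end[1L], truthK$exons[[1L]]$interval$end)
})

test_that("invalid query alphabets are hard errors", {
  g <- plastome("t", rand_seq(1000, 5))
  expect_error(similarity_search("ACGT!!ACGTACGT", g, "nucleotide"), "alphabet")
  expect_error(similarity_search("ACGT", g, "nucleotide"), "shorter")
})

test_that("chaining follows the documented gap and overlap rules", {
  mk <- function(qs, qe, ts, te, score, strand = "+") {
    data.frame(query_gene = "g", q_start = qs, q_end = qe, t_start = ts,
               t_end = te, strand = strand, frame = 0L, score = score,
               identity = 1, evalue = 1e-30, stringsAsFactors = FALSE)
  }
  ## two colinear HSPs 800 apart -> one chain, two exons
  h <- rbind(mk(1, 100, 1000, 1099, 200), mk(101, 200, 1900, 1999, 200))
  ch <- chain_hsps(h, 2000L)
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1L]]$hsps), 2L)
  expect_equal(ch[[1L]]$score, 400)
  ## gap beyond max_intron -> two separate chains
  h2 <- rbind(mk(1, 100, 1000, 1099, 200), mk(101, 200, 6200, 6299, 180))
  ch2 <- chain_hsps(h2, 2000L)
  expect_length(ch2, 2L)
  expect_true(all(vapply(ch2, function(z) nrow(z$hsps), integer(1L)) == 1L))
  ## >50% query overlap -> lower-scoring HSP cannot join; best chain is
  ## just the higher-scoring HSP
  h3 <- rbind(mk(1, 100, 1000, 1099, 200), mk(30, 130, 1500, 1600, 150))
  ch3 <- chain_hsps(h3, 2000L)
  expect_equal(ch3[[1L]]$score, 200)
  expect_equal(nrow(ch3[[1L]]$hsps), 1L)
  ## empty input -> empty output
  expect_length(chain_hsps(plastannot:::empty_hsps(), 2000L), 0L)
})

test_that("chain score equals brute-force enumeration on random instances", {
  for (seed in 1:6) {
    hs <- withr::with_seed(seed, {
      n <- sample(4:9, 1L)
      qs <- sort(sample(1:500, n))
      data.frame(query_gene = "g",
                 q_start = qs, q_end = qs + sample(20:80, n, TRUE),
                 t_start = ts <- sort(sample(1:5000, n)),
                 t_end = ts + sample(20:80, n, TRUE),
                 strand = "+", frame = 0L,
                 score = sample(50:300, n, TRUE), identity = 1,
                 evalue = 1e-30, stringsAsFactors = FALSE)
    })
    best <- plastannot:::best_chain(hs, 2000L)
    expect_equal(best$score, chain_oracle(hs, 2000L), info = paste("seed", seed))
  }
})
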