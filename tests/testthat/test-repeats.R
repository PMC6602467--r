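test_that("SSR finder reports canonical motifs, thresholds and trimming", {
  pad <- rand_seq(300, 61)
  ## guard junctions so planted runs stay maximal
  g1 <- paste0(pad, "C", strrep("A", 12), "C", rand_seq(200, 62))
  r <- find_ssrs(g1)
  expect_equal(nrow(r), 1L)
  expect_equal(r$motif, "A"); expect_equal(r$copies, 12L)
  expect_equal(r$start, 302L); expect_equal(r$end, 313L)
  ## dinucleotide run: one SSR with canonical rotation, not two mono runs
  g2 <- paste0(pad, "C", strrep("TA", 6), "TCC", rand_seq(200, 63))
  r2 <- find_ssrs(g2)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$motif, "AT")      # lexicographically minimal rotation
  expect_equal(r2$unit_len, 2L)
  ## below threshold: silent
  g3 <- paste0(pad, "C", strrep("AT", 5), "C", rand_seq(200, 64))
  expect_equal(nrow(find_ssrs(g3)), 0L)
})

test_that("tandem finder handles exact, mutated and SSR-overlap cases", {
  unit <- rand_seq(30, 65)
  pad1 <- rand_seq(400, 66); pad2 <- rand_seq(400, 67)
  g <- paste0(pad1, strrep(unit, 4), pad2)
  r <- find_tandem_repeats(g, max_unit = 50)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit_len, 30L)
  expect_gte(r$copies, 4)
  expect_equal(r$consensus, unit)
  expect_equal(r$percent_identity, 1)
  ## two point mutations in one copy: still found, identity < 1
  x <- strsplit(strrep(unit, 4), "")[[1L]]
  for (p in c(40L, 50L)) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1L]
  g2 <- paste0(pad1, paste(x, collapse = ""), pad2)
  r2 <- find_tandem_repeats(g2, max_unit = 50)
  expect_equal(nrow(r2), 1L)
  expect_lt(r2$percent_identity, 1)
  expect_equal(r2$consensus, unit)
  ## an SSR region is never reported as a tandem repeat (unit <= 6)
  g3 <- paste0(pad1, strrep("AG", 20), pad2)
  expect_equal(nrow(find_tandem_repeats(g3, max_unit = 50)), 0L)
})

test_that("dispersed finder reports planted forward and palindromic pairs", {
  seg <- rand_seq(40, 68)
  g <- paste0(rand_seq(500, 69), "C", seg, "G",
              rand_seq(5000, 70), "A", seg, "T",
              rand_seq(400, 71))
  r <- find_dispersed_repeats(g, exclude_ir = FALSE)
  fw <- r[r$orientation == "forward", ]
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$length, 40L); expect_equal(fw$mismatches, 0L)
  expect_equal(c(fw$a_start, fw$b_start), c(502L, 5544L))
  ## palindromic pair; CCCCCC guards pair with themselves as C/G
  ## mismatches under reverse complement, so the planted 40-mer cannot be
  ## extended in either direction
  g2 <- paste0(rand_seq(400, 72), "CCCCCC", seg, "CCCCCC", rand_seq(2000, 73),
               "CCCCCC", revcomp_chr(seg), "CCCCCC", rand_seq(300, 74))
  r2 <- find_dispersed_repeats(g2, exclude_ir = FALSE)
  expect_equal(r2$orientation, "palindromic")
  expect_equal(r2$length, 40L)
  ## two interior substitutions, max_mismatch 3: reported with mismatches 2
  seg_mut <- seg
  for (p in c(12L, 25L)) {
    substr(seg_mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(seg, p, p))[1L]
  }
  g3 <- paste0(rand_seq(500, 75), "C", seg, "G", rand_seq(3000, 76),
               "A", seg_mut, "T", rand_seq(300, 77))
  r3 <- find_dispersed_repeats(g3, exclude_ir = FALSE)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$mismatches, 2L)
  expect_equal(r3$length, 40L)
})

test_that("exclude_ir suppresses the IRa/IRb pair itself", {
  tr <- default_fixture()
  with_ir <- find_dispersed_repeats(tr$genome, exclude_ir = FALSE)
  expect_true(any(with_ir$length > 5000L))       # the IR pair
  no_ir <- find_dispersed_repeats(tr$genome, layout = tr$layout)
  expect_false(any(no_ir$length > 5000L))
  expect_equal(nrow(no_ir), nrow(tr$repeats$dispersed))
})

test_that("planted fixture rosters are recovered exactly", {
  tr <- default_fixture()
  ssr <- find_ssrs(tr$genome)
  expect_equal(ssr$motif, tr$repeats$ssr$motif)
  expect_equal(ssr$start, tr$repeats$ssr$start)
  expect_equal(ssr$copies, tr$repeats$ssr$copies)
  tan <- find_tandem_repeats(tr$genome, max_unit = 60)
  expect_equal(nrow(tan), 1L)
  expect_equal(tan$start, tr$repeats$tandem$start)
  expect_equal(tan$end, tr$repeats$tandem$end)
  expect_equal(tan$consensus, tr$repeats$tandem$consensus)
})

test_that("SSR and tandem finders never claim the same interval across the 6-bp line", {
  tr <- default_fixture()
  ssr <- find_ssrs(tr$genome)
  tan <- find_tandem_repeats(tr$genome, max_unit = 60)
  for (i in seq_len(nrow(tan))) {
    same <- ssr$start == tan$start[i] & ssr$end == tan$end[i]
    expect_false(any(same))
  }
})

test_that("finders agree with brute-force oracles on mixed mini genomes", {
  for (seed in c(3, 4)) {
    g <- repeat_mini(seed, 2200)
    f_ssr <- find_ssrs(g)
    o_ssr <- ssr_oracle(g$sequence)
    expect_equal(f_ssr[, c("motif", "unit_len", "copies", "start", "end")],
                 o_ssr[, c("motif", "unit_len", "copies", "start", "end")],
                 ignore_attr = TRUE, info = paste("ssr seed", seed))
    f_d <- find_dispersed_repeats(g, exclude_ir = FALSE)
    o_d <- dispersed_oracle(g$sequence)
    rownames(f_d) <- rownames(o_d) <- NULL
    expect_equal(f_d, o_d, ignore_attr = TRUE, info = paste("disp seed", seed))
    ## tandem oracle on the window holding the planted array
    at <- as.integer(2200 * 0.87)
    sub <- substr(g$sequence, at - 300L, min(at + 400L, 2200L))
    f_t <- find_tandem_repeats(sub, max_unit = 25)
    o_t <- tandem_oracle(sub, max_unit = 25)
    expect_equal(f_t, o_t, ignore_attr = TRUE, info = paste("tandem seed", seed))
  }
})
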