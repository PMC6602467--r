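## Shared fixture cache: the default synthetic plastome (seed 7) and the
## objects derived from it are built once per test run.

## the cache lives in options() so it survives re-sourcing of the helper
## between test files within one test_dir() process
.fixture_cache <- local({
  env <- getOption("plastannot.test.cache")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    options(plastannot.test.cache = env)
  }
  env
})

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

default_fixture <- function() cached("truth", function() generate_plastome(7))

default_fixture_files <- function() cached("files", function() {
  d <- file.path(tempdir(), "plastannot-fixture-7")
  fw <- fixture_write(default_fixture(), d)
  pf <- fixture_trna_predictions(default_fixture(), d)
  c(fw, pf, dir = d)
})

default_db <- function() cached("db", function() {
  suppressWarnings(load_reference(default_fixture_files()$reference))
})

default_annotation <- function() cached("annotation", function() {
  suppressWarnings(annotate_genome(default_fixture()$genome, default_db()))
})

## random DNA with a fixed local RNG (does not disturb the global stream)
rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

## mini genome for ISECUS tests: filler + anchor + exon1 + intron + exon2
## + filler; anchor optionally mutated at a per-base rate
isecus_mini <- function(seed, gene = "petB", anchor_mut = 0,
                        n_flank = 400L, intron_len = 300L) {
  withr::with_seed(seed, {
    cons <- switch(gene, petB = "ATGAGT", petD = "ATGGGAGT",
                   rpl16 = "ATGCTTAGT")
    anchor <- paste(sample(c("A", "C", "G", "T"), 50L, TRUE), collapse = "")
    exon2_len <- switch(gene, petB = 642L, petD = 475L, rpl16 = 399L)
    exon2 <- paste(c(sample(c("A", "C", "G", "T"), exon2_len - 3L, TRUE),
                     "T", "A", "A"), collapse = "")
    mut_anchor <- anchor
    if (anchor_mut > 0) {
      x <- strsplit(anchor, "", fixed = TRUE)[[1L]]
      hit <- which(runif(50L) < anchor_mut)
      for (i in hit) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[sample.int(3L, 1L)]
      mut_anchor <- paste(x, collapse = "")
    }
    pre <- paste(sample(c("A", "C", "G", "T"), n_flank, TRUE), collapse = "")
    intron <- paste(sample(c("A", "C", "G", "T"), intron_len, TRUE), collapse = "")
    post <- paste(sample(c("A", "C", "G", "T"), n_flank, TRUE), collapse = "")
    genome <- plastome("mini", paste0(pre, mut_anchor, cons, intron, exon2, post))
    e1_start <- n_flank + 50L + 1L
    anchors <- data.frame(gene = gene, side = "five_prime",
                          anchor_seq = anchor, exon_seq = cons,
                          exon_len = nchar(cons), source_accession = "mini",
                          valid = TRUE, stringsAsFactors = FALSE)
    partner_start <- e1_start + nchar(cons) + intron_len
    list(genome = genome, anchors = anchors,
         exon1 = c(e1_start, e1_start + nchar(cons) - 1L),
         partner = interval(partner_start, partner_start + exon2_len - 1L, "+"))
  })
}

## small plastome with planted repeats on random background (for oracle
## equivalence); returns genome + planted coordinates
repeat_mini <- function(seed, n = 6000L) {
  withr::with_seed(seed, {
    base <- strsplit(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = ""), "", fixed = TRUE)[[1L]]
    ## squash chance SSR runs so planted repeats are the only signal
    for (u in 1:6) {
      thr <- c(10L, 6L, 5L, 5L, 5L, 5L)[u]
      repeat {
        eq <- base[seq_len(n - u)] == base[seq_len(n - u) + u]
        r <- rle(eq); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        bad <- which(r$values & (r$lengths + u) >= (thr - 1L) * u)
        if (length(bad) == 0L) break
        for (i in bad) {
          p <- starts[i] + (r$lengths[i] %/% 2L)
          base[p] <- setdiff(c("A", "C", "G", "T"), base[p])[1L]
        }
      }
    }
    at <- function(frac) as.integer(n * frac)
    put <- function(pos, seqstr) {
      base[pos:(pos + nchar(seqstr) - 1L)] <<- strsplit(seqstr, "")[[1L]]
    }
    dseq <- paste(sample(c("A", "C", "G", "T"), 40L, TRUE), collapse = "")
    put(at(0.08), dseq)
    put(at(0.50), dseq)
    pseq <- paste(sample(c("A", "C", "G", "T"), 35L, TRUE), collapse = "")
    put(at(0.20), pseq)
    put(at(0.75), revcomp_chr(pseq))
    put(at(0.33), strrep("A", 12L))                      # SSR A x 12
    put(at(0.38), strrep("AG", 7L))                      # SSR AG x 7
    unit <- paste(sample(c("A", "C", "G", "T"), 20L, TRUE), collapse = "")
    muts <- list(c(3L, 11L), c(7L, 15L), c(5L, 19L))
    arr <- vapply(muts, function(mm) {
      u2 <- strsplit(unit, "")[[1L]]
      for (p in mm) u2[p] <- setdiff(c("A", "C", "G", "T"), u2[p])[1L]
      paste(u2, collapse = "")
    }, character(1L))
    put(at(0.87), paste(arr, collapse = ""))
    plastome("repmini", paste(base, collapse = ""))
  })
}
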