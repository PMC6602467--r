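## Deterministic synthetic-plastome and read simulator.
##
## The generator builds a quadripartite genome with known ground truth for
## every other module: multi-exon genes with valid ORFs, the micro-exon
## genes petB/petD/rpl16 behind fixed 50-bp 5'UTR anchors, the
## trans-spliced rps12 (exon 1 in the LSC, exons 2+3 in both IRs, last
## exon 26 bp), rRNA and tRNA loci (two tRNAs with introns), and planted
## SSR / tandem / dispersed repeats.  Regeneration from (seed, config) is
## byte-identical.

## micro-exon consensus sequences used as fixture defaults (most abundant
## patterns across curated plastome sets)
MICROEXON_CONSENSUS <- list(
  petB = "ATGAGT",
  petD = "ATGGGAGT",
  rpl16 = "ATGCTTAGT",
  rps12_last = "AATATGGGGTCAAAAAGCCAAAATAA"
)

STOPLESS_CODONS <- {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

## default SSR copy-number thresholds (MISA tradition)
SSR_DEFAULT_MIN_COPIES <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                            `5` = 5L, `6` = 5L)

#' Default fixture configuration
#'
#' Region sizes follow a scaled-down quadripartite plastome (real
#' plastomes are 120-170 kb; the fixture keeps the same architecture at
#' 34 kb so brute-force test oracles stay fast).
#'
#' @param lsc,ir,ssc Region sizes in bp.
#' @param divergence Per-base substitution rate applied to the query
#'   genome relative to the emitted reference (0 = identical).  Anchors,
#'   micro-exons and the IR regions are never mutated (IR mutation would
#'   break the exact inverted-repeat structure).
#' @return A named list of configuration values.
#' @export
fixture_config <- function(lsc = 18000L, ir = 6000L, ssc = 4000L,
                           divergence = 0) {
  list(lsc = as.integer(lsc), ir = as.integer(ir), ssc = as.integer(ssc),
       divergence = divergence)
}

## ---- random-sequence primitives ------------------------------------------

rand_dna <- function(n) {
  ## AT-rich composition typical of plastome intergenic sequence
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.31, 0.19, 0.18, 0.32)), collapse = "")
}

## TRUE when s contains a perfect tandem run of a unit of size 1..6
## reaching the SSR thresholds (with a one-copy safety margin subtracted)
has_ssr_run <- function(s, margin = 1L) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(x)
  for (u in 1:6) {
    need <- (SSR_DEFAULT_MIN_COPIES[[as.character(u)]] - margin) * u
    if (n < need) next
    eq <- x[seq_len(n - u)] == x[seq_len(n - u) + u]
    r <- rle(eq)
    run_len <- r$lengths[r$values]
    if (length(run_len) && any(run_len + u >= need)) return(TRUE)
  }
  FALSE
}

## random DNA free of near-threshold SSR runs
clean_rand <- function(n) {
  for (i in 1:50) {
    s <- rand_dna(n)
    if (!has_ssr_run(s)) return(s)
  }
  stop("could not generate SSR-free filler (should not happen)")
}

rand_codons <- function(k) {
  if (k == 0L) return("")
  paste(sample(STOPLESS_CODONS, k, replace = TRUE), collapse = "")
}

## build a CDS of total_len starting with `prefix`, padded to frame with
## non-stop bases, filled with random non-stop codons, ending with TAA
finish_cds <- function(prefix, total_len) {
  m <- nchar(prefix)
  stopifnot(total_len %% 3L == 0L, total_len >= m + 3L)
  for (i in 1:50) {
    s <- prefix
    phase <- m %% 3L
    if (phase != 0L) {
      ## complete the open codon without creating a stop
      open <- substr(s, nchar(s) - phase + 1L, nchar(s))
      pad <- ""
      for (j in seq_len(3L - phase)) {
        cand <- sample(c("A", "C", "G", "T"))
        for (b in cand) {
          if (!(j == 3L - phase &&
                paste0(open, pad, b) %in% c("TAA", "TAG", "TGA"))) {
            pad <- paste0(pad, b); break
          }
        }
      }
      s <- paste0(s, pad)
    }
    fill <- (total_len - nchar(s) - 3L) %/% 3L
    s <- paste0(s, rand_codons(fill), "TAA")
    stopifnot(nchar(s) == total_len)
    p <- translate_cds(s)
    if (!attr(p, "internal_stop") && !has_ssr_run(s)) return(s)
  }
  stop("could not build clean CDS")
}

## ---- region builder -------------------------------------------------------

new_builder <- function(offset) {
  env <- new.env(parent = emptyenv())
  env$parts <- character(0)
  env$mutable <- list()     # per-part logical
  env$pos <- offset + 1L    # absolute coordinate of next base
  env
}

b_len <- function(b) sum(nchar(b$parts))

## append sequence; returns the absolute interval it occupies
b_add <- function(b, s, mutable = FALSE) {
  st <- b$pos
  b$parts <- c(b$parts, s)
  b$mutable[[length(b$mutable) + 1L]] <- mutable
  b$pos <- b$pos + nchar(s)
  c(st, b$pos - 1L)
}

b_spacer <- function(b, n) b_add(b, clean_rand(n), mutable = TRUE)

## guard base breaking any repeat continuation across a junction
guard_base <- function(avoid) {
  for (c in c("C", "G", "A", "T")) if (!(c %in% avoid)) return(c)
  "C"
}

## place a sense-oriented block (named list of part sequences) on a strand;
## returns list of absolute intervals per part (strand-aware)
b_block <- function(b, parts, strand) {
  block <- paste(unlist(parts), collapse = "")
  ins <- if (strand == "-") revcomp_chr(block) else block
  iv <- b_add(b, ins, mutable = FALSE)
  L <- nchar(block)
  res <- list()
  cum <- 0L
  for (nm in names(parts)) {
    l <- nchar(parts[[nm]])
    s_lo <- cum + 1L; s_hi <- cum + l          # sense-block coords
    if (strand == "+") {
      res[[nm]] <- interval(iv[1L] + s_lo - 1L, iv[1L] + s_hi - 1L, "+")
    } else {
      res[[nm]] <- interval(iv[1L] + (L - s_hi), iv[1L] + (L - s_lo), "-")
    }
    cum <- cum + l
  }
  res
}

## ---- the generator --------------------------------------------------------

#' Generate a synthetic plastome fixture with known truth
#'
#' @param seed Integer seed; regeneration from the same (seed, config) is
#'   byte-identical.
#' @param config A [fixture_config()] list.
#' @return A `fixture_truth` list with elements `genome` (query
#'   `plastome`), `ref_genome` (un-diverged `plastome`), `layout`,
#'   `annotation` (truth `annotation_set` on the query genome),
#'   `ref_models` (models as emitted into the reference GenBank),
#'   `repeats` (list `ssr`, `tandem`, `dispersed`), `variants`,
#'   `editing`, `trna_truth`, `seed`, `config`.
#' @export
generate_plastome <- function(seed, config = fixture_config()) {
  set.seed(seed)
  n_lsc <- config$lsc; n_ir <- config$ir; n_ssc <- config$ssc
  n <- n_lsc + 2L * n_ir + n_ssc

  models <- list()        # truth models (query coordinates)
  ref_models <- list()    # reference GenBank models (one copy per gene)
  ssr_truth <- list(); tan_truth <- list(); disp_truth <- list()
  trna_truth <- list()

  add_model <- function(m, ref = TRUE) {
    models[[length(models) + 1L]] <<- m
    if (ref) ref_models[[length(ref_models) + 1L]] <<- m
  }

  ## ================= LSC =================
  L <- new_builder(0L)
  b_spacer(L, 180L)

  ## psbA: single-exon CDS, + strand
  cds <- finish_cds("ATG", 900L)
  iv <- b_block(L, list(cds = cds), "+")$cds
  add_model(gene_model("psbA", "CDS", list(exon(iv)), provenance = "truth",
                       product = "photosystem II protein D1"))

  ## spacer with planted SSR "A" x 12
  b_spacer(L, 90L)
  b_add(L, guard_base(c("A")))
  siv <- b_add(L, strrep("A", 12L))
  b_add(L, guard_base(c("A")))
  ssr_truth[[1L]] <- list(motif = "A", copies = 12L, start = siv[1L], end = siv[2L])
  b_spacer(L, 80L)

  ## matK: single-exon CDS, - strand
  cds <- finish_cds("ATG", 750L)
  iv <- b_block(L, list(cds = cds), "-")$cds
  add_model(gene_model("matK", "CDS", list(exon(iv)), provenance = "truth",
                       product = "maturase K"))

  ## spacer with planted SSR "AT" x 7
  b_spacer(L, 85L)
  b_add(L, guard_base(c("A", "T")))
  siv <- b_add(L, strrep("AT", 7L))
  b_add(L, guard_base(c("A", "T")))
  ssr_truth[[2L]] <- list(motif = "AT", copies = 7L, start = siv[1L], end = siv[2L])
  b_spacer(L, 75L)

  ## atpF: two-exon CDS, + strand
  cds <- finish_cds("ATG", 855L)
  e1 <- substr(cds, 1L, 411L); e2 <- substr(cds, 412L, 855L)
  ivs <- b_block(L, list(e1 = e1, i1 = clean_rand(650L), e2 = e2), "+")
  add_model(gene_model("atpF", "CDS", list(exon(ivs$e1, 0L, 1L),
                                           exon(ivs$e2, 0L, 2L)),
                       provenance = "truth", product = "ATP synthase CF0 B subunit"))

  ## dispersed repeat, forward pair: copy 1
  b_spacer(L, 100L)
  disp_seq <- clean_rand(40L)
  b_add(L, "C"); f1 <- b_add(L, disp_seq); b_add(L, "G")
  b_spacer(L, 110L)

  ## petB: micro-exon 1 behind a 50-bp 5'UTR anchor, + strand
  petB_anchor <- clean_rand(50L)
  cds <- finish_cds(MICROEXON_CONSENSUS$petB, 648L)
  ivs <- b_block(L, list(anchor = petB_anchor,
                         e1 = substr(cds, 1L, 6L),
                         i1 = clean_rand(700L),
                         e2 = substr(cds, 7L, 648L)), "+")
  add_model(gene_model("petB", "CDS", list(exon(ivs$e1, 0L, 1L),
                                           exon(ivs$e2, 0L, 2L)),
                       provenance = "truth", product = "cytochrome b6"))
  b_spacer(L, 120L)

  ## petD: 8-bp micro-exon, + strand
  petD_anchor <- clean_rand(50L)
  cds <- finish_cds(MICROEXON_CONSENSUS$petD, 483L)
  ivs <- b_block(L, list(anchor = petD_anchor,
                         e1 = substr(cds, 1L, 8L),
                         i1 = clean_rand(680L),
                         e2 = substr(cds, 9L, 483L)), "+")
  add_model(gene_model("petD", "CDS", list(exon(ivs$e1, 0L, 1L),
                                           exon(ivs$e2, 1L, 2L)),
                       provenance = "truth",
                       product = "cytochrome b6/f complex subunit IV"))

  ## spacer with planted SSR "AAG" x 6
  b_spacer(L, 70L)
  b_add(L, guard_base(c("A", "G")))
  siv <- b_add(L, strrep("AAG", 6L))
  b_add(L, guard_base(c("A", "G")))
  ssr_truth[[3L]] <- list(motif = "AAG", copies = 6L, start = siv[1L], end = siv[2L])
  b_spacer(L, 60L)

  ## rpl16: 9-bp micro-exon, minus strand
  rpl16_anchor <- clean_rand(50L)
  cds <- finish_cds(MICROEXON_CONSENSUS$rpl16, 408L)
  ivs <- b_block(L, list(anchor = rpl16_anchor,
                         e1 = substr(cds, 1L, 9L),
                         i1 = clean_rand(600L),
                         e2 = substr(cds, 10L, 408L)), "-")
  add_model(gene_model("rpl16", "CDS", list(exon(ivs$e1, 0L, 1L),
                                            exon(ivs$e2, 0L, 2L)),
                       provenance = "truth",
                       product = "ribosomal protein L16"))
  b_spacer(L, 130L)

  ## rps12 full CDS: exon1 (LSC, - strand) + exon2/exon3 planted later in
  ## the IR.  372 bp total; last 26 bp are the conserved terminal pattern.
  rps12_cds <- {
    cons <- MICROEXON_CONSENSUS$rps12_last
    repeat {
      b346 <- sample(c("A", "C", "G"), 1L)
      s <- paste0("ATG", rand_codons(114L), b346, cons)
      stopifnot(nchar(s) == 372L)
      p <- translate_cds(s)
      if (!attr(p, "internal_stop") && !has_ssr_run(s)) break
    }
    s
  }
  rps12_e1_seq <- substr(rps12_cds, 1L, 114L)
  rps12_e2_seq <- substr(rps12_cds, 115L, 346L)
  rps12_e3_seq <- substr(rps12_cds, 347L, 372L)
  rps12_anchor3p <- clean_rand(50L)
  iv_rps12e1 <- b_block(L, list(e1 = rps12_e1_seq), "-")$e1

  ## tandem repeat: 30-bp unit x 4 copies, each copy carrying two private
  ## substitutions so copies never pair as dispersed repeats
  b_spacer(L, 140L)
  t_unit <- clean_rand(30L)
  mutate_at <- function(s, pos) {
    x <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1L]
    paste(x, collapse = "")
  }
  ## three private substitutions per copy (disjoint positions): per-copy
  ## identity 27/30 stays at the 0.9 detection floor while every copy
  ## pair differs at six positions, so no copy pair can surface as a
  ## dispersed repeat (max_mismatch 3)
  copies <- c(mutate_at(t_unit, c(4L, 14L, 24L)),
              mutate_at(t_unit, c(8L, 18L, 28L)),
              mutate_at(t_unit, c(6L, 16L, 26L)),
              mutate_at(t_unit, c(2L, 12L, 22L)))
  tiv <- b_add(L, paste(copies, collapse = ""))
  tan_truth[[1L]] <- list(unit_len = 30L, copies = 4, consensus = t_unit,
                          start = tiv[1L], end = tiv[2L])
  b_spacer(L, 120L)

  ## overlapping genes on opposite strands: psbD (+) and psbN (-); the
  ## last 24 bp of psbD double as the (reverse-complement) stop region of
  ## psbN
  restricted <- setdiff(STOPLESS_CODONS, c("TTA", "CTA", "TCA"))
  psbD_cds <- {
    repeat {
      s <- paste0("ATG", rand_codons(224L), "TTA",
                  paste(sample(restricted, 6L, replace = TRUE), collapse = ""),
                  "TAA")
      stopifnot(nchar(s) == 699L)
      if (!attr(translate_cds(s), "internal_stop") && !has_ssr_run(s)) break
    }
    s
  }
  iv_psbD <- b_block(L, list(cds = psbD_cds), "+")$cds
  add_model(gene_model("psbD", "CDS", list(exon(iv_psbD)),
                       provenance = "truth",
                       product = "photosystem II protein D2"))
  ## psbN: coding seq ends with revcomp of psbD's last 24 bases
  psbN_tail <- revcomp_chr(substr(psbD_cds, 676L, 699L))
  psbN_cds <- {
    repeat {
      s <- paste0("ATG", rand_codons(124L), psbN_tail)
      stopifnot(nchar(s) == 399L)
      if (!attr(translate_cds(s), "internal_stop") && !has_ssr_run(s)) break
    }
    s
  }
  ## genome already holds the overlap; append the non-overlapping remainder
  rest <- substr(revcomp_chr(psbN_cds), 25L, 399L)
  iv_rest <- b_add(L, rest)
  iv_psbN <- interval(iv_psbD$end - 23L, iv_rest[2L], "-")
  add_model(gene_model("psbN", "CDS", list(exon(iv_psbN)),
                       provenance = "truth",
                       product = "photosystem II protein N"))
  b_spacer(L, 110L)

  ## rps2: single-exon CDS, + strand
  cds <- finish_cds("ATG", 711L)
  iv <- b_block(L, list(cds = cds), "+")$cds
  add_model(gene_model("rps2", "CDS", list(exon(iv)), provenance = "truth",
                       product = "ribosomal protein S2"))

  ## SSR "AAAT" x 5
  b_spacer(L, 65L)
  b_add(L, guard_base(c("A", "T")))
  siv <- b_add(L, strrep("AAAT", 5L))
  b_add(L, guard_base(c("A")))
  ssr_truth[[4L]] <- list(motif = "AAAT", copies = 5L, start = siv[1L], end = siv[2L])
  b_spacer(L, 55L)

  ## four intron-less tRNA loci
  mk_trna <- function(name, anticodon_rna, strand, len = 74L) {
    anti_dna <- chartr("U", "T", anticodon_rna)
    repeat {
      s <- clean_rand(len)
      substr(s, 33L, 35L) <- anti_dna
      if (!has_ssr_run(s)) break
    }
    iv <- b_block(L, list(t = s), strand)$t
    m <- gene_model(name, "tRNA", list(exon(iv)), provenance = "truth",
                    product = paste0("tRNA-", name))
    add_model(m)
    trna_truth[[length(trna_truth) + 1L]] <<-
      list(name = name, anticodon = anticodon_rna, start = iv$start,
           end = iv$end, strand = strand, intron = NULL, seq = s)
    b_spacer(L, 60L)
  }
  mk_trna("trnH-GUG", "GUG", "+")
  mk_trna("trnQ-UUG", "UUG", "-")
  mk_trna("trnS-GCU", "GCU", "+")
  mk_trna("trnT-GGU", "GGU", "-")

  ## dispersed repeat, forward pair: copy 2 (identical, far from copy 1)
  b_add(L, "A"); f2 <- b_add(L, disp_seq); b_add(L, "T")
  disp_truth[[1L]] <- list(a_start = f1[1L], a_end = f1[2L],
                           b_start = f2[1L], b_end = f2[2L],
                           orientation = "forward", length = 40L,
                           mismatches = 0L)

  ## palindromic dispersed repeat: copy P here, revcomp in the SSC
  b_spacer(L, 90L)
  pal_seq <- clean_rand(35L)
  b_add(L, "C"); p1 <- b_add(L, pal_seq); b_add(L, "G")

  left <- n_lsc - (b_len(L))
  if (left < 0L) stop("LSC roster exceeds configured LSC size")
  if (left > 0L) b_spacer(L, left)
  lsc_seq <- paste(L$parts, collapse = "")
  lsc_mutable <- rep(unlist(L$mutable), times = nchar(L$parts))

  ## ================= IRa =================
  A <- new_builder(n_lsc)
  b_spacer(A, 120L)
  mk_rrna <- function(name, len) {
    s <- clean_rand(len)
    iv <- b_block(A, list(r = s), "+")$r
    add_model(gene_model(name, "rRNA", list(exon(iv)), provenance = "truth",
                         product = paste0(name, " ribosomal RNA")))
    b_spacer(A, 70L)
    iv
  }
  mk_rrna("rrn16", 700L)
  mk_rrna("rrn23", 900L)
  mk_rrna("rrn4.5", 95L)
  mk_rrna("rrn5", 110L)

  mk_trna_intron <- function(name, anticodon_rna, e1_len, int_len, e2_len) {
    anti_dna <- chartr("U", "T", anticodon_rna)
    repeat {
      s1 <- clean_rand(e1_len)
      substr(s1, 33L, 35L) <- anti_dna
      if (!has_ssr_run(s1)) break
    }
    s2 <- clean_rand(e2_len)
    ivs <- b_block(A, list(e1 = s1, i1 = clean_rand(int_len), e2 = s2), "+")
    m <- gene_model(name, "tRNA", list(exon(ivs$e1, 0L, 1L), exon(ivs$e2, 0L, 2L)),
                    provenance = "truth", product = paste0("tRNA-", name))
    add_model(m)
    trna_truth[[length(trna_truth) + 1L]] <<-
      list(name = name, anticodon = anticodon_rna, start = ivs$e1$start,
           end = ivs$e2$end, strand = "+",
           intron = c(ivs$e1$end + 1L, ivs$e2$start - 1L),
           seq = paste0(s1, s2))
    b_spacer(A, 80L)
  }
  mk_trna_intron("trnI-GAU", "GAU", 37L, 180L, 35L)
  mk_trna_intron("trnA-UGC", "UGC", 38L, 160L, 35L)

  ## rps12 exons 2 and 3 (+ 3' anchor) inside the IR
  b_spacer(A, 100L)
  ivs <- b_block(A, list(e2 = rps12_e2_seq, i2 = clean_rand(300L),
                         e3 = rps12_e3_seq, anchor = rps12_anchor3p), "+")
  rps12_ira <- ivs

  left <- n_ir - b_len(A)
  if (left < 0L) stop("IR roster exceeds configured IR size")
  if (left > 0L) b_spacer(A, left)
  ira_seq <- paste(A$parts, collapse = "")

  ## ================= SSC =================
  S <- new_builder(n_lsc + n_ir)   # SSC sits between the two IR copies
  b_spacer(S, 150L)

  ## ndhB: editing-site host gene; twelve TCA codons planted at known
  ## codon positions (codon position 2 is the edited C)
  edit_codons <- seq(40L, 480L, by = 40L)
  ndhB_cds <- {
    repeat {
      s <- finish_cds("ATG", 1494L)
      for (ci in edit_codons) {
        substr(s, 3L * (ci - 1L) + 1L, 3L * ci) <- "TCA"
      }
      if (!attr(translate_cds(s), "internal_stop") && !has_ssr_run(s)) break
    }
    s
  }
  iv_ndhB <- b_block(S, list(cds = ndhB_cds), "+")$cds
  add_model(gene_model("ndhB", "CDS", list(exon(iv_ndhB)), provenance = "truth",
                       product = "NADH-plastoquinone oxidoreductase subunit 2"))
  b_spacer(S, 120L)

  ## palindromic partner
  b_add(S, "A"); p2 <- b_add(S, revcomp_chr(pal_seq)); b_add(S, "T")
  disp_truth[[2L]] <- list(a_start = p1[1L], a_end = p1[2L],
                           b_start = p2[1L], b_end = p2[2L],
                           orientation = "palindromic", length = 35L,
                           mismatches = 0L)
  b_spacer(S, 100L)

  ## ndhF: single-exon CDS, - strand
  cds <- finish_cds("ATG", 600L)
  iv <- b_block(S, list(cds = cds), "-")$cds
  add_model(gene_model("ndhF", "CDS", list(exon(iv)), provenance = "truth",
                       product = "NADH-plastoquinone oxidoreductase subunit 5"))

  left <- n_ssc - b_len(S)
  if (left < 0L) stop("SSC roster exceeds configured SSC size")
  if (left > 0L) b_spacer(S, left)
  ssc_seq <- paste(S$parts, collapse = "")

  ## ================= assemble =================
  irb_seq <- revcomp_chr(ira_seq)
  genome_seq <- paste0(lsc_seq, ira_seq, ssc_seq, irb_seq)
  stopifnot(nchar(genome_seq) == n)

  layout <- structure(list(
    lsc = interval(1L, n_lsc),
    ira = interval(n_lsc + 1L, n_lsc + n_ir),
    ssc = interval(n_lsc + n_ir + 1L, n_lsc + n_ir + n_ssc),
    irb = interval(n_lsc + n_ir + n_ssc + 1L, n)),
    class = "quadripartite_layout")

  ## IRa local interval -> IRb mirrored interval (opposite strand)
  ira0 <- n_lsc               # IRa starts at ira0+1
  irb0 <- n_lsc + n_ir + n_ssc
  mirror_iv <- function(iv) {
    lo <- iv$start - ira0; hi <- iv$end - ira0
    interval(irb0 + (n_ir - hi + 1L), irb0 + (n_ir - lo + 1L),
             if (iv$strand == "+") "-" else "+")
  }

  ## duplicate IR-resident genes into IRb (truth only; the reference file
  ## carries one copy per gene)
  ir_genes <- Filter(function(m) {
    sp <- gene_model_span(m)
    sp$start > n_lsc && sp$end <= n_lsc + n_ir
  }, models)
  for (m in ir_genes) {
    ## mirroring reverses genomic order, which IS transcription order on
    ## the minus strand: exon 1 keeps index 1
    exs <- lapply(m$exons, function(e) exon(mirror_iv(e$interval)))
    m2 <- gene_model(m$name, m$kind, exs, provenance = "truth",
                     product = m$product)
    models[[length(models) + 1L]] <- m2
    if (m$kind == "tRNA") {
      tt <- Filter(function(z) z$name == m$name, trna_truth)[[1L]]
      sp <- gene_model_span(m2)
      intr <- NULL
      if (length(m2$exons) == 2L) {
        intr <- c(m2$exons[[1L]]$interval$end + 1L,
                  m2$exons[[2L]]$interval$start - 1L)
        ## exons were reversed by mirroring: transcription order on "-"
        ## runs from high to low coordinates
        intr <- c(min(m2$exons[[1L]]$interval$end, m2$exons[[2L]]$interval$end) + 1L,
                  max(m2$exons[[1L]]$interval$start, m2$exons[[2L]]$interval$start) - 1L)
      }
      trna_truth[[length(trna_truth) + 1L]] <-
        list(name = tt$name, anticodon = tt$anticodon, start = sp$start,
             end = sp$end, strand = "-", intron = intr, seq = tt$seq)
    }
  }

  ## rps12 truth: two transcripts sharing exon 1
  e2_ira <- rps12_ira$e2; e3_ira <- rps12_ira$e3
  e2_irb <- mirror_iv(e2_ira); e3_irb <- mirror_iv(e3_ira)
  t1 <- gene_model("rps12", "CDS",
                   list(exon(iv_rps12e1, 0L, 1L), exon(e2_ira, 0L, 2L),
                        exon(e3_ira, 2L, 3L)),
                   trans_spliced = TRUE, provenance = "truth",
                   transcript_id = "rps12.t1", shared_exon = 1L,
                   product = "ribosomal protein S12")
  t2 <- gene_model("rps12", "CDS",
                   list(exon(iv_rps12e1, 0L, 1L), exon(e2_irb, 2L, 2L),
                        exon(e3_irb, 2L, 3L)),
                   trans_spliced = TRUE, provenance = "truth",
                   transcript_id = "rps12.t2", shared_exon = 1L,
                   product = "ribosomal protein S12")
  models <- c(models, list(t1, t2))
  ref_models[[length(ref_models) + 1L]] <- t1

  ## assign copy numbers to duplicated names (ascending start)
  models <- assign_copy_numbers(models)

  ref_genome <- plastome("fixture_ref", genome_seq)

  ## optional reference-vs-query divergence (substitutions only), applied
  ## outside anchors/micro-exons and outside the IRs
  query_seq <- genome_seq
  if (config$divergence > 0) {
    protected <- rep(FALSE, n)
    protected[(n_lsc + 1L):n] <- TRUE   # IRs + SSC boundary simplification:
    protected[(n_lsc + n_ir + 1L):(n_lsc + n_ir + n_ssc)] <- FALSE
    mark <- function(iv) protected[iv$start:iv$end] <<- TRUE
    for (nm in c("petB", "petD", "rpl16")) {
      m <- Filter(function(x) x$name == nm, models)[[1L]]
      mark(m$exons[[1L]]$interval)
    }
    ## anchors: 50 bp upstream (in transcription orientation) of each
    ## micro-exon; rps12 3' anchor region lives in the IR (already protected)
    x <- strsplit(query_seq, "", fixed = TRUE)[[1L]]
    mut <- runif(n) < config$divergence & !protected
    for (i in which(mut)) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[
      sample.int(3L, 1L)]
    query_seq <- paste(x, collapse = "")
  }
  genome <- plastome("fixture", query_seq)

  truth_ann <- annotation_set("fixture", models, layout)

  ## planted repeat tables
  ssr <- do.call(rbind, lapply(ssr_truth, as.data.frame))
  tan <- do.call(rbind, lapply(tan_truth, as.data.frame))
  disp <- do.call(rbind, lapply(disp_truth, as.data.frame))

  editing <- data.frame(
    position = iv_ndhB$start + 3L * (edit_codons - 1L) + 1L,
    gene = "ndhB", strand = "+",
    level = rep(c(0.3, 0.45, 0.6), length.out = length(edit_codons)),
    codon_index = edit_codons, stringsAsFactors = FALSE)

  ## heteroplasmic SNPs in mutable LSC filler, well apart from each other
  mut_pos <- which(lsc_mutable)
  mut_pos <- mut_pos[mut_pos > 50L & mut_pos < n_lsc - 50L]
  vp <- sort(sample(mut_pos, 200L))
  vp <- vp[c(TRUE, diff(vp) > 60L)][1:15]
  refb <- substring(genome_seq, vp, vp)
  altb <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
  variants <- data.frame(position = vp, ref = refb, alt = unname(altb),
                         fraction = 0.3, stringsAsFactors = FALSE)

  structure(list(genome = genome, ref_genome = ref_genome, layout = layout,
                 annotation = truth_ann, ref_models = ref_models,
                 repeats = list(ssr = ssr, tandem = tan, dispersed = disp),
                 variants = variants, editing = editing,
                 trna_truth = trna_truth,
                 seed = seed, config = config),
            class = "fixture_truth")
}

## suffix duplicate gene names with a copy index in ascending start order;
## stored in model$copy (1 for unique models)
assign_copy_numbers <- function(models) {
  nm <- vapply(models, function(m) paste0(m$name, "|", m$transcript_id %||% ""),
               character(1L))
  for (u in unique(nm)) {
    idx <- which(nm == u)
    if (length(idx) == 1L) { models[[idx]]$copy <- 1L; next }
    starts <- vapply(idx, function(i) gene_model_span(models[[i]])$start,
                     integer(1L))
    for (r in seq_along(idx)) {
      models[[idx[order(starts)][r]]]$copy <- r
    }
  }
  models
}

#' Write fixture files (FASTA genome + reference GenBank)
#'
#' @param truth A `fixture_truth`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`fasta`, `reference`).
#' @export
fixture_write <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  writeLines(c(paste0(">", truth$genome$id),
               substring(truth$genome$sequence,
                         seq(1L, truth$genome$length, 70L),
                         pmin(seq(1L, truth$genome$length, 70L) + 69L,
                              truth$genome$length))),
             fasta)
  ref <- file.path(dir, "reference.gb")
  ref_ann <- annotation_set(truth$ref_genome$id, truth$ref_models)
  write_genbank(ref_ann, truth$ref_genome, ref)
  list(fasta = fasta, reference = ref)
}

## ---- read simulation ------------------------------------------------------

#' Simulate aligned reads over a fixture genome
#'
#' Uniform gapless reads with CIGAR `<len>M`, emitted with their true
#' coordinates so no mapper is needed.  `dna` mode injects the planted
#' heteroplasmic variants at their fractions; `rna` mode samples reads
#' only from exonic regions (exons at least `read_len` long) and injects
#' the planted C-to-U editing sites at their levels.
#'
#' @param truth A `fixture_truth`.
#' @param mode `"dna"` or `"rna"`.
#' @param depth Target mean coverage.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return A list with `sam` (character lines) and `fastq` (character
#'   lines, 4 per read).
#' @export
simulate_reads <- function(truth, mode = c("dna", "rna"), depth = 50L,
                           read_len = 100L, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  g <- truth$genome
  n <- g$length
  starts <- integer(0)
  if (mode == "dna") {
    n_reads <- ceiling(depth * n / read_len)
    starts <- sample.int(n - read_len + 1L, n_reads, replace = TRUE)
  } else {
    for (m in truth$annotation$models) {
      if (!is.null(m$transcript_id) && m$transcript_id == "rps12.t2") next
      for (e in m$exons) {
        iv <- e$interval
        len <- iv$end - iv$start + 1L
        if (len < read_len) next
        k <- ceiling(depth * len / read_len)
        starts <- c(starts, iv$start - 1L +
                      sample.int(len - read_len + 1L, k, replace = TRUE))
      }
    }
  }
  reads <- substring(g$sequence, starts, starts + read_len - 1L)
  ## inject planted substitutions
  inject <- function(reads, starts, pos, base, prob) {
    cover <- which(starts <= pos & starts + read_len - 1L >= pos)
    if (length(cover) == 0L) return(reads)
    hit <- cover[stats::runif(length(cover)) < prob]
    for (i in hit) {
      off <- pos - starts[i] + 1L
      substr(reads[i], off, off) <- base
    }
    reads
  }
  if (mode == "dna") {
    for (r in seq_len(nrow(truth$variants))) {
      v <- truth$variants[r, ]
      reads <- inject(reads, starts, v$position, v$alt, v$fraction)
    }
  } else {
    for (r in seq_len(nrow(truth$editing))) {
      e <- truth$editing[r, ]
      ## C->U on the sense strand; on the forward strand this is C->T for
      ## plus-strand genes and G->A for minus-strand genes
      base <- if (e$strand == "+") "T" else "A"
      reads <- inject(reads, starts, e$position, base, e$level)
    }
  }
  flags <- sample(c(0L, 16L), length(starts), replace = TRUE)
  qual <- strrep("I", read_len)
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", g$id, n),
    sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
            seq_along(starts), flags, g$id, starts, read_len, reads, qual)
  )
  fastq <- as.vector(rbind(sprintf("@r%06d", seq_along(starts)),
                           reads, "+", rep(qual, length(starts))))
  list(sam = sam, fastq = fastq, starts = starts)
}

## ---- predictor-file emission ---------------------------------------------

#' Emit synthetic tRNA predictor files from fixture truth
#'
#' Writes a tRNAscan-SE-style tabular file (`scanner_a`; every tRNA locus,
#' reported without introns) and an ARAGORN-style batch file (`scanner_b`;
#' intron-bearing loci with their introns), the inputs the reconciliation
#' rule expects.
#'
#' @param truth A `fixture_truth`.
#' @param dir Output directory.
#' @return Named list of file paths (`a`, `b`).
#' @export
fixture_trna_predictions <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa_of <- function(name) sub("^trn([A-Z]).*$", "\\1", name)
  aa_name <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
               G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
               M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
               S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  a_path <- file.path(dir, "trnascan.out")
  b_path <- file.path(dir, "aragorn.txt")
  a_lines <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----")
  b_lines <- c(paste0(">", truth$genome$id), "")
  bi <- 0L
  for (i in seq_along(truth$trna_truth)) {
    tt <- truth$trna_truth[[i]]
    aa <- aa_of(tt$name)
    anti_dna <- chartr("U", "T", tt$anticodon)
    ## scanner a: begin > end encodes the minus strand; introns omitted
    if (tt$strand == "+") { b0 <- tt$start; e0 <- tt$end }
    else { b0 <- tt$end; e0 <- tt$start }
    a_lines <- c(a_lines, sprintf("%s\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f",
                                  truth$genome$id, i, b0, e0,
                                  aa_name[[aa]], anti_dna, 55 + i))
    if (!is.null(tt$intron)) {
      bi <- bi + 1L
      loc <- sprintf("%s[%d,%d]", if (tt$strand == "-") "c" else "",
                     tt$start, tt$end)
      rel <- tt$intron[1L] - tt$start + 1L
      ilen <- tt$intron[2L] - tt$intron[1L] + 1L
      if (tt$strand == "-") rel <- tt$end - tt$intron[2L] + 1L
      b_lines <- c(b_lines,
                   sprintf("%d   tRNA-%s(%s)   %s   33   (%s)   i(%d,%d)",
                           bi, aa_name[[aa]], tolower(anti_dna), loc,
                           tolower(anti_dna), rel, ilen))
    }
  }
  b_lines[2L] <- sprintf("%d genes found", bi)
  writeLines(a_lines, a_path)
  writeLines(b_lines, b_path)
  list(a = a_path, b = b_path)
}
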