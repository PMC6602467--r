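## Trans-spliced rps12 assembly from individually located exons.
##
## Exons 1 and 2 are located independently by nucleotide search against
## per-exon reference sets (all genomic copies kept); the short last exon
## is located by the anchored micro-exon finder in 3'UTR mode, constrained
## downstream of each exon-2 copy.  Each (exon2, exon3) cassette is joined
## with the single exon 1 into one transcript, so a two-IR genome yields
## two transcripts sharing exon 1.

#' Assemble the trans-spliced rps12 gene
#'
#' @param genome A `plastome`.
#' @param db A `reference_db` containing at least one rps12 entry with
#'   resolved exons.
#' @param layout Optional `quadripartite_layout` (used to sanity-check
#'   exon placement; assembly works without it).
#' @param max_intron Maximum exon2-exon3 intron length (default 2000).
#' @param min_evalue E-value cutoff for the exon searches (default 1e-6).
#' @param anchor_evalue E-value cutoff for the anchored exon-3 scan
#'   (default 1e-20).
#' @param idx_nuc Optional prebuilt nucleotide `search_index`.
#' @return A list of trans-spliced `gene_model`s (possibly length 1-2),
#'   or an empty list with warnings when assembly fails.
#' @export
assemble_rps12 <- function(genome, db, layout = NULL, max_intron = 2000L,
                           min_evalue = 1e-6, anchor_evalue = 1e-20,
                           idx_nuc = NULL) {
  refs <- db_genes(db, "rps12", "CDS")
  if (length(refs) == 0L) stop("no rps12 reference in database")
  if (is.null(idx_nuc)) idx_nuc <- build_search_index(genome, "nucleotide")

  ## choose the reference whose exon-1 search scores best
  pick <- NULL
  for (ref in refs) {
    if (length(ref$exons) < 2L) {
      warning("rps12 reference from ", ref$source_accession,
              " has fewer than 2 exons; skipped")
      next
    }
    h1 <- similarity_search(ref$exons[[1L]]$sequence, idx_nuc, "nucleotide",
                            min_evalue, "rps12.e1")
    if (nrow(h1) == 0L) next
    if (is.null(pick) || h1$score[1L] > pick$score) {
      pick <- list(ref = ref, h1 = h1, score = h1$score[1L])
    }
  }
  if (is.null(pick)) {
    warning("rps12 exon 1 not found in genome")
    return(list())
  }
  ref <- pick$ref
  three_exon <- length(ref$exons) >= 3L
  e1_len <- nchar(ref$exons[[1L]]$sequence)
  e2_len <- nchar(ref$exons[[2L]]$sequence)

  ## ---- exon 1: single locus expected (LSC) ----
  loci1 <- hit_loci(pick$h1, e1_len, idx_nuc$n)
  if (length(loci1) > 1L) {
    in_ir <- vapply(loci1, function(iv) {
      !is.null(layout) &&
        (pos_in_interval(iv$start, layout$ira, idx_nuc$n) ||
         pos_in_interval(iv$start, layout$irb, idx_nuc$n))
    }, logical(1L))
    if (sum(!in_ir) > 1L) {
      warning("rps12 exon 1 found at multiple single-copy loci; keeping best")
    }
    loci1 <- loci1[1L]
  }
  e1_iv <- loci1[[1L]]

  ## ---- exon 2: all copies (typically one per IR) ----
  h2 <- similarity_search(ref$exons[[2L]]$sequence, idx_nuc, "nucleotide",
                          min_evalue, "rps12.e2")
  if (nrow(h2) == 0L) {
    warning("rps12 exon 2 not found; emitting single-exon fragment")
    return(list())
  }
  loci2 <- hit_loci(h2, e2_len, idx_nuc$n)

  ## ---- exon 3 per exon-2 copy (3'UTR anchored) ----
  anchors <- suppressWarnings(build_anchor_table(db))
  a3 <- anchors[anchors$gene == "rps12" & anchors$side == "three_prime" &
                  anchors$valid, , drop = FALSE]
  out <- list()
  loci2 <- loci2[order(vapply(loci2, `[[`, integer(1L), "start"))]
  for (k in seq_along(loci2)) {
    e2_iv <- loci2[[k]]
    exons <- list(exon(e1_iv, 0L, 1L), exon(e2_iv, 0L, 2L))
    partial_3p <- FALSE
    notes <- character(0)
    if (three_exon) {
      e3 <- NULL
      if (nrow(a3)) {
        e3 <- find_small_exon(idx_nuc, a3, anchor_evalue,
                              partner_exon = e2_iv, max_intron = max_intron)
      }
      if (is.null(e3)) {
        warning("rps12 exon 3 not found downstream of exon 2 copy ", k,
                "; transcript emitted as 2-exon partial")
        partial_3p <- TRUE
      } else {
        exons[[3L]] <- exon(e3$interval, 0L, 3L)
      }
    }
    ivs <- lapply(exons, `[[`, "interval")
    model <- gene_model("rps12", "CDS", make_phased_exons(ivs, genome),
                        strand = if (length(unique(vapply(ivs, `[[`, character(1L), "strand"))) > 1L)
                          "mixed" else ivs[[1L]]$strand,
                        trans_spliced = TRUE,
                        partial_3p = partial_3p,
                        provenance = "itgie",
                        transcript_id = sprintf("rps12.t%d", k),
                        shared_exon = 1L,
                        product = ref$product %||% "ribosomal protein S12",
                        notes = notes)
    cds <- gene_model_cds(model, genome)
    if (!partial_3p) {
      if (nchar(cds) %% 3L != 0L ||
          substr(cds, 1L, 3L) != "ATG" ||
          !substr(cds, nchar(cds) - 2L, nchar(cds)) %in% STOP_CODONS) {
        warning("assembled rps12 transcript ", k,
                " is not a clean ORF; kept with note")
        model$notes <- c(model$notes, "assembled CDS fails ORF checks")
      }
    }
    attr(model, "score") <- pick$score
    out[[length(out) + 1L]] <- model
  }
  out
}

## collapse HSPs into distinct full-length loci: project the full query
## extent through each hit (gapless) and deduplicate overlapping loci,
## keeping the best-scoring hit per locus
hit_loci <- function(hits, qlen, glen) {
  loci <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$strand == "+") {
      fs <- h$t_start - (h$q_start - 1L); fe <- fs + qlen - 1L
    } else {
      fe <- h$t_end + (h$q_start - 1L); fs <- fe - qlen + 1L
    }
    if (fs < 1L || fe > glen) next
    iv <- interval(fs, fe, h$strand)
    dup <- FALSE
    for (x in loci) {
      ov <- min(x$end, iv$end) - max(x$start, iv$start) + 1L
      if (ov > 0.5 * qlen) { dup <- TRUE; break }
    }
    if (!dup) loci[[length(loci) + 1L]] <- iv
  }
  loci
}
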