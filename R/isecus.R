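## Anchored micro-exon detection.
##
## Micro-exons (6-9 bp here) are invisible to similarity search on their
## own.  The finder scans the genome with the concatenation of a conserved
## 50-bp UTR anchor and the reference micro-exon, then cuts the exon out
## of the hit footprint by the reference exon length: from the 3' end for
## 5'UTR anchors (petB/petD/rpl16 first exons), from the 5' end for the
## 3'UTR-anchored rps12 last exon.

#' Locate a micro-exon through its conserved UTR anchor
#'
#' @param genome A `plastome` (or prebuilt nucleotide `search_index`).
#' @param anchors Anchor table rows (see [build_anchor_table()]) for one
#'   gene and one side.
#' @param evalue_cutoff BLAST-style E-value cutoff for the anchored scan
#'   (default 1e-20).
#' @param partner_exon Optional `gint`: the neighbouring exon the
#'   micro-exon must splice to.  5' micro-exons must lie upstream of it in
#'   transcription orientation, 3' micro-exons downstream, within
#'   `max_intron`.
#' @param max_intron Maximum intron length (default 2000).
#' @return An `exon` whose interval spans exactly `exon_len` bases and
#'   which starts with ATG (5' side) or ends with a stop codon (3' side);
#'   `NULL` with a warning when no anchor yields an admissible exon.
#'   Attributes: `gene`, `side`, `score`, `anchor_accession`.
#' @export
find_small_exon <- function(genome, anchors, evalue_cutoff = 1e-20,
                            partner_exon = NULL, max_intron = 2000L) {
  stopifnot(nrow(anchors) >= 1L, evalue_cutoff > 0)
  gene <- unique(anchors$gene); side <- unique(anchors$side)
  stopifnot(length(gene) == 1L, length(side) == 1L,
            side %in% c("five_prime", "three_prime"))
  idx <- if (inherits(genome, "search_index")) genome
         else build_search_index(genome, "nucleotide")
  glen <- idx$n
  gseq <- idx$fwd
  best <- NULL

  for (r in seq_len(nrow(anchors))) {
    a <- anchors[r, ]
    query <- if (side == "five_prime") paste0(a$anchor_seq, a$exon_seq)
             else paste0(a$exon_seq, a$anchor_seq)
    qlen <- nchar(query)
    hits <- similarity_search(query, idx, "nucleotide",
                              min_evalue = evalue_cutoff,
                              query_gene = gene)
    if (nrow(hits) == 0L) next
    for (h in seq_len(nrow(hits))) {
      hit <- hits[h, ]
      ## project the full query extent onto the genome (gapless
      ## assumption) so alignment trimming cannot shift the exon cut
      if (hit$strand == "+") {
        fs <- hit$t_start - (hit$q_start - 1L)
        fe <- hit$t_end + (qlen - hit$q_end)
      } else {
        fs <- hit$t_start - (qlen - hit$q_end)
        fe <- hit$t_end + (hit$q_start - 1L)
      }
      if (fs < 1L || fe > glen) {
        warning("anchored hit for ", gene, " footprint out of genome bounds; skipped")
        next
      }
      if (fe - fs + 1L < a$exon_len) {
        warning("anchored hit for ", gene, " shorter than reference exon; skipped")
        next
      }
      ## cut the exon from the footprint in transcription orientation
      ex_iv <- micro_exon_interval(fs, fe, hit$strand, side, a$exon_len)
      ex_seq <- extract_seq(plastome_stub(gseq), ex_iv)
      ok <- if (side == "five_prime") {
        substr(ex_seq, 1L, 3L) == "ATG"
      } else {
        substr(ex_seq, nchar(ex_seq) - 2L, nchar(ex_seq)) %in% STOP_CODONS
      }
      if (!ok) next
      if (!is.null(partner_exon) &&
          !micro_exon_admissible(ex_iv, partner_exon, side, max_intron)) next
      cand <- list(iv = ex_iv, score = hit$score,
                   dist = partner_distance(ex_iv, partner_exon),
                   accession = a$source_accession)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
           (cand$dist < best$dist ||
            (cand$dist == best$dist && cand$iv$start < best$iv$start)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    warning("no admissible micro-exon found for ", gene, " (", side, ")")
    return(NULL)
  }
  structure(exon(best$iv, 0L, 1L), gene = gene, side = side,
            score = best$score, anchor_accession = best$accession)
}

## cheap plastome wrapper around a validated sequence (skips re-validation)
plastome_stub <- function(seqstr) {
  structure(list(id = "stub", sequence = seqstr, circular = TRUE,
                 length = nchar(seqstr)), class = "plastome")
}

micro_exon_interval <- function(fs, fe, strand, side, exon_len) {
  if (side == "five_prime") {
    ## exon is the 3'-most exon_len bases of the footprint
    if (strand == "+") interval(fe - exon_len + 1L, fe, "+")
    else interval(fs, fs + exon_len - 1L, "-")
  } else {
    ## exon is the 5'-most exon_len bases of the footprint
    if (strand == "+") interval(fs, fs + exon_len - 1L, "+")
    else interval(fe - exon_len + 1L, fe, "-")
  }
}

## strand-aware up/downstream constraint relative to the partner exon
micro_exon_admissible <- function(ex_iv, partner, side, max_intron) {
  if (ex_iv$strand != partner$strand) return(FALSE)
  if (side == "five_prime") {
    gap <- if (ex_iv$strand == "+") partner$start - ex_iv$end - 1L
           else ex_iv$start - partner$end - 1L
  } else {
    gap <- if (ex_iv$strand == "+") ex_iv$start - partner$end - 1L
           else partner$start - ex_iv$end - 1L
  }
  gap >= 0L && gap <= max_intron
}

partner_distance <- function(ex_iv, partner) {
  if (is.null(partner)) return(0L)
  abs((ex_iv$start + ex_iv$end) / 2 - (partner$start + partner$end) / 2)
}
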