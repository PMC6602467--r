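## NCBI five-column feature table (.tbl) + matching FASTA (.fsa): the
## modern replacement for Sequin submission files.

tbl_pos <- function(p, marker = "") paste0(marker, p)

## interval lines in transcription order; minus strand encoded by
## start > end, as the tbl dialect requires
tbl_intervals <- function(model, genome_length) {
  segs <- list()
  for (e in model$exons) {
    iv <- e$interval
    if (iv$wraps_origin) {
      if (iv$strand == "+") {
        segs <- c(segs, list(c(iv$start, genome_length), c(1L, iv$end)))
      } else {
        segs <- c(segs, list(c(iv$end, 1L), c(genome_length, iv$start)))
      }
    } else {
      segs <- c(segs, list(if (iv$strand == "+") c(iv$start, iv$end)
                           else c(iv$end, iv$start)))
    }
  }
  segs
}

#' Write the NCBI feature table and submission FASTA
#'
#' Emits the five-column `.tbl` dialect (`>Feature` header, tab-separated
#' interval lines, qualifiers on continuation lines; partial 5'/3' ends
#' marked `<` / `>`) plus the `.fsa` sequence file.
#'
#' @param annotation An `annotation_set`.
#' @param genome A `plastome`.
#' @param base Output path without extension; `<base>.tbl` and
#'   `<base>.fsa` are written.
#' @return Named list of the two paths, invisibly.
#' @export
write_feature_table <- function(annotation, genome, base) {
  n <- genome$length
  lines <- sprintf(">Feature %s", genome$id)
  qual <- function(k, v) sprintf("\t\t\t%s\t%s", k, v)
  for (m in annotation$models) {
    segs <- tbl_intervals(m, n)
    sp <- gene_model_span(m)
    gene_seg <- if (m$trans_spliced) segs else {
      if (sp$strand == "-") list(c(sp$end, sp$start)) else list(c(sp$start, sp$end))
    }
    for (i in seq_along(gene_seg)) {
      s <- gene_seg[[i]]
      key <- if (i == 1L) "gene" else ""
      lines <- c(lines, paste0(s[1L], "\t", s[2L], if (nzchar(key)) paste0("\t", key)))
    }
    lines <- c(lines, qual("gene", m$name))
    key <- switch(m$kind, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA")
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      a <- as.character(s[1L]); b <- as.character(s[2L])
      if (i == 1L && m$partial_5p) a <- paste0("<", a)
      if (i == length(segs) && m$partial_3p) b <- paste0(">", b)
      lines <- c(lines, paste0(a, "\t", b, if (i == 1L) paste0("\t", key)))
    }
    lines <- c(lines, qual("gene", m$name))
    if (!is.null(m$product) && !is.na(m$product %||% NA)) {
      lines <- c(lines, qual("product", m$product))
    }
    if (m$trans_spliced) lines <- c(lines, qual("exception", "trans-splicing"))
    if (m$kind == "CDS") lines <- c(lines, qual("codon_start", "1"))
  }
  tbl <- paste0(base, ".tbl"); fsa <- paste0(base, ".fsa")
  writeLines(lines, tbl)
  writeLines(c(sprintf(">%s [location=chloroplast] [topology=circular]", genome$id),
               substring(genome$sequence, seq(1L, n, 70L),
                         pmin(seq(1L, n, 70L) + 69L, n))), fsa)
  invisible(list(tbl = tbl, fsa = fsa))
}
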