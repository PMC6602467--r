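## GFF3 writer and round-trip reader.
##
## Encoding: gene -> (mRNA | tRNA | rRNA) -> exon (+ CDS for coding
## models).  Trans-spliced rps12 is one gene with two mRNA children; the
## shared exon 1 is a single exon feature carrying both transcript IDs in
## its Parent attribute.  Origin-wrapping features are split into two
## segment lines sharing one ID.  Coordinates 1-based inclusive.

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}
gff_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

model_uid <- function(m) {
  base <- if (!is.null(m$transcript_id)) m$transcript_id else m$name
  if (!is.null(m$copy) && m$copy > 1L) paste0(base, "_", m$copy) else base
}

#' Write an annotation set as GFF3
#'
#' @param annotation An `annotation_set`.
#' @param genome A `plastome`.
#' @param path Output path; `NULL` returns lines only.
#' @return Character vector of GFF3 lines, invisibly.
#' @export
write_gff3 <- function(annotation, genome, path = NULL) {
  n <- genome$length
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, n))
  src <- "plastannot"
  ## group models into genes: trans-spliced transcripts share one gene
  groups <- split(seq_along(annotation$models),
                  vapply(annotation$models, function(m)
                    paste0(m$name, "|", m$copy %||% 1L,
                           if (isTRUE(m$trans_spliced)) "|ts" else paste0("|", m$transcript_id %||% "")),
                    character(1L)))
  ## stable order: by genomic start of the first model in each group
  ord <- order(vapply(groups, function(idx)
    gene_model_span(annotation$models[[idx[1L]]])$start, integer(1L)))
  for (idx in groups[ord]) {
    ms <- annotation$models[idx]
    m1 <- ms[[1L]]
    gid <- paste0("gene:", m1$name,
                  if ((m1$copy %||% 1L) > 1L) paste0("_", m1$copy) else "")
    span_s <- min(vapply(ms, function(m) gene_model_span(m)$start, integer(1L)))
    span_e <- max(vapply(ms, function(m) gene_model_span(m)$end, integer(1L)))
    gstrand <- if (m1$strand == "mixed") "+" else m1$strand
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                              genome$id, src, span_s, span_e, gstrand,
                              gid, gff_escape(m1$name)))
    shared_exon_written <- FALSE
    for (m in ms) {
      tid <- paste0("transcript:", model_uid(m))
      ttype <- switch(m$kind, CDS = "mRNA", rRNA = "rRNA", tRNA = "tRNA")
      sp <- gene_model_span(m)
      attrs <- sprintf("ID=%s;Parent=%s", tid, gid)
      extras <- c(
        if (isTRUE(m$trans_spliced)) "trans_splicing=true",
        if (m$partial_5p) "partial_5p=true",
        if (m$partial_3p) "partial_3p=true",
        sprintf("provenance=%s", m$provenance),
        if (!is.null(m$product) && !is.na(m$product %||% NA))
          sprintf("product=%s", gff_escape(m$product)))
      attrs <- paste(c(attrs, extras), collapse = ";")
      tstrand <- if (m$strand == "mixed") "+" else m$strand
      lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                genome$id, src, ttype, sp$start, sp$end,
                                tstrand, attrs))
      cum <- 0L
      for (e in m$exons) {
        iv <- e$interval
        eid <- paste0("exon:", model_uid(m), ".", e$ordinal)
        parent <- tid
        if (isTRUE(m$trans_spliced) && identical(e$ordinal, m$shared_exon)) {
          ## one shared exon feature with all transcript parents
          if (shared_exon_written) { cum <- cum + interval_span(iv, n); next }
          parent <- paste(vapply(ms, function(z)
            paste0("transcript:", model_uid(z)), character(1L)),
            collapse = ",")
          eid <- paste0("exon:", m1$name,
                        if ((m1$copy %||% 1L) > 1L) paste0("_", m1$copy) else "",
                        ".shared", e$ordinal)
          shared_exon_written <- TRUE
        }
        segs <- if (iv$wraps_origin) {
          list(c(iv$start, n), c(1L, iv$end))
        } else list(c(iv$start, iv$end))
        for (sg in segs) {
          lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;ordinal=%d",
                                    genome$id, src, sg[1L], sg[2L],
                                    iv$strand, eid, parent, e$ordinal))
          if (m$kind == "CDS") {
            lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s.%d;Parent=%s;ordinal=%d",
                                      genome$id, src, sg[1L], sg[2L],
                                      iv$strand, e$phase, model_uid(m),
                                      e$ordinal, tid, e$ordinal))
          }
        }
        cum <- cum + interval_span(iv, n)
      }
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' Reconstructs the annotation set (models with exon structure, strand,
#' partial flags, trans-splicing and copy numbering).
#'
#' @param path GFF3 file path (or character vector of lines).
#' @return An `annotation_set` (layout not persisted in GFF3 and left
#'   `NULL`).
#' @export
read_gff3 <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  glen <- NA_integer_
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) glen <- as.integer(strsplit(sr[1L], "\\s+")[[1L]][4L])
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(annotation_set("unknown", list()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  seqid <- f[[1L]][1L]
  parse_attrs <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- vapply(kv, function(z) gff_unescape(z[2L] %||% ""), character(1L))
    names(vals) <- vapply(kv, `[[`, character(1L), 1L)
    vals
  }
  rows <- lapply(f, function(z) list(type = z[3L],
                                     start = as.integer(z[4L]),
                                     end = as.integer(z[5L]),
                                     strand = z[7L], phase = z[8L],
                                     attrs = parse_attrs(z[9L])))
  transcripts <- Filter(function(r) r$type %in% c("mRNA", "rRNA", "tRNA"), rows)
  exons <- Filter(function(r) r$type == "exon", rows)
  models <- list()
  for (tr in transcripts) {
    tid <- tr$attrs[["ID"]]
    kind <- switch(tr$type, mRNA = "CDS", rRNA = "rRNA", tRNA = "tRNA")
    ex <- Filter(function(r) tid %in% strsplit(r$attrs[["Parent"]], ",",
                                               fixed = TRUE)[[1L]], exons)
    ords <- vapply(ex, function(r) as.integer(r$attrs[["ordinal"]]), integer(1L))
    ex <- ex[order(ords)]
    ords <- sort(ords)
    ivs <- list()
    for (u in unique(ords)) {
      segs <- ex[ords == u]
      if (length(segs) == 2L) {
        ## origin-wrapping exon split into two segments sharing an ID
        hi <- segs[[which.max(vapply(segs, `[[`, integer(1L), "start"))]]
        lo <- segs[[which.min(vapply(segs, `[[`, integer(1L), "start"))]]
        ivs[[length(ivs) + 1L]] <- interval(hi$start, lo$end, hi$strand,
                                            wraps_origin = TRUE)
      } else {
        s1 <- segs[[1L]]
        ivs[[length(ivs) + 1L]] <- interval(s1$start, s1$end, s1$strand)
      }
    }
    a <- tr$attrs
    name <- sub("^gene:", "", a[["Parent"]])
    copy <- 1L
    if (grepl("_(\\d+)$", name)) {
      copy <- as.integer(sub(".*_(\\d+)$", "\\1", name))
      name <- sub("_(\\d+)$", "", name)
    }
    trans <- identical(a["trans_splicing"][[1L]], "true")
    tid_short <- sub("^transcript:", "", tid)
    if (copy > 1L) tid_short <- sub(paste0("_", copy, "$"), "", tid_short)
    exl <- {
      cumlen <- 0L
      out <- vector("list", length(ivs))
      for (ii in seq_along(ivs)) {
        out[[ii]] <- exon(ivs[[ii]], (3L - (cumlen %% 3L)) %% 3L, ii)
        cumlen <- cumlen + interval_span(ivs[[ii]], glen)
      }
      out
    }
    m <- gene_model(
      name, kind, exl,
      trans_spliced = trans,
      partial_5p = identical(a["partial_5p"][[1L]], "true"),
      partial_3p = identical(a["partial_3p"][[1L]], "true"),
      provenance = a["provenance"][[1L]] %||% "core",
      transcript_id = if (trans) tid_short else NULL,
      shared_exon = if (trans) 1L else NULL,
      product = if (!is.na(a["product"][[1L]])) a[["product"]] else NULL)
    m$copy <- copy
    models[[length(models) + 1L]] <- m
  }
  annotation_set(seqid, models)
}

#' Canonical comparison key of a gene model
#'
#' Captures name, kind, strand, flags and exact exon coordinates; two
#' models with equal keys describe the same annotation.
#'
#' @param m A `gene_model`.
#' @return A single string.
#' @export
model_key <- function(m) {
  paste(m$name, m$kind, m$strand, m$copy %||% 1L,
        m$transcript_id %||% "", isTRUE(m$trans_spliced),
        m$partial_5p, m$partial_3p,
        paste(vapply(m$exons, function(e)
          sprintf("%d-%d%s%s", e$interval$start, e$interval$end,
                  e$interval$strand,
                  if (e$interval$wraps_origin) "w" else ""), character(1L)),
          collapse = ";"),
        sep = "|")
}
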