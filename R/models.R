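## GeneModel / AnnotationSet containers and their invariant checks.

#' Construct an exon
#'
#' @param interval A `gint`.
#' @param phase Codon phase 0/1/2 at the exon start (CDS only).
#' @param ordinal 1-based order of the exon in the transcript.
#' @return An `exon` object.
#' @export
exon <- function(interval, phase = 0L, ordinal = 1L) {
  stopifnot(inherits(interval, "gint"), phase %in% 0:2, ordinal >= 1L)
  structure(list(interval = interval, phase = as.integer(phase),
                 ordinal = as.integer(ordinal)),
            class = "exon")
}

#' Construct a gene model
#'
#' A strand-aware, possibly trans-spliced multi-exon gene structure.
#' Exons are kept in transcription order.
#'
#' @param name Gene symbol (e.g. `petB`).
#' @param kind One of `CDS`, `rRNA`, `tRNA`.
#' @param exons List of `exon` objects in transcription order.
#' @param strand `"+"`, `"-"`, or `"mixed"` for trans-spliced models.
#' @param trans_spliced Logical.
#' @param partial_5p,partial_3p Logical partial-end flags.
#' @param provenance One of `core`, `isecus`, `itgie`, `trna`, `truth`.
#' @param transcript_id Optional transcript identifier (trans-spliced).
#' @param shared_exon Optional ordinal of the exon shared across
#'   transcripts of a trans-spliced gene.
#' @param product Optional product description.
#' @param notes Character vector of free-text notes.
#' @return A `gene_model`.
#' @export
gene_model <- function(name, kind, exons, strand = NULL,
                       trans_spliced = FALSE,
                       partial_5p = FALSE, partial_3p = FALSE,
                       provenance = "core", transcript_id = NULL,
                       shared_exon = NULL, product = NULL,
                       notes = character(0)) {
  stopifnot(kind %in% c("CDS", "rRNA", "tRNA"), length(exons) >= 1L)
  exons <- lapply(seq_along(exons), function(i) {
    e <- exons[[i]]; e$ordinal <- i; e
  })
  strands <- vapply(exons, function(e) e$interval$strand, character(1L))
  if (is.null(strand)) {
    strand <- if (length(unique(strands)) == 1L) strands[1L] else "mixed"
  }
  if (strand == "mixed" && !trans_spliced) {
    stop("mixed-strand exons are only legal for trans-spliced models (", name, ")")
  }
  structure(list(name = name, kind = kind, exons = exons, strand = strand,
                 trans_spliced = isTRUE(trans_spliced),
                 partial_5p = isTRUE(partial_5p),
                 partial_3p = isTRUE(partial_3p),
                 provenance = provenance,
                 transcript_id = transcript_id,
                 shared_exon = shared_exon,
                 product = product,
                 notes = notes),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  spans <- vapply(x$exons, function(e)
    sprintf("%d..%d(%s)", e$interval$start, e$interval$end, e$interval$strand),
    character(1L))
  cat(sprintf("<gene_model> %s [%s, %s] %s%s\n", x$name, x$kind, x$strand,
              paste(spans, collapse = ","),
              if (x$trans_spliced) " trans-spliced" else ""))
  invisible(x)
}

#' Spliced coding/transcript sequence of a model
#'
#' Concatenates exon sequences in transcription order, each on its own
#' strand.
#'
#' @param model A `gene_model`.
#' @param genome A `plastome`.
#' @return Character string.
#' @export
gene_model_cds <- function(model, genome) {
  paste(vapply(model$exons, function(e) extract_seq(genome, e$interval),
               character(1L)), collapse = "")
}

#' Genomic span of a model (min start, max end over exons)
#' @param model A `gene_model`.
#' @return List with `start`, `end`, `strand`.
#' @export
gene_model_span <- function(model) {
  st <- min(vapply(model$exons, function(e) e$interval$start, integer(1L)))
  en <- max(vapply(model$exons, function(e) e$interval$end, integer(1L)))
  list(start = st, end = en, strand = if (model$strand == "mixed") "+" else model$strand)
}

#' Total exonic length of a model in bp
#' @param model A `gene_model`.
#' @param genome_length Needed when an exon wraps the origin.
#' @return Integer.
#' @export
gene_model_length <- function(model, genome_length = NULL) {
  sum(vapply(model$exons, function(e) interval_span(e$interval, genome_length),
             integer(1L)))
}

#' Construct an annotation set
#'
#' @param genome_id Genome identifier.
#' @param models List of `gene_model` objects.
#' @param layout Optional `quadripartite_layout`.
#' @param warnings A data.frame of warnings (see [warning_record()]).
#' @return An `annotation_set`.
#' @export
annotation_set <- function(genome_id, models = list(), layout = NULL,
                           warnings = empty_warnings()) {
  structure(list(genome_id = genome_id, models = models, layout = layout,
                 warnings = warnings),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  kinds <- table(vapply(x$models, function(m) m$kind, character(1L)))
  cat(sprintf("<annotation_set> %s: %d models (%s), %d warnings\n",
              x$genome_id, length(x$models),
              paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "),
              nrow(x$warnings)))
  invisible(x)
}

#' Empty warnings table
#' @return Zero-row data.frame with the warning columns.
#' @export
empty_warnings <- function() {
  data.frame(category = character(0), subject = character(0),
             severity = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Create a one-row warning record
#' @param category Short machine-readable category.
#' @param subject Feature or file the warning is about.
#' @param message Human-readable message (non-empty).
#' @param severity `"info"` or `"warn"`.
#' @return One-row data.frame.
#' @export
warning_record <- function(category, subject, message, severity = "warn") {
  stopifnot(nzchar(message), severity %in% c("info", "warn"))
  data.frame(category = category, subject = subject, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

#' Validate gene-model invariants
#'
#' Checks exon ordering/overlap, CDS length divisibility, start/stop
#' codons and internal stops for complete CDS models.
#'
#' @param model A `gene_model`.
#' @param genome A `plastome`.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_gene_model <- function(model, genome) {
  bad <- character(0)
  n <- genome$length
  ivs <- lapply(model$exons, function(e) e$interval)
  for (iv in ivs) {
    if (iv$start < 1L || iv$end > n) bad <- c(bad, "exon outside genome bounds")
  }
  ## pairwise non-overlap (linearized; wrapping exons skipped in this check)
  plain <- Filter(function(iv) !iv$wraps_origin, ivs)
  if (length(plain) > 1L) {
    rng <- IRanges::IRanges(
      start = vapply(plain, `[[`, integer(1L), "start"),
      end = vapply(plain, `[[`, integer(1L), "end"))
    if (any(IRanges::countOverlaps(rng, rng) > 1L)) {
      bad <- c(bad, "overlapping exons")
    }
  }
  if (model$kind == "CDS") {
    cds <- gene_model_cds(model, genome)
    complete <- !model$partial_5p && !model$partial_3p
    if (complete && nchar(cds) %% 3L != 0L) {
      bad <- c(bad, "complete CDS length not divisible by 3")
    }
    if (complete) {
      if (substr(cds, 1L, 3L) != "ATG") bad <- c(bad, "complete CDS lacks ATG start")
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (!last %in% c("TAA", "TAG", "TGA")) bad <- c(bad, "complete CDS lacks stop codon")
      if (nchar(cds) %% 3L == 0L && nchar(cds) >= 6L) {
        prot <- translate_cds(cds)
        if (attr(prot, "internal_stop") &&
            !any(grepl("internal stop", model$notes))) {
          bad <- c(bad, "internal stop codon without warning note")
        }
      }
    }
  }
  bad
}
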