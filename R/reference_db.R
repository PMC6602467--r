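## Reference GenBank files -> searchable gene/protein/anchor database.

## Gene-name synonym map: GenBank naming of plastid genes is inconsistent.
## Keys are lowercase with punctuation stripped.
GENE_SYNONYMS <- c(
  "rpl-16" = "rpl16", "rps-12" = "rps12", "pet-b" = "petB", "pet-d" = "petD",
  "rrn16s" = "rrn16", "rrn23s" = "rrn23", "rrn5s" = "rrn5",
  "rrn4.5s" = "rrn4.5", "16s rrna" = "rrn16", "23s rrna" = "rrn23"
)

#' Normalize a plastid gene name
#'
#' Case-insensitive canonicalization with a small synonym map.  tRNA names
#' are normalized to `trnX-NNN` with an uppercase RNA-alphabet anticodon.
#'
#' @param name Raw gene name.
#' @return Canonical name string.
#' @export
normalize_gene_name <- function(name) {
  if (is.na(name) || !nzchar(name)) return(NA_character_)
  raw <- trimws(name)
  key <- tolower(raw)
  if (key %in% names(GENE_SYNONYMS)) return(unname(GENE_SYNONYMS[key]))
  ## tRNA: trnX-NNN with anticodon in uppercase RNA alphabet
  m <- regmatches(key, regexec("^trn([a-z])[-_ ]?([acgtu]{3})?$", key))[[1L]]
  if (length(m) && nzchar(m[2L])) {
    aa <- toupper(m[2L])
    anti <- if (nzchar(m[3L])) chartr("T", "U", toupper(m[3L])) else ""
    return(if (nzchar(anti)) sprintf("trn%s-%s", aa, anti) else sprintf("trn%s", aa))
  }
  ## standard plastid style: lowercase stem + capital suffix letter kept as-is
  ## (petB, ndhA, ...) -- fold only fully-upper or fully-lower variants
  if (key %in% c("petb", "petd", "rpl16", "rps12", "matk", "psba", "psbd",
                 "psbn", "ndhb", "ndhf", "atpf", "rps2", "atpb", "rpob")) {
    fixed <- c(petb = "petB", petd = "petD", rpl16 = "rpl16", rps12 = "rps12",
               matk = "matK", psba = "psbA", psbd = "psbD", psbn = "psbN",
               ndhb = "ndhB", ndhf = "ndhF", atpf = "atpF", rps2 = "rps2",
               atpb = "atpB", rpob = "rpoB")
    return(unname(fixed[key]))
  }
  raw
}

## circular-aware slice of a plain sequence; positions outside 1..n wrap
slice_circular <- function(seqstr, from, to, circular = TRUE) {
  n <- nchar(seqstr)
  idx <- from:to
  if (all(idx >= 1L & idx <= n)) return(substr(seqstr, from, to))
  if (!circular) return(NA_character_)
  idx <- ((idx - 1L) %% n) + 1L
  paste(strsplit(seqstr, "", fixed = TRUE)[[1L]][idx], collapse = "")
}

#' Load reference plastomes in GenBank format
#'
#' Every CDS/rRNA/tRNA feature becomes a reference gene with ordered,
#' sequence-resolved exons.  Trans-spliced rps12 records (mixed-strand or
#' `/exception="trans-splicing"` joins) are flagged and kept with their
#' per-exon segments.
#'
#' @param paths Character vector of GenBank file paths.
#' @return A `reference_db`: list with `genes` (list of reference genes)
#'   and `genomes` (per-accession sequence records).
#' @export
load_reference <- function(paths) {
  genes <- list()
  genomes <- list()
  for (path in paths) {
    recs <- tryCatch(read_genbank(path),
                     error = function(e) stop("cannot parse reference ", path,
                                              ": ", conditionMessage(e)))
    for (rec in recs) {
      if (!nzchar(rec$sequence)) {
        stop("reference record ", rec$accession, " in ", path,
             " has no ORIGIN sequence")
      }
      genomes[[rec$accession]] <- list(sequence = rec$sequence,
                                       circular = rec$circular,
                                       length = rec$length)
      keep <- Filter(function(f) f$type %in% c("CDS", "rRNA", "tRNA"),
                     rec$features)
      qget <- function(q, key) if (key %in% names(q)) q[[key]] else NA_character_
      for (f in keep) {
        nm <- normalize_gene_name(qget(f$qualifiers, "gene") %||%
                                  qget(f$qualifiers, "locus_tag"))
        if (is.na(nm)) {
          warning("reference ", rec$accession, ": ", f$type,
                  " feature without /gene skipped")
          next
        }
        segs <- f$location$segments
        exs <- lapply(seq_len(nrow(segs)), function(i) {
          s <- substr(rec$sequence, segs$start[i], segs$end[i])
          if (segs$strand[i] == "-") s <- revcomp_chr(s)
          list(interval = interval(segs$start[i], segs$end[i], segs$strand[i]),
               sequence = s, ordinal = i)
        })
        cds <- paste(vapply(exs, `[[`, character(1L), "sequence"), collapse = "")
        trans <- identical(qget(f$qualifiers, "exception"), "trans-splicing") ||
          length(unique(segs$strand)) > 1L
        protein <- NA_character_
        internal_stop <- FALSE
        if (f$type == "CDS" && nchar(cds) >= 6L && nchar(cds) %% 3L == 0L) {
          p <- translate_cds(cds)
          protein <- as.character(p)
          internal_stop <- attr(p, "internal_stop")
          if (internal_stop) {
            warning("reference CDS ", nm, " (", rec$accession,
                    ") translates with internal stop; kept and flagged")
          }
        }
        genes[[length(genes) + 1L]] <- list(
          name = nm, kind = f$type, exons = exs, cds = cds,
          protein = protein, internal_stop = internal_stop,
          trans_spliced = trans,
          source_accession = rec$accession,
          product = qget(f$qualifiers, "product")
        )
      }
    }
  }
  if (length(genes) == 0L) {
    stop("no CDS/rRNA/tRNA features found in reference file(s): ",
         paste(paths, collapse = ", "))
  }
  structure(list(genes = genes, genomes = genomes), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d genes from %d reference genome(s)\n",
              length(x$genes), length(x$genomes)))
  invisible(x)
}

## all reference genes with a given canonical name
db_genes <- function(db, name = NULL, kind = NULL) {
  g <- db$genes
  if (!is.null(name)) g <- Filter(function(x) x$name == name, g)
  if (!is.null(kind)) g <- Filter(function(x) x$kind == kind, g)
  g
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build the micro-exon anchor table
#'
#' For petB, petD and rpl16 the anchor is the 50 bp of 5' UTR immediately
#' upstream of the exon-1 start codon on the coding strand, paired with
#' the exon-1 sequence.  For rps12 the anchor is the 50 bp immediately
#' downstream of the stop codon on the coding strand, paired with the last
#' exon.  Records are deduplicated on (gene, side, anchor, exon).
#'
#' @param db A `reference_db`.
#' @param anchor_len Anchor length in bp (default 50).
#' @return A data.frame with columns `gene`, `side`, `anchor_seq`,
#'   `exon_seq`, `exon_len`, `source_accession`, `valid`.
#' @export
build_anchor_table <- function(db, anchor_len = 50L) {
  rows <- list()
  five_prime_genes <- c("petB", "petD", "rpl16")
  for (g in db$genes) {
    gen <- db$genomes[[g$source_accession]]
    if (is.null(gen)) next
    if (g$name %in% five_prime_genes && g$kind == "CDS") {
      e1 <- g$exons[[1L]]
      iv <- e1$interval
      anchor <- if (iv$strand == "+") {
        slice_circular(gen$sequence, iv$start - anchor_len, iv$start - 1L,
                       gen$circular)
      } else {
        s <- slice_circular(gen$sequence, iv$end + 1L, iv$end + anchor_len,
                            gen$circular)
        if (is.na(s)) NA_character_ else revcomp_chr(s)
      }
      if (is.na(anchor) || nchar(anchor) < anchor_len) {
        warning("anchor for ", g$name, " (", g$source_accession,
                ") truncated at a non-circular contig edge; dropped")
        next
      }
      valid <- substr(e1$sequence, 1L, 3L) == "ATG"
      if (!valid) warning("reference ", g$name, " exon 1 does not begin with ATG")
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$name, side = "five_prime", anchor_seq = anchor,
        exon_seq = e1$sequence, exon_len = nchar(e1$sequence),
        source_accession = g$source_accession, valid = valid,
        stringsAsFactors = FALSE)
    }
    if (g$name == "rps12" && g$kind == "CDS") {
      el <- g$exons[[length(g$exons)]]
      iv <- el$interval
      anchor <- if (iv$strand == "+") {
        slice_circular(gen$sequence, iv$end + 1L, iv$end + anchor_len,
                       gen$circular)
      } else {
        s <- slice_circular(gen$sequence, iv$start - anchor_len, iv$start - 1L,
                            gen$circular)
        if (is.na(s)) NA_character_ else revcomp_chr(s)
      }
      if (is.na(anchor) || nchar(anchor) < anchor_len) {
        warning("3' anchor for rps12 (", g$source_accession,
                ") truncated at a non-circular contig edge; dropped")
        next
      }
      last3 <- substr(el$sequence, nchar(el$sequence) - 2L, nchar(el$sequence))
      valid <- last3 %in% STOP_CODONS
      if (!valid) warning("reference rps12 last exon does not end with a stop codon")
      rows[[length(rows) + 1L]] <- data.frame(
        gene = "rps12", side = "three_prime", anchor_seq = anchor,
        exon_seq = el$sequence, exon_len = nchar(el$sequence),
        source_accession = g$source_accession, valid = valid,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), side = character(0),
                      anchor_seq = character(0), exon_seq = character(0),
                      exon_len = integer(0), source_accession = character(0),
                      valid = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("gene", "side", "anchor_seq", "exon_seq")]), ,
      drop = FALSE]
}
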