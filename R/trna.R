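## Reconciliation of tRNA predictions from two external predictors.
##
## The predictors themselves (covariance models) are out of scope; this
## module consumes their output files.  The reconciliation rule: keep
## intron-less predictions from scanner A (the tRNAscan-SE role) and
## intron-bearing predictions from scanner B (the ARAGORN role); when a
## kept prediction from each scanner covers the same locus (>= 50%
## reciprocal overlap) the one matching its intron status wins.

AA_THREE_TO_ONE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
                     Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
                     Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
                     Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
                     SeC = "U", Sup = "X", Undet = "X")

empty_trna_predictions <- function() {
  data.frame(source = character(0), name = character(0),
             anticodon = character(0), start = integer(0), end = integer(0),
             strand = character(0), intron_start = integer(0),
             intron_end = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

trna_name <- function(aa_letter, anticodon_dna) {
  sprintf("trn%s-%s", aa_letter, chartr("T", "U", toupper(anticodon_dna)))
}

#' Parse tRNAscan-SE tabular output
#'
#' Accepts the v2 `.out` tabular format: three header lines followed by
#' whitespace-separated columns (sequence name, tRNA number, begin, end,
#' type, anticodon, intron begin, intron end, score).  `begin > end`
#' encodes the minus strand; intron bounds of 0 mean no intron.
#'
#' @param path File path.
#' @return A tRNA prediction data.frame (`source == "scanner_a"`).
#' @export
parse_trnascan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(Sequence|Name|--)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_trna_predictions())
  rows <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 9L) return(NULL)
    b <- as.integer(f[3L]); e <- as.integer(f[4L])
    strand <- if (b <= e) "+" else "-"
    ib <- as.integer(f[7L]); ie <- as.integer(f[8L])
    if (strand == "-") { tmp <- b; b <- e; e <- tmp
                         if (ib > 0L) { t2 <- ib; ib <- ie; ie <- t2 } }
    aa <- AA_THREE_TO_ONE[[f[5L]]] %||% "X"
    data.frame(source = "scanner_a", name = trna_name(aa, f[6L]),
               anticodon = chartr("T", "U", toupper(f[6L])),
               start = b, end = e, strand = strand,
               intron_start = if (ib > 0L) ib else NA_integer_,
               intron_end = if (ie > 0L) ie else NA_integer_,
               score = as.numeric(f[9L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_trna_predictions() else out
}

#' Parse ARAGORN-style batch output
#'
#' Accepts the batch text dialect: a `>name` header, a `N genes found`
#' line, then one line per gene of the form
#' `idx tRNA-Xxx(nnn) c?[start,end] apos (nnn)` with an optional trailing
#' `i(rel_start,len)` token giving the intron start (relative to the gene
#' 5' end, 1-based) and length.  `c[...]` marks the minus strand.
#'
#' @param path File path.
#' @return A tRNA prediction data.frame (`source == "scanner_b"`).
#' @export
parse_aragorn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "tRNA-([A-Za-z]{3})\\(([a-zA-Z]{3})\\)\\s+(c?)\\[(\\d+),(\\d+)\\]",
      ln))[[1L]]
    if (length(m) == 0L) next
    aa <- AA_THREE_TO_ONE[[m[2L]]] %||% "X"
    strand <- if (m[4L] == "c") "-" else "+"
    b <- as.integer(m[5L]); e <- as.integer(m[6L])
    ib <- NA_integer_; ie <- NA_integer_
    mi <- regmatches(ln, regexec("i\\((\\d+),(\\d+)\\)", ln))[[1L]]
    if (length(mi)) {
      rel <- as.integer(mi[2L]); ilen <- as.integer(mi[3L])
      if (strand == "+") { ib <- b + rel - 1L; ie <- ib + ilen - 1L }
      else { ie <- e - rel + 1L; ib <- ie - ilen + 1L }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = "scanner_b", name = trna_name(aa, m[3L]),
      anticodon = chartr("T", "U", toupper(m[3L])),
      start = b, end = e, strand = strand,
      intron_start = ib, intron_end = ie,
      score = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) empty_trna_predictions() else do.call(rbind, rows)
}

#' Parse the neutral TSV tRNA prediction format
#'
#' Columns: name, start, end, strand, anticodon, intron_start,
#' intron_end, score (empty/NA intron columns mean no intron).
#'
#' @param path File path.
#' @param source `"scanner_a"` or `"scanner_b"`.
#' @return A tRNA prediction data.frame.
#' @export
parse_trna_tsv <- function(path, source = "scanner_a") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_trna_predictions())
  data.frame(source = source,
             name = vapply(df$name, normalize_gene_name, character(1L)),
             anticodon = chartr("T", "U", toupper(df$anticodon)),
             start = as.integer(df$start), end = as.integer(df$end),
             strand = df$strand,
             intron_start = suppressWarnings(as.integer(df$intron_start)),
             intron_end = suppressWarnings(as.integer(df$intron_end)),
             score = suppressWarnings(as.numeric(df$score)),
             stringsAsFactors = FALSE)
}

has_intron <- function(p) !is.na(p$intron_start)

#' Reconcile tRNA predictions from the two scanners
#'
#' Keeps every scanner-A prediction without an intron and every scanner-B
#' prediction with one; overlapping keeps resolve by intron status (an
#' intron-bearing locus is trusted to scanner B, an intron-less one to
#' scanner A).  Scanner-A intron-bearing predictions without a scanner-B
#' counterpart are dropped with a warning record, never silently.
#'
#' @param preds_a,preds_b Prediction data.frames (see the parsers).
#' @return A list of tRNA `gene_model`s (exons = interval minus intron),
#'   with a `warnings` attribute (data.frame).
#' @export
reconcile_trna <- function(preds_a, preds_b) {
  warns <- empty_warnings()
  keep <- list()
  if (nrow(preds_a)) {
    for (i in seq_len(nrow(preds_a))) {
      p <- preds_a[i, ]
      if (!has_intron(p)) keep[[length(keep) + 1L]] <- p
      else {
        ## rule closure: scanner A intron predictions are never saved
        counterpart <- FALSE
        if (nrow(preds_b)) {
          for (j in seq_len(nrow(preds_b))) {
            if (reciprocal_overlap(p, preds_b[j, ]) >= 0.5) counterpart <- TRUE
          }
        }
        if (!counterpart) {
          warns <- rbind(warns, warning_record(
            "trna", p$name,
            sprintf("intron-bearing scanner_a prediction %s at %d..%d dropped (no scanner_b counterpart)",
                    p$name, p$start, p$end)))
        }
      }
    }
  }
  if (nrow(preds_b)) {
    for (i in seq_len(nrow(preds_b))) {
      p <- preds_b[i, ]
      if (has_intron(p)) keep[[length(keep) + 1L]] <- p
    }
  }
  ## resolve cross-scanner locus conflicts among keeps: intron => B wins,
  ## no intron => A wins
  drop <- rep(FALSE, length(keep))
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (i >= j || drop[i] || drop[j]) next
      a <- keep[[i]]; b <- keep[[j]]
      if (a$source == b$source) next
      if (reciprocal_overlap(a, b) < 0.5) next
      winner_src <- if (has_intron(a) || has_intron(b)) "scanner_b" else "scanner_a"
      if (a$source == winner_src) drop[j] <- TRUE else drop[i] <- TRUE
    }
  }
  keep <- keep[!drop]
  keep <- keep[order(vapply(keep, function(p) p$start, integer(1L)),
                     vapply(keep, function(p) p$name, character(1L)))]
  models <- lapply(keep, trna_prediction_model)
  structure(models, warnings = warns)
}

reciprocal_overlap <- function(a, b) {
  ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
  if (ov <= 0L) return(0)
  min(ov / (a$end - a$start + 1L), ov / (b$end - b$start + 1L))
}

trna_prediction_model <- function(p) {
  exons <- if (has_intron(p)) {
    e1 <- interval(p$start, p$intron_start - 1L, p$strand)
    e2 <- interval(p$intron_end + 1L, p$end, p$strand)
    ## transcription order: high-coordinate exon first on the minus strand
    if (p$strand == "-") list(exon(e2, 0L, 1L), exon(e1, 0L, 2L))
    else list(exon(e1, 0L, 1L), exon(e2, 0L, 2L))
  } else {
    list(exon(interval(p$start, p$end, p$strand)))
  }
  m <- gene_model(p$name, "tRNA", exons, provenance = "trna",
                  product = paste0("tRNA-", sub("^trn", "", p$name)))
  attr(m, "anticodon") <- p$anticodon
  attr(m, "pred_source") <- p$source
  m
}

#' Validate predicted tRNA names against reference tRNAs
#'
#' Each predicted tRNA sequence is aligned against every reference tRNA;
#' when the best hit's (normalized) name differs from the prediction's
#' name a warning record is emitted naming both.
#'
#' @param models List of tRNA `gene_model`s.
#' @param db A `reference_db` with tRNA genes.
#' @param genome The annotated `plastome` (to extract model sequences).
#' @return A warnings data.frame (possibly zero rows).
#' @export
validate_trna_names <- function(models, db, genome) {
  models <- Filter(function(m) m$kind == "tRNA", models)
  if (length(models) == 0L) return(empty_warnings())
  refs <- db_genes(db, kind = "tRNA")
  if (length(refs) == 0L) {
    return(warning_record("trna_names", "db",
                          "no reference tRNAs; name validation skipped",
                          "info"))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = NUC_MATCH, mismatch = NUC_MISMATCH, baseOnly = FALSE)
  warns <- empty_warnings()
  for (m in models) {
    qseq <- gene_model_cds(m, genome)
    best_name <- NA_character_; best_score <- -Inf
    for (r in refs) {
      for (sub in c(r$cds, revcomp_chr(r$cds))) {
        sc <- Biostrings::score(Biostrings::pairwiseAlignment(
          qseq, sub, type = "local", substitutionMatrix = submat,
          gapOpening = NUC_GAP_OPEN, gapExtension = NUC_GAP_EXT))
        if (sc > best_score) { best_score <- sc; best_name <- r$name }
      }
    }
    if (!is.na(best_name) &&
        normalize_gene_name(m$name) != normalize_gene_name(best_name)) {
      warns <- rbind(warns, warning_record(
        "trna_names", m$name,
        sprintf("predicted name %s differs from best reference hit %s",
                m$name, best_name)))
    }
  }
  warns
}

#' Write the warnings table as TSV
#'
#' @param warnings Warnings data.frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_warnings_tsv <- function(warnings, path) {
  utils::write.table(
    warnings[, c("category", "subject", "severity", "message")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
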