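## Exploratory diversity analyses: read prefiltering, pileup
## construction, heteroplasmic SNP calling and C-to-U RNA-editing site
## detection with codon-effect annotation.
##
## Mapping is out of scope: the module consumes SAM.  Pileup construction
## is delegated to Rsamtools (CIGAR-aware, quality- and flag-filtered);
## the callers are transparent threshold rules on the resulting columns.

PILEUP_BASES <- c("A", "C", "G", "T")

#' Build a per-position pileup from a SAM file
#'
#' CIGAR-aware base counts per strand over aligned bases; reads below
#' `min_mapq`, bases below `min_baseq`, and unmapped / secondary /
#' duplicate-flagged reads are excluded.  Deletions contribute no base
#' count.
#'
#' @param sam Path to a SAM file (or character vector of SAM lines).
#' @param genome The matching `plastome` (reference name and length are
#'   checked against the SAM header).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param min_baseq Minimum base quality (default 20).
#' @return data.frame: `position`, `ref_base`, `<base>_fwd`/`<base>_rev`
#'   counts for A/C/G/T, `depth`; one row per covered position.
#' @export
build_pileup <- function(sam, genome, min_mapq = 20L, min_baseq = 20L) {
  if (length(sam) > 1L || !file.exists(sam[1L])) {
    path <- tempfile(fileext = ".sam")
    writeLines(sam, path)
    sam <- path
  }
  hdr <- grep("^@SQ", readLines(sam, n = 50L), value = TRUE)
  if (length(hdr)) {
    sn <- sub(".*SN:([^\t]+).*", "\\1", hdr[1L])
    ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", hdr[1L]))
    if (sn != genome$id || ln != genome$length) {
      stop("SAM reference (", sn, ", ", ln, " bp) does not match genome (",
           genome$id, ", ", genome$length, " bp)")
    }
  }
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    include_deletions = FALSE, include_insertions = FALSE)
  res <- Rsamtools::pileup(bam,
                           scanBamParam = Rsamtools::ScanBamParam(flag = flags),
                           pileupParam = pp)
  if (nrow(res) == 0L) {
    out <- data.frame(position = integer(0), ref_base = character(0))
    for (b in PILEUP_BASES) { out[[paste0(b, "_fwd")]] <- integer(0)
                              out[[paste0(b, "_rev")]] <- integer(0) }
    out$depth <- integer(0)
    return(out)
  }
  pos <- sort(unique(res$pos))
  out <- data.frame(position = pos,
                    ref_base = substring(genome$sequence, pos, pos),
                    stringsAsFactors = FALSE)
  for (b in PILEUP_BASES) {
    for (st in c("+", "-")) {
      sel <- res$nucleotide == b & res$strand == st
      cnt <- integer(length(pos))
      if (any(sel)) {
        agg <- tapply(res$count[sel], res$pos[sel], sum)
        cnt[match(as.integer(names(agg)), pos)] <- as.integer(agg)
      }
      out[[paste0(b, if (st == "+") "_fwd" else "_rev")]] <- cnt
    }
  }
  out$depth <- rowSums(out[, paste0(rep(PILEUP_BASES, each = 2L),
                                    c("_fwd", "_rev"))])
  out
}

pileup_base_count <- function(pileup, base, strand = NULL) {
  if (is.null(strand)) {
    pileup[[paste0(base, "_fwd")]] + pileup[[paste0(base, "_rev")]]
  } else {
    pileup[[paste0(base, if (strand == "+") "_fwd" else "_rev")]]
  }
}

#' Call SNPs from a pileup with transparent thresholds
#'
#' A column yields one call per alternate base whose total count reaches
#' `min_alt_count` and whose fraction of the column depth reaches
#' `min_alt_fraction`.  Columns passing those rules but with depth below
#' `min_depth` are flagged `low_depth`; alternate alleles seen on only
#' one strand despite >= 10 supporting reads are flagged `strand_bias`.
#'
#' @param pileup data.frame from [build_pileup()].
#' @param min_depth Minimum depth for a PASS call (default 10).
#' @param min_alt_fraction Minimum alternate-allele fraction (default
#'   0.05).
#' @param min_alt_count Minimum alternate-read count (default 3).
#' @return data.frame: `position`, `ref_base`, `alt_base`,
#'   `alt_fraction`, `depth`, `filter`.
#' @export
call_snps <- function(pileup, min_depth = 10L, min_alt_fraction = 0.05,
                      min_alt_count = 3L) {
  rows <- list()
  for (b in PILEUP_BASES) {
    alt_f <- pileup_base_count(pileup, b, "+")
    alt_r <- pileup_base_count(pileup, b, "-")
    alt <- alt_f + alt_r
    sel <- pileup$ref_base != b & alt >= min_alt_count &
      alt / pmax(pileup$depth, 1L) >= min_alt_fraction
    if (!any(sel)) next
    filt <- ifelse(pileup$depth[sel] < min_depth, "low_depth",
                   ifelse((alt_f[sel] == 0L | alt_r[sel] == 0L) &
                            alt[sel] >= 10L, "strand_bias", "PASS"))
    rows[[length(rows) + 1L]] <- data.frame(
      position = pileup$position[sel], ref_base = pileup$ref_base[sel],
      alt_base = b, alt_fraction = alt[sel] / pileup$depth[sel],
      depth = pileup$depth[sel], filter = filt, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(0), ref_base = character(0),
                      alt_base = character(0), alt_fraction = numeric(0),
                      depth = integer(0), filter = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$alt_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call C-to-U RNA-editing sites from an RNA pileup
#'
#' Candidate sites are columns inside CDS exons whose sense-strand
#' genomic base is C with a sense-strand T mismatch (C with T reads on
#' plus-strand genes, G with A reads on minus-strand genes), with depth
#' and editing level above threshold.  Each site is annotated with the
#' codon and amino-acid change implied by the gene model's frame.  Only
#' the C-to-U class (and its antisense mirror) is considered.
#'
#' @param pileup data.frame from [build_pileup()] over RNA-derived reads.
#' @param annotation An `annotation_set` with CDS models.
#' @param genome The `plastome`.
#' @param min_depth Minimum depth (default 10).
#' @param min_level Minimum editing level (default 0.1).
#' @return data.frame: `position`, `gene`, `strand`, `genomic_base`,
#'   `rna_base`, `editing_level`, `depth`, `codon_before`, `codon_after`,
#'   `aa_before`, `aa_after`, `cds_position`.
#' @export
call_editing_sites <- function(pileup, annotation, genome,
                               min_depth = 10L, min_level = 0.1) {
  rows <- list()
  for (m in annotation$models) {
    if (m$kind != "CDS") next
    cds <- gene_model_cds(m, genome)
    ## map CDS positions to genomic positions in transcription order
    gpos <- unlist(lapply(m$exons, function(e) {
      iv <- e$interval
      if (iv$strand == "+") iv$start:iv$end else iv$end:iv$start
    }))
    hit <- match(pileup$position, gpos)       # CDS position or NA
    cand <- which(!is.na(hit))
    for (i in cand) {
      cpos <- hit[i]
      ## sense base at this CDS position
      sense <- substr(cds, cpos, cpos)
      if (sense != "C") next
      ex_strand <- exon_strand_at(m, pileup$position[i])
      edited <- if (ex_strand == "+") pileup_base_count(pileup, "T")[i]
                else pileup_base_count(pileup, "A")[i]
      depth <- pileup$depth[i]
      if (depth < min_depth) next
      level <- edited / depth
      if (level < min_level) next
      ci <- (cpos - 1L) %/% 3L + 1L
      off <- (cpos - 1L) %% 3L + 1L
      codon_before <- substr(cds, 3L * (ci - 1L) + 1L, 3L * ci)
      codon_after <- codon_before
      substr(codon_after, off, off) <- "T"
      aa_b <- as.character(translate_cds(paste0(codon_before, "TAA")))
      aa_a <- as.character(translate_cds(paste0(codon_after, "TAA")))
      aa_b <- if (nzchar(aa_b)) substr(aa_b, 1L, 1L) else "*"
      aa_a <- if (nzchar(aa_a)) substr(aa_a, 1L, 1L) else "*"
      rows[[length(rows) + 1L]] <- data.frame(
        position = pileup$position[i], gene = m$name, strand = ex_strand,
        genomic_base = pileup$ref_base[i], rna_base = if (ex_strand == "+") "T" else "A",
        editing_level = level, depth = depth,
        codon_before = codon_before, codon_after = codon_after,
        aa_before = aa_b, aa_after = aa_a, cds_position = cpos,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(0), gene = character(0),
                      strand = character(0), genomic_base = character(0),
                      rna_base = character(0), editing_level = numeric(0),
                      depth = integer(0), codon_before = character(0),
                      codon_after = character(0), aa_before = character(0),
                      aa_after = character(0), cds_position = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$position, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

exon_strand_at <- function(m, pos) {
  for (e in m$exons) {
    if (pos >= e$interval$start && pos <= e$interval$end) return(e$interval$strand)
  }
  m$exons[[1L]]$interval$strand
}

#' Prefilter reads by similarity to a gene set
#'
#' A read passes when its best local alignment to any gene sequence
#' (either strand) reaches `min_identity` over at least `min_cov` of the
#' read length.  With a mate file, a pair passes when either mate passes.
#'
#' @param fastq Path to a FASTQ file.
#' @param gene_seqs Character vector of gene sequences.
#' @param mate Optional path to the mate FASTQ (pairs kept together).
#' @param min_identity Minimum alignment identity (default 0.9).
#' @param min_cov Minimum fraction of the read aligned (default 0.5).
#' @param out Output FASTQ path (required); with a mate, `.1`/`.2`
#'   suffixed files are written.
#' @return Named list: `n_in`, `n_out`, `n_malformed`, `paths`.
#' @export
prefilter_reads <- function(fastq, gene_seqs, mate = NULL,
                            min_identity = 0.9, min_cov = 0.5, out) {
  stopifnot(length(gene_seqs) >= 1L)
  r1 <- read_fastq_records(fastq)
  r2 <- if (!is.null(mate)) read_fastq_records(mate) else NULL
  pass1 <- reads_pass(r1$seq, gene_seqs, min_identity, min_cov)
  pass <- pass1
  if (!is.null(r2)) {
    if (nrow(r2$df) != nrow(r1$df)) {
      warning("mate files differ in read count; pairing by position up to the shorter")
    }
    k <- min(length(pass1), nrow(r2$df))
    pass2 <- reads_pass(r2$seq, gene_seqs, min_identity, min_cov)
    pass <- rep(FALSE, length(pass1))
    pass[seq_len(k)] <- pass1[seq_len(k)] | pass2[seq_len(k)]
  }
  paths <- character(0)
  if (is.null(r2)) {
    write_fastq_records(r1$df[pass, , drop = FALSE], out)
    paths <- out
  } else {
    p1 <- paste0(out, ".1"); p2 <- paste0(out, ".2")
    k <- min(nrow(r1$df), nrow(r2$df))
    write_fastq_records(r1$df[seq_len(k), ][pass[seq_len(k)], , drop = FALSE], p1)
    write_fastq_records(r2$df[seq_len(k), ][pass[seq_len(k)], , drop = FALSE], p2)
    paths <- c(p1, p2)
  }
  list(n_in = nrow(r1$df), n_out = sum(pass),
       n_malformed = r1$n_malformed + (if (is.null(r2)) 0L else r2$n_malformed),
       paths = paths)
}

read_fastq_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_mal <- 0L
  recs <- list()
  i <- 1L
  while (i + 3L <= length(lines) + 0L) {
    blk <- lines[i:(i + 3L)]
    if (!startsWith(blk[1L], "@") || blk[3L] != "+" && !startsWith(blk[3L], "+") ||
        nchar(blk[2L]) != nchar(blk[4L])) {
      n_mal <- n_mal + 1L
      i <- i + 1L                       # resync one line at a time
      next
    }
    recs[[length(recs) + 1L]] <- blk
    i <- i + 4L
  }
  df <- if (length(recs)) as.data.frame(do.call(rbind, recs),
                                        stringsAsFactors = FALSE)
        else data.frame(V1 = character(0), V2 = character(0),
                        V3 = character(0), V4 = character(0))
  list(df = df, seq = df$V2, n_malformed = n_mal)
}

write_fastq_records <- function(df, path) {
  writeLines(as.vector(t(as.matrix(df))), path)
}

reads_pass <- function(seqs, gene_seqs, min_identity, min_cov) {
  if (length(seqs) == 0L) return(logical(0))
  pass <- rep(FALSE, length(seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  pat <- Biostrings::DNAStringSet(seqs)
  for (g in gene_seqs) {
    for (sub in c(g, revcomp_chr(g))) {
      todo <- which(!pass)
      if (length(todo) == 0L) return(pass)
      aln <- Biostrings::pairwiseAlignment(
        pat[todo], sub, type = "local", substitutionMatrix = submat,
        gapOpening = 4, gapExtension = 1)
      pal <- as.character(Biostrings::alignedPattern(aln))
      sal <- as.character(Biostrings::alignedSubject(aln))
      nm <- mapply(function(a, b) {
        ac <- strsplit(a, "", fixed = TRUE)[[1L]]
        bc <- strsplit(b, "", fixed = TRUE)[[1L]]
        sum(ac == bc & ac != "-")
      }, pal, sal)
      alen <- nchar(pal)
      qlen <- nchar(seqs[todo])
      cov <- (Biostrings::width(Biostrings::pattern(aln))) / qlen
      ident <- ifelse(alen > 0L, nm / alen, 0)
      pass[todo] <- ident >= min_identity & cov >= min_cov
    }
  }
  pass
}

#' Write variant calls as TSV
#' @param calls data.frame from [call_snps()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write editing sites as TSV
#' @param sites data.frame from [call_editing_sites()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_editing_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
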