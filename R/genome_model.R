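## Core sequence/coordinate types and circular-genome arithmetic.
##
## Coordinates are 1-based inclusive everywhere inside the package; the
## writer layer is the single conversion point to external conventions.

#' Construct a plastome object
#'
#' A plastome is a (typically circular) plastid genome sequence held as an
#' uppercase DNA string over the alphabet A, C, G, T, N.
#'
#' @param id Non-empty sequence identifier.
#' @param sequence DNA string; lowercase is accepted and upper-cased, U is
#'   converted to T.
#' @param circular Logical; plastomes are circular unless stated otherwise.
#' @return An object of class `plastome` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @export
plastome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("u", "t", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (!nzchar(sequence)) stop("plastome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("plastome sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         length = nchar(sequence)),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a plastome from a FASTA file
#'
#' Reads the first record of a FASTA file; additional records trigger a
#' warning and are ignored (a plastome is a single circular contig).
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, passed through to [plastome()].
#' @return A `plastome`.
#' @export
read_plastome_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (length(set) > 1L) {
    warning("multiple FASTA records in ", path, "; using the first")
  }
  id <- sub("\\s.*$", "", names(set)[1L])
  plastome(id, as.character(set[[1L]]), circular = circular)
}

#' Construct a genomic interval
#'
#' 1-based inclusive interval on a plastome.  `wraps_origin` marks features
#' crossing the origin of the circular sequence, in which case
#' `start > end` and the span runs start..length,1..end.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param wraps_origin Logical.
#' @return An object of class `gint`.
#' @export
interval <- function(start, end, strand = "+", wraps_origin = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1L, end >= 1L, strand %in% c("+", "-"))
  if (!wraps_origin && start > end) stop("start > end on non-wrapping interval")
  structure(list(start = start, end = end, strand = strand,
                 wraps_origin = isTRUE(wraps_origin)),
            class = "gint")
}

#' @export
print.gint <- function(x, ...) {
  cat(sprintf("<interval> %d..%d (%s)%s\n", x$start, x$end, x$strand,
              if (x$wraps_origin) " wraps origin" else ""))
  invisible(x)
}

#' Span of an interval in bp
#' @param iv A `gint`.
#' @param genome_length Genome length, required when `iv$wraps_origin`.
#' @return Integer span.
#' @export
interval_span <- function(iv, genome_length = NULL) {
  if (iv$wraps_origin) {
    stopifnot(!is.null(genome_length))
    genome_length - iv$start + 1L + iv$end
  } else {
    iv$end - iv$start + 1L
  }
}

## Fast reverse complement on plain character strings.  N maps to N.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Extract interval sequence from a plastome
#'
#' Returns the sequence of `iv` on its own strand (minus-strand intervals
#' are reverse-complemented).  Origin-wrapping intervals are stitched from
#' the two segments.
#'
#' @param genome A `plastome`.
#' @param iv A `gint`.
#' @return Character string.
#' @export
extract_seq <- function(genome, iv) {
  s <- if (iv$wraps_origin) {
    paste0(substr(genome$sequence, iv$start, genome$length),
           substr(genome$sequence, 1L, iv$end))
  } else {
    substr(genome$sequence, iv$start, iv$end)
  }
  if (iv$strand == "-") revcomp_chr(s) else s
}

#' Translate a coding sequence
#'
#' Translation under an NCBI genetic-code table (default 11,
#' bacterial/plant-plastid).  The trailing stop codon is dropped from the
#' returned protein.  Codons containing N translate to `X`.
#'
#' @param cds DNA string, length >= 3.
#' @param genetic_code_table NCBI table number (default 11).
#' @return Character protein string with attributes `internal_stop`
#'   (logical: a stop occurred before the final codon) and `partial`
#'   (logical: `nchar(cds)` was not divisible by 3; the trailing 1-2 bases
#'   were ignored).
#' @export
translate_cds <- function(cds, genetic_code_table = 11L) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) >= 3L)
  cds <- toupper(cds)
  partial <- (nchar(cds) %% 3L) != 0L
  n_codon <- nchar(cds) %/% 3L
  trimmed <- substr(cds, 1L, n_codon * 3L)
  code <- Biostrings::getGeneticCode(as.character(genetic_code_table))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(trimmed),
    genetic.code = code, if.fuzzy.codon = "X", no.init.codon = TRUE
  )))
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  internal_stop <- any(chars[-length(chars)] == "*")
  if (chars[length(chars)] == "*") {
    chars <- chars[-length(chars)]
  }
  ## a protein truncated at the first internal stop is never silently
  ## returned: caller sees the full translation plus the flag
  structure(paste(chars, collapse = ""),
            internal_stop = internal_stop, partial = partial)
}

## ---- inverted repeat detection -------------------------------------------

## All exact maximal matches >= min_len between two strings, found by
## shared k-mer seeding and per-diagonal run merging.  Returns a data.frame
## with columns a_start, b_start, len (1-based in x and y).
exact_matches_min_len <- function(x, y, min_len, k = 24L) {
  k <- min(k, min_len)
  nx <- nchar(x); ny <- nchar(y)
  if (nx < k || ny < k) return(data.frame(a_start = integer(), b_start = integer(), len = integer()))
  xs <- substring(x, seq_len(nx - k + 1L), seq_len(nx - k + 1L) + k - 1L)
  ys <- substring(y, seq_len(ny - k + 1L), seq_len(ny - k + 1L) + k - 1L)
  ## positions of every shared k-mer
  m <- match(xs, ys)                     # first occurrence is not enough:
  shared <- intersect(unique(xs[!is.na(m)]), ys)
  if (length(shared) == 0L) return(data.frame(a_start = integer(), b_start = integer(), len = integer()))
  xi <- which(xs %in% shared); yi <- which(ys %in% shared)
  xmap <- split(xi, xs[xi]); ymap <- split(yi, ys[yi])
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (kmer in names(xmap)) {
    yv <- ymap[[kmer]]
    if (is.null(yv)) next
    xv <- xmap[[kmer]]
    pairs_a <- c(pairs_a, rep(xv, each = length(yv)))
    pairs_b <- c(pairs_b, rep(yv, times = length(xv)))
  }
  if (length(pairs_a) == 0L) return(data.frame(a_start = integer(), b_start = integer(), len = integer()))
  diag <- pairs_b - pairs_a
  ord <- order(diag, pairs_a)
  pairs_a <- pairs_a[ord]; pairs_b <- pairs_b[ord]; diag <- diag[ord]
  ## merge runs of consecutive seeds on the same diagonal
  brk <- c(TRUE, diff(diag) != 0L | diff(pairs_a) > k)
  grp <- cumsum(brk)
  a0 <- tapply(pairs_a, grp, min); a1 <- tapply(pairs_a, grp, max)
  d0 <- tapply(diag, grp, function(z) z[1L])
  res_a <- integer(0); res_b <- integer(0); res_l <- integer(0)
  xc <- strsplit(x, "", fixed = TRUE)[[1L]]
  yc <- strsplit(y, "", fixed = TRUE)[[1L]]
  for (i in seq_along(a0)) {
    ast <- as.integer(a0[[i]]); aen <- as.integer(a1[[i]]) + k - 1L
    d <- as.integer(d0[[i]])
    ## extend left
    while (ast > 1L && ast + d > 1L && xc[ast - 1L] == yc[ast + d - 1L] &&
           xc[ast - 1L] != "N") ast <- ast - 1L
    ## extend right
    while (aen < nx && aen + d < ny && xc[aen + 1L] == yc[aen + d + 1L] &&
           xc[aen + 1L] != "N") aen <- aen + 1L
    len <- aen - ast + 1L
    if (len >= min_len) {
      res_a <- c(res_a, ast); res_b <- c(res_b, ast + d); res_l <- c(res_l, len)
    }
  }
  out <- data.frame(a_start = res_a, b_start = res_b, len = res_l)
  unique(out)
}

#' Detect the inverted-repeat quadripartite structure
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' segments of at least `min_ir_len` bp and labels the resulting four
#' regions so that the longer single-copy region is the LSC.  Circularity
#' is honoured: an IR copy may wrap the origin.
#'
#' @param genome A `plastome`.
#' @param min_ir_len Minimum IR length in bp (default 1000).
#' @return A `quadripartite_layout` (list with `lsc`, `ira`, `ssc`, `irb`
#'   intervals), or `NULL` when no qualifying IR pair exists (IR-lacking
#'   plastomes; a warning is logged, never an error).
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 1000L) {
  stopifnot(inherits(genome, "plastome"))
  n <- genome$length
  if (n < 2L * min_ir_len) {
    warning("sequence shorter than 2*min_ir_len; no IR detected")
    return(NULL)
  }
  ## scan the doubled sequence so IR copies crossing the origin are seen
  s2 <- if (genome$circular) paste0(genome$sequence, genome$sequence) else genome$sequence
  rc2 <- revcomp_chr(s2)
  mm <- exact_matches_min_len(s2, rc2, min_ir_len)
  if (nrow(mm) == 0L) {
    warning("no inverted repeat >= ", min_ir_len, " bp found")
    return(NULL)
  }
  n2 <- nchar(s2)
  ## map match in revcomp coordinates back to forward coordinates:
  ## rc2[j .. j+L-1] corresponds to forward s2[n2-j-L+2 .. n2-j+1]
  mm$c_start <- n2 - mm$b_start - mm$len + 2L
  ## canonical forward positions (mod n), IRa = copy with smaller start
  mm$a_mod <- ((mm$a_start - 1L) %% n) + 1L
  mm$c_mod <- ((mm$c_start - 1L) %% n) + 1L
  ## drop self matches (a segment is its own revcomp partner) and clip to
  ## candidates where copies are disjoint on the circle
  cand <- NULL
  for (i in order(-mm$len)) {
    L <- mm$len[i]
    if (L > n) L <- n   # degenerate: whole genome palindromic
    a <- mm$a_mod[i]; b <- mm$c_mod[i]
    if (a == b) next
    ## occupied positions (on the circle) of both copies must be disjoint
    occ_a <- ((a - 1L + seq_len(L) - 1L) %% n) + 1L
    occ_b <- ((b - 1L + seq_len(L) - 1L) %% n) + 1L
    if (length(intersect(occ_a, occ_b)) > 0L) next
    cand <- list(a = a, b = b, len = L)
    break
  }
  if (is.null(cand)) {
    warning("no disjoint inverted repeat pair >= ", min_ir_len, " bp found")
    return(NULL)
  }
  mk_iv <- function(st, L) {
    en <- ((st - 1L + L - 1L) %% n) + 1L
    interval(st, en, "+", wraps_origin = en < st)
  }
  iva <- mk_iv(cand$a, cand$len)
  ivb <- mk_iv(cand$b, cand$len)
  ## single-copy gaps between the two IR copies (circle order)
  gap_after <- function(iv1, iv2) {
    st <- (iv1$end %% n) + 1L
    en <- ((iv2$start - 2L) %% n) + 1L
    glen <- (en - st) %% n + 1L
    if (glen == n) return(NULL)         # no gap
    interval(st, en, "+", wraps_origin = en < st)
  }
  g1 <- gap_after(iva, ivb)   # between IRa-end and IRb-start
  g2 <- gap_after(ivb, iva)   # between IRb-end and IRa-start
  if (is.null(g1) || is.null(g2)) {
    warning("IR copies leave no single-copy region; not a quadripartite genome")
    return(NULL)
  }
  l1 <- interval_span(g1, n); l2 <- interval_span(g2, n)
  if (l1 >= l2) { lsc <- g1; ssc <- g2 } else { lsc <- g2; ssc <- g1 }
  ## relabel so the copy downstream of the LSC is IRa (convention)
  after_lsc <- (lsc$end %% n) + 1L
  if (ivb$start == after_lsc) { tmp <- iva; iva <- ivb; ivb <- tmp }
  structure(list(lsc = lsc, ira = iva, ssc = ssc, irb = ivb),
            class = "quadripartite_layout")
}

#' @export
print.quadripartite_layout <- function(x, ...) {
  for (nm in c("lsc", "ira", "ssc", "irb")) {
    iv <- x[[nm]]
    cat(sprintf("%4s %7d..%7d%s\n", toupper(nm), iv$start, iv$end,
                if (iv$wraps_origin) " (wraps origin)" else ""))
  }
  invisible(x)
}

## TRUE when position p lies within interval iv on a circle of length n.
pos_in_interval <- function(p, iv, n) {
  if (iv$wraps_origin) p >= iv$start | p <= iv$end else p >= iv$start & p <= iv$end
}

## Region label for a position given a layout: "LSC", "IRa", "SSC", "IRb".
layout_region <- function(layout, p, n) {
  for (nm in c("lsc", "ira", "ssc", "irb")) {
    if (pos_in_interval(p, layout[[nm]], n)) {
      return(c(lsc = "LSC", ira = "IRa", ssc = "SSC", irb = "IRb")[[nm]])
    }
  }
  NA_character_
}
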