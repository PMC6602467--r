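## Seeded local similarity search and HSP chaining.
##
## The search engine is self-contained: exact k-mer seeds locate candidate
## loci on both strands, and each candidate window is scored with an
## affine-gap local alignment (Biostrings::pairwiseAlignment).  E-values
## follow a Karlin-Altschul-style scaling of the raw score against query
## and target lengths with documented constants.

## scoring constants (BLASTN-like for nucleotide, BLOSUM62 for protein)
NUC_MATCH <- 2; NUC_MISMATCH <- -3; NUC_GAP_OPEN <- 5; NUC_GAP_EXT <- 2
NUC_LAMBDA <- 0.625; NUC_K <- 0.41
PRO_GAP_OPEN <- 11; PRO_GAP_EXT <- 1
PRO_LAMBDA <- 0.267; PRO_K <- 0.041

## all k-mer start positions of s, excluding k-mers containing N/X/*
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Build a reusable search index over a target genome
#'
#' Precomputes k-mer position tables (and, for translated searches, the
#' six-frame translation) so that repeated [similarity_search()] calls over
#' the same genome do not repeat the indexing work.
#'
#' @param target A `plastome`.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param k Seed length (default 11 nt / 4 aa).
#' @return A `search_index` object.
#' @export
build_search_index <- function(target, mode = c("nucleotide", "translated"),
                               k = NULL) {
  mode <- match.arg(mode)
  fwd <- target$sequence
  rev <- revcomp_chr(fwd)
  if (mode == "nucleotide") {
    k <- k %||% 11L
    tabs <- list(
      "+" = list(seq = fwd, tab = kmer_table(fwd, k, "[^ACGT]")),
      "-" = list(seq = rev, tab = kmer_table(rev, k, "[^ACGT]"))
    )
    frames <- NULL
  } else {
    k <- k %||% 4L
    code <- Biostrings::getGeneticCode("11")
    tr <- function(s, off) {
      sub <- substr(s, off + 1L, off + ((nchar(s) - off) %/% 3L) * 3L)
      if (nchar(sub) < 3L) return("")
      suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), genetic.code = code,
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
    }
    frames <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (f in 0:2) {
        aa <- tr(s, f)
        frames[[paste0(strand, f)]] <- list(
          strand = strand, frame = f, aa = aa,
          tab = kmer_table(aa, k, "[^A-WYZ]")  # drop X and * containing seeds
        )
      }
    }
    tabs <- NULL
  }
  structure(list(mode = mode, k = k, n = target$length,
                 fwd = fwd, rev = rev, tabs = tabs, frames = frames),
            class = "search_index")
}

kmer_table <- function(s, k, bad_re) {
  km <- seq_kmers(s, k)
  if (length(km) == 0L) return(list())
  ok <- !grepl(bad_re, km)
  split(which(ok), km[ok])
}

karlin_evalue <- function(score, qlen, tlen, lambda, K) {
  K * qlen * tlen * exp(-lambda * score)
}

empty_hsps <- function() {
  data.frame(query_gene = character(0), q_start = integer(0),
             q_end = integer(0), t_start = integer(0), t_end = integer(0),
             strand = character(0), frame = integer(0), score = numeric(0),
             identity = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

## seed hits of query against one indexed sequence; returns q_pos/t_pos
seed_hits <- function(query, tab, k) {
  qk <- seq_kmers(query, k)
  hits_q <- integer(0); hits_t <- integer(0)
  for (i in seq_along(qk)) {
    tp <- tab[[qk[i]]]
    if (!is.null(tp)) {
      hits_q <- c(hits_q, rep.int(i, length(tp)))
      hits_t <- c(hits_t, tp)
    }
  }
  list(q = hits_q, t = hits_t)
}

## cluster seeds into candidate windows (band on diagonal, gap on target)
cluster_seeds <- function(q, t, band, tgap) {
  d <- t - q
  ord <- order(d, t)
  q <- q[ord]; t <- t[ord]; d <- d[ord]
  brk <- c(TRUE, diff(d) > band | diff(t) > tgap)
  grp <- cumsum(brk)
  lapply(split(seq_along(q), grp), function(i) {
    list(q0 = min(q[i]), q1 = max(q[i]), t0 = min(t[i]), t1 = max(t[i]))
  })
}

align_window <- function(query, subject_seq, win0, win1, submat,
                         gap_open, gap_ext) {
  win <- substr(subject_seq, win0, win1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = win, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_ext)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pa, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1L]]
  nmatch <- sum(pc == sc & pc != "-")
  list(score = Biostrings::score(aln),
       q_start = Biostrings::start(Biostrings::pattern(aln)),
       q_end = Biostrings::end(Biostrings::pattern(aln)),
       s_start = win0 + Biostrings::start(Biostrings::subject(aln)) - 1L,
       s_end = win0 + Biostrings::end(Biostrings::subject(aln)) - 1L,
       identity = nmatch / length(pc))
}

#' Local similarity search of a query against a plastome
#'
#' Both strands are searched.  Minus-strand HSPs report target coordinates
#' on the forward strand with `strand == "-"` (the query matches the
#' reverse complement of the reported segment).
#'
#' @param query Query sequence: DNA for `mode = "nucleotide"`, protein for
#'   `mode = "translated"`.
#' @param target A `plastome`, or a prebuilt `search_index`.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param min_evalue Maximum E-value to report (default 1e-6).
#' @param query_gene Label recorded on the HSPs.
#' @return A data.frame of HSPs sorted by descending score with columns
#'   `query_gene`, `q_start`, `q_end` (query units: nt or aa), `t_start`,
#'   `t_end` (nt, forward strand), `strand`, `frame`, `score`, `identity`,
#'   `evalue`.
#' @export
similarity_search <- function(query, target,
                              mode = c("nucleotide", "translated"),
                              min_evalue = 1e-6, query_gene = "query") {
  mode <- match.arg(mode)
  idx <- if (inherits(target, "search_index")) target
         else build_search_index(target, mode)
  if (idx$mode != mode) stop("search index mode mismatch")
  query <- toupper(query)
  if (mode == "nucleotide") {
    if (grepl("[^ACGTN]", query)) stop("invalid nucleotide query alphabet")
    if (nchar(query) < 8L) stop("nucleotide query shorter than 8 bp")
    similarity_search_nuc(query, idx, min_evalue, query_gene)
  } else {
    if (grepl("[^A-Z*]", query)) stop("invalid protein query alphabet")
    if (nchar(query) < 5L) stop("protein query shorter than 5 aa")
    similarity_search_pro(query, idx, min_evalue, query_gene)
  }
}

similarity_search_nuc <- function(query, idx, min_evalue, query_gene) {
  n <- idx$n
  qlen <- nchar(query)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = NUC_MATCH, mismatch = NUC_MISMATCH, baseOnly = FALSE)
  rows <- list()
  for (strand in c("+", "-")) {
    ent <- idx$tabs[[strand]]
    hits <- seed_hits(query, ent$tab, idx$k)
    if (length(hits$q) == 0L) next
    clus <- cluster_seeds(hits$q, hits$t, band = 32L, tgap = qlen + 200L)
    for (cl in clus) {
      win0 <- max(1L, cl$t0 - cl$q0 - 20L)
      win1 <- min(nchar(ent$seq), cl$t1 + (qlen - cl$q1) + idx$k + 20L)
      a <- align_window(query, ent$seq, win0, win1, submat,
                        NUC_GAP_OPEN, NUC_GAP_EXT)
      ev <- karlin_evalue(a$score, qlen, n, NUC_LAMBDA, NUC_K)
      if (ev > min_evalue) next
      if (strand == "+") {
        ts <- a$s_start; te <- a$s_end
      } else {
        ts <- n - a$s_end + 1L; te <- n - a$s_start + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_gene = query_gene, q_start = a$q_start, q_end = a$q_end,
        t_start = ts, t_end = te, strand = strand, frame = 0L,
        score = a$score, identity = a$identity, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  finish_hsps(rows)
}

similarity_search_pro <- function(query, idx, min_evalue, query_gene) {
  n <- idx$n
  qlen <- nchar(query)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (fr in idx$frames) {
    if (!nzchar(fr$aa)) next
    hits <- seed_hits(query, fr$tab, idx$k)
    if (length(hits$q) == 0L) next
    clus <- cluster_seeds(hits$q, hits$t, band = 16L, tgap = qlen + 100L)
    for (cl in clus) {
      win0 <- max(1L, cl$t0 - cl$q0 - 10L)
      win1 <- min(nchar(fr$aa), cl$t1 + (qlen - cl$q1) + idx$k + 10L)
      a <- align_window(query, fr$aa, win0, win1, submat,
                        PRO_GAP_OPEN, PRO_GAP_EXT)
      ev <- karlin_evalue(a$score, qlen, n / 3, PRO_LAMBDA, PRO_K)
      if (ev > min_evalue) next
      ## map aa positions on this strand/frame back to forward-strand nt
      nt_lo <- 3L * (a$s_start - 1L) + fr$frame + 1L
      nt_hi <- 3L * (a$s_end - 1L) + fr$frame + 3L
      if (fr$strand == "+") {
        ts <- nt_lo; te <- nt_hi
      } else {
        ts <- n - nt_hi + 1L; te <- n - nt_lo + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_gene = query_gene, q_start = a$q_start, q_end = a$q_end,
        t_start = ts, t_end = te, strand = fr$strand, frame = fr$frame,
        score = a$score, identity = a$identity, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  finish_hsps(rows)
}

finish_hsps <- function(rows) {
  if (length(rows) == 0L) return(empty_hsps())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("t_start", "t_end", "strand", "q_start")]), ,
             drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- chaining -------------------------------------------------------------

#' Chain HSPs into candidate exon structures
#'
#' Selects maximum-total-score chains of HSPs that are colinear in query
#' and target, on one strand, with target gaps at most `max_intron`.
#' Chains are extracted iteratively: the best chain is reported, its HSPs
#' (and HSPs overlapping them by >= 50% on the target) are removed, and
#' the process repeats, so IR-duplicated loci yield one chain per copy.
#'
#' @param hsps A data.frame of HSPs for one query gene.
#' @param max_intron Maximum intron (target gap) length in bp (default
#'   2000).
#' @return A list of chains; each chain is a list with `hsps` (data.frame
#'   in chain order), `score` and `strand`.
#' @export
chain_hsps <- function(hsps, max_intron = 2000L) {
  if (is.null(hsps) || nrow(hsps) == 0L) return(list())
  chains <- list()
  pool <- hsps
  while (nrow(pool) > 0L) {
    best <- best_chain(pool, max_intron)
    if (is.null(best)) break
    chains[[length(chains) + 1L]] <- best
    ## remove used HSPs and target-redundant ones
    used <- best$hsps
    keep <- rep(TRUE, nrow(pool))
    for (i in seq_len(nrow(pool))) {
      for (j in seq_len(nrow(used))) {
        ov <- min(pool$t_end[i], used$t_end[j]) -
          max(pool$t_start[i], used$t_start[j]) + 1L
        len_i <- pool$t_end[i] - pool$t_start[i] + 1L
        if (ov > 0L && ov >= 0.5 * len_i) { keep[i] <- FALSE; break }
      }
    }
    if (all(keep)) break  # safety: no progress
    pool <- pool[keep, , drop = FALSE]
  }
  chains
}

## single maximum-score chain by dynamic programming
best_chain <- function(hsps, max_intron) {
  n <- nrow(hsps)
  if (n == 0L) return(NULL)
  hsps <- hsps[order(hsps$t_start, hsps$t_end), , drop = FALSE]
  score <- hsps$score
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      if (!chain_compatible(hsps[i, ], hsps[j, ], max_intron)) next
      cand <- score[i] + hsps$score[j]
      if (cand > score[j]) { score[j] <- cand; prev[j] <- i }
    }
  }
  end <- which.max(score)
  path <- integer(0); cur <- end
  while (!is.na(cur)) { path <- c(cur, path); cur <- prev[cur] }
  list(hsps = hsps[path, , drop = FALSE], score = score[end],
       strand = hsps$strand[path[1L]])
}

## i precedes j on the target (t_start_i <= t_start_j assumed by sort)
chain_compatible <- function(i, j, max_intron) {
  if (i$strand != j$strand) return(FALSE)
  t_gap <- j$t_start - i$t_end - 1L
  if (t_gap < -10L) return(FALSE)            # target overlap beyond slack
  if (t_gap > max_intron) return(FALSE)
  li <- i$q_end - i$q_start + 1L
  lj <- j$q_end - j$q_start + 1L
  if (i$strand == "+") {
    q_gap <- j$q_start - i$q_end - 1L
  } else {
    ## minus strand: ascending target position = descending query position
    q_gap <- i$q_start - j$q_end - 1L
  }
  if (q_gap < 0L) {
    ov <- -q_gap
    if (ov > 0.5 * min(li, lj)) return(FALSE)  # >50% query overlap
  }
  TRUE
}
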