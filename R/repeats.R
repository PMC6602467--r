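## Integrated repeat discovery: SSRs (unit 1-6 bp), longer tandem repeats
## (unit > 6 bp) and dispersed forward/palindromic repeat pairs.
##
## Definitions (shared by the finders and the brute-force test oracles):
## an SSR is a maximal perfect tandem run of a primitive unit, trimmed to
## whole copies; a tandem repeat is a maximal array of >= min_copies
## approximate copies of a unit > 6 bp whose per-copy identity to the
## column-majority consensus reaches min_identity and whose match score
## (+2 per matching base, -7 per mismatch, TRF-style weights) reaches
## min_score; a dispersed repeat is a maximal-scoring diagonal segment
## pair (+1 match, -3 mismatch) with at most max_mismatch substitutions
## and length >= min_len, in forward or palindromic orientation.

TANDEM_MATCH_W <- 2; TANDEM_MISMATCH_W <- 7; TANDEM_MIN_SCORE <- 50
DISP_MISMATCH_PENALTY <- 3

## lexicographically minimal rotation of a motif
canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L)), character(1L))
  min(rots)
}

## smallest period of a string (== nchar when primitive)
smallest_period <- function(s) {
  k <- nchar(s)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L &&
        s == strrep(substr(s, 1L, p), k %/% p)) return(p)
  }
  k
}

## TRUE when s is dominated (>= 90% of positions) by a string
## periodicity p <= pmax, i.e. it is essentially a fragment of a
## short-unit tandem run and belongs to the SSR finder
has_period_leq <- function(s, pmax, min_frac = 0.9) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  k <- length(x)
  for (p in seq_len(min(pmax, k - 1L))) {
    if (mean(x[seq_len(k - p)] == x[seq_len(k - p) + p]) >= min_frac) {
      return(TRUE)
    }
  }
  FALSE
}

#' Find simple sequence repeats (SSRs)
#'
#' Reports every maximal perfect tandem run of a primitive unit of size
#' 1-6 bp that reaches its unit-size copy threshold, trimmed to whole
#' copies.  Motifs are canonicalized to their lexicographically minimal
#' rotation.  Runs whose gaps are at most `compound_gap` share a
#' `compound_id`.
#'
#' @param genome A `plastome` (or plain character sequence).
#' @param min_copies Named integer vector mapping unit length (`"1"` ..
#'   `"6"`) to the minimum copy number; defaults 10,6,5,5,5,5.
#' @param compound_gap Maximum gap for compounding (default 100).
#' @return data.frame: `motif`, `unit_len`, `copies`, `start`, `end`,
#'   `compound_id` (NA when not compounded), sorted by start.
#' @export
find_ssrs <- function(genome, min_copies = SSR_DEFAULT_MIN_COPIES,
                      compound_gap = 100L) {
  s <- if (inherits(genome, "plastome")) genome$sequence else genome
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(x)
  rows <- list()
  for (u in 1:6) {
    thr <- min_copies[[as.character(u)]]
    if (is.null(thr) || n < thr * u) next
    eq <- x[seq_len(n - u)] == x[seq_len(n - u) + u] & x[seq_len(n - u)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      ## periodic region [starts[i], ends[i]+u] with period u
      span <- r$lengths[i] + u
      copies <- span %/% u
      if (copies < thr) next
      a <- starts[i]
      motif <- substr(s, a, a + u - 1L)
      if (smallest_period(motif) != u) next   # counted at its primitive unit
      rows[[length(rows) + 1L]] <- data.frame(
        motif = canonical_rotation(motif), unit_len = u,
        copies = copies, start = a, end = a + copies * u - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), compound_id = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  ## compound id for runs within compound_gap of each other
  cid <- rep(NA_integer_, nrow(out))
  grp <- cumsum(c(TRUE, out$start[-1L] - out$end[-nrow(out)] - 1L > compound_gap))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) cid[idx] <- g
  }
  out$compound_id <- cid
  rownames(out) <- NULL
  out
}

#' Find longer tandem repeats (unit > 6 bp)
#'
#' Candidate unit lengths are screened by self-match autocorrelation
#' (positions where the sequence equals itself shifted by the unit
#' length); dense regions are folded into rows of the unit width, the
#' consensus is taken by column majority, and the array is accepted when
#' per-copy identity and the TRF-style score reach their thresholds.
#' Arrays explained by a smaller unit (SSRs or a divisor period) are
#' suppressed.
#'
#' @param genome A `plastome` or character sequence.
#' @param min_unit,max_unit Unit length bounds (defaults 7, 500).
#' @param min_identity Minimum per-copy identity to the consensus
#'   (default 0.9).
#' @param min_copies Minimum (fractional) copy number (default 2).
#' @param min_score Minimum match score, +2 per match / -7 per mismatch
#'   (default 50, so a perfect array needs >= 25 matched bases).
#' @return data.frame: `unit_len`, `copies`, `consensus`, `start`, `end`,
#'   `percent_identity`.
#' @export
find_tandem_repeats <- function(genome, min_unit = 7L, max_unit = 500L,
                                min_identity = 0.9, min_copies = 2.0,
                                min_score = TANDEM_MIN_SCORE) {
  stopifnot(min_unit > 6L)
  s <- if (inherits(genome, "plastome")) genome$sequence else genome
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(x)
  cands <- list()
  max_unit <- min(max_unit, n %/% 2L)
  for (u in min_unit:max_unit) {
    if (n < 2L * u) break
    eq <- x[seq_len(n - u)] == x[seq_len(n - u) + u] & x[seq_len(n - u)] != "N"
    ## candidate regions: windows of width u with >= min_identity matches
    cs <- cumsum(c(0L, eq))
    win <- cs[(u + 1L):(n - u + 1L)] - cs[seq_len(n - 2L * u + 1L)]
    ## two copies each >= min_identity to the consensus can disagree with
    ## each other at up to twice the divergence
    dense <- win >= max(1L, floor((2 * min_identity - 1) * u))
    if (!any(dense)) next
    r <- rle(dense)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    dsta <- starts[r$values]; dend <- ends[r$values]
    ## merge dense runs separated by less than one unit: windows
    ## straddling two copy pairs can dip just under the threshold
    if (length(dsta) > 1L) {
      grp <- cumsum(c(TRUE, dsta[-1L] - dend[-length(dend)] - 1L > u))
      dsta <- tapply(dsta, grp, min); dend <- tapply(dend, grp, max)
    }
    for (i in seq_along(dsta)) {
      a <- dsta[[i]]                  # array start candidate
      b <- min(dend[[i]] + 2L * u - 1L, n)
      ## choose the copy register (phase) scoring best over this region
      best <- NULL
      for (off in 0L:(u - 1L)) {
        cand <- evaluate_tandem(x, a + off, b, u, min_identity, min_copies,
                                min_score)
        if (!is.null(cand) &&
            (is.null(best) || cand$score > best$score)) best <- cand
      }
      if (is.null(best)) next
      if (has_period_leq(best$consensus, 6L)) next  # SSR territory
      cands[[length(cands) + 1L]] <- best
    }
  }
  if (length(cands) == 0L) {
    return(data.frame(unit_len = integer(0), copies = numeric(0),
                      consensus = character(0), start = integer(0),
                      end = integer(0), percent_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ## greedy selection: smallest explaining unit first, then score; a
  ## candidate overlapping an accepted array by >= 50% is redundant
  ord <- order(vapply(cands, `[[`, integer(1L), "unit_len"),
               -vapply(cands, `[[`, numeric(1L), "score"))
  accepted <- list()
  for (cand in cands[ord]) {
    dup <- FALSE
    for (acc in accepted) {
      ov <- min(acc$end, cand$end) - max(acc$start, cand$start) + 1L
      if (ov >= 0.5 * (cand$end - cand$start + 1L)) { dup <- TRUE; break }
    }
    if (!dup) accepted[[length(accepted) + 1L]] <- cand
  }
  out <- do.call(rbind, lapply(accepted, function(z)
    as.data.frame(z[c("unit_len", "copies", "consensus", "start", "end",
                      "percent_identity")])))
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## score an array candidate: trim to whole+fractional copies, consensus by
## column majority, per-copy identity, TRF-style score
evaluate_tandem <- function(x, a, b, u, min_identity, min_copies, min_score) {
  len <- b - a + 1L
  if (len < 2L * u) return(NULL)
  n_full <- len %/% u
  cols <- matrix(NA_character_, nrow = n_full, ncol = u)
  for (r in seq_len(n_full)) {
    cols[r, ] <- x[(a + (r - 1L) * u):(a + r * u - 1L)]
  }
  consensus <- apply(cols, 2L, function(cc) names(sort(table(cc), decreasing = TRUE))[1L])
  per_copy <- vapply(seq_len(n_full), function(r) mean(cols[r, ] == consensus),
                     numeric(1L))
  ## trim trailing/leading copies below identity (small tolerance so an
  ## exact-ratio copy like 27/30 sits on the 0.9 floor, not under it)
  keep <- per_copy >= min_identity - 1e-9
  if (!any(keep)) return(NULL)
  first <- which(keep)[1L]; last <- rev(which(keep))[1L]
  if (any(!keep[first:last])) return(NULL)   # interior degenerate copy
  a2 <- a + (first - 1L) * u
  b2 <- a + last * u - 1L
  ## fractional extension of the final copy
  extra <- 0L
  while (b2 + 1L <= length(x) && extra < u - 1L &&
         x[b2 + 1L] == consensus[extra + 1L]) {
    b2 <- b2 + 1L; extra <- extra + 1L
  }
  copies <- (b2 - a2 + 1L) / u
  if (copies < min_copies) return(NULL)
  rows <- first:last
  matches <- sum(vapply(rows, function(r) sum(cols[r, ] == consensus), numeric(1L))) + extra
  mism <- (last - first + 1L) * u - (matches - extra)
  score <- TANDEM_MATCH_W * matches - TANDEM_MISMATCH_W * mism
  if (score < min_score) return(NULL)
  ident <- matches / (b2 - a2 + 1L)
  if (ident < min_identity - 1e-9) return(NULL)
  list(unit_len = u, copies = round(copies, 2),
       consensus = paste(consensus, collapse = ""),
       start = a2, end = b2, percent_identity = round(ident, 4),
       score = score)
}

#' Find dispersed repeat pairs
#'
#' All maximal-scoring pairs of equal-length segments at least `min_len`
#' long matching in forward or palindromic (reverse-complement)
#' orientation with at most `max_mismatch` substitutions.  Candidate
#' diagonals are located by shared 7-mers (a segment of length >= 28 with
#' <= 3 mismatches always contains an exact 7-mer), then each diagonal is
#' scanned for maximal-scoring segments.  Pairs whose two intervals
#' overlap each other, and (when `exclude_ir`) pairs with both intervals
#' inside the inverted repeats, are suppressed.
#'
#' @param genome A `plastome` or character sequence.
#' @param min_len Minimum pair length (default 30).
#' @param max_mismatch Maximum substitutions (default 3).
#' @param exclude_ir Drop pairs lying within the IR copies (default TRUE;
#'   the IRa/IRb pair itself is the layout, not a dispersed repeat).
#' @param layout Optional `quadripartite_layout` for `exclude_ir`.
#' @return data.frame: `a_start`, `a_end`, `b_start`, `b_end`,
#'   `orientation` (`forward`/`palindromic`), `length`, `mismatches`.
#' @export
find_dispersed_repeats <- function(genome, min_len = 30L, max_mismatch = 3L,
                                   exclude_ir = TRUE, layout = NULL) {
  stopifnot(min_len >= 12L)
  s <- if (inherits(genome, "plastome")) genome$sequence else genome
  n <- nchar(s)
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  rc <- strsplit(revcomp_chr(s), "", fixed = TRUE)[[1L]]
  k <- 7L    # a segment >= 28 bp with <= 3 mismatches always has an exact 7-mer
  rows <- list()

  seg_rows <- function(seed_pairs, xa, xb, orient) {
    ## seed_pairs: data.frame(i, j): exact k-mer at xa[i..] and xb[j..];
    ## scan only windows around seeds on each diagonal
    if (nrow(seed_pairs) == 0L) return(invisible())
    d_all <- seed_pairs$j - seed_pairs$i
    ord <- order(d_all, seed_pairs$i, method = "radix")
    ds <- d_all[ord]; is <- seed_pairs$i[ord]
    ## pigeonhole: when min_len - max_mismatch > k + max_mismatch*(k-1),
    ## a reportable segment always contains at least two exact k-mers on
    ## its diagonal within min_len of each other, so isolated chance
    ## seeds are dropped wholesale (vectorized over all diagonals)
    if ((min_len - max_mismatch) > (k + max_mismatch * (k - 1L)) &&
        length(is) > 1L) {
      near <- diff(ds) == 0L & diff(is) <= min_len
      keep <- c(near, FALSE) | c(FALSE, near)
      ds <- ds[keep]; is <- is[keep]
      if (length(is) == 0L) return(invisible())
    }
    by_diag <- split(is, ds)   # per-diagonal, ascending
    for (dk in names(by_diag)) {
      d <- as.integer(dk)
      iv <- by_diag[[dk]]
      lo_all <- max(1L, 1L - d); hi_all <- min(length(xa), length(xb) - d)
      ## merge seed windows
      w0 <- pmax(lo_all, iv - min_len - 20L)
      w1 <- pmin(hi_all, iv + k - 1L + min_len + 20L)
      merged <- list(); cur <- c(w0[1L], w1[1L])
      for (t in seq_along(iv)[-1L]) {
        if (w0[t] <= cur[2L] + 1L) cur[2L] <- max(cur[2L], w1[t])
        else { merged[[length(merged) + 1L]] <- cur; cur <- c(w0[t], w1[t]) }
      }
      merged[[length(merged) + 1L]] <- cur
      for (win in merged) {
        repeat {
          idx <- win[1L]:win[2L]
          m <- xa[idx] == xb[idx + d] & xa[idx] != "N"
          ## cheap screen: a reportable segment needs >= min_len -
          ## max_mismatch matches inside some min_len window; windows
          ## seeded by a single chance k-mer fail this immediately
          if (length(m) >= min_len) {
            cs <- cumsum(c(0L, m))
            wmax <- max(cs[(min_len + 1L):length(cs)] -
                          cs[seq_len(length(cs) - min_len)])
            if (wmax < min_len - max_mismatch) { segs <- list(); break }
          } else { segs <- list(); break }
          segs <- max_scoring_segments(m, DISP_MISMATCH_PENALTY)
          ## expand the window when a segment touches its edge
          touch <- any(vapply(segs, function(sg)
            (sg[1L] == 1L && win[1L] > lo_all) ||
            (sg[2L] == length(m) && win[2L] < hi_all), logical(1L)))
          if (!touch) break
          win <- c(max(lo_all, win[1L] - 200L), min(hi_all, win[2L] + 200L))
        }
        for (seg in segs) {
          len <- seg[2L] - seg[1L] + 1L
          if (len < min_len) next
          mm <- sum(!m[seg[1L]:seg[2L]])
          if (mm > max_mismatch) next
          a0 <- win[1L] + seg[1L] - 1L
          a1 <- win[1L] + seg[2L] - 1L
          b0 <- a0 + d; b1 <- a1 + d
          if (orient == "forward") {
            pa <- c(a0, a1); pb <- c(b0, b1)
          } else {
            ## xb is the reverse complement: rc position j = genome n - j + 1
            pb <- c(n - b1 + 1L, n - b0 + 1L)
            pa <- c(a0, a1)
          }
          if (pa[1L] > pb[1L]) { tmp <- pa; pa <- pb; pb <- tmp }
          if (pa[2L] >= pb[1L]) next      # overlapping intervals: tandem-like
          rows[[length(rows) + 1L]] <<- data.frame(
            a_start = pa[1L], a_end = pa[2L], b_start = pb[1L], b_end = pb[2L],
            orientation = orient, length = len, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  seg_rows(shared_kmer_pairs(x, x, k, self = TRUE), x, x, "forward")
  seg_rows(shared_kmer_pairs(x, rc, k, self = FALSE), x, rc, "palindromic")

  if (length(rows) == 0L) {
    out <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), length = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- unique(do.call(rbind, rows))
  out <- drop_contained_pairs(out)
  if (exclude_ir && !is.null(layout)) {
    in_ir <- function(st, en) {
      (pos_in_interval(st, layout$ira, n) & pos_in_interval(en, layout$ira, n)) |
        (pos_in_interval(st, layout$irb, n) & pos_in_interval(en, layout$irb, n))
    }
    drop <- in_ir(out$a_start, out$a_end) & in_ir(out$b_start, out$b_end)
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## maximality dedup: a pair whose two intervals are both contained in
## another pair of the same orientation is not maximal and is dropped
drop_contained_pairs <- function(out) {
  if (nrow(out) <= 1L) return(out)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i]) next
      if (out$orientation[i] != out$orientation[j]) next
      if (out$length[j] < out$length[i]) next
      if (out$length[j] == out$length[i] && j > i) next
      if (out$a_start[i] >= out$a_start[j] && out$a_end[i] <= out$a_end[j] &&
          out$b_start[i] >= out$b_start[j] && out$b_end[i] <= out$b_end[j]) {
        keep[i] <- FALSE
      }
    }
  }
  out[keep, , drop = FALSE]
}

## exact shared k-mer positions between two sequences; for self
## comparison only ordered pairs (j > i) are kept
shared_kmer_pairs <- function(xa, xb, k, self = FALSE) {
  sa <- paste(xa, collapse = ""); sb <- paste(xb, collapse = "")
  ka <- seq_kmers(sa, k); kb <- seq_kmers(sb, k)
  ia <- which(!grepl("N", ka, fixed = TRUE))
  ib <- which(!grepl("N", kb, fixed = TRUE))
  tab <- split(ib, kb[ib])
  map <- split(ia, ka[ia])
  li <- vector("list", length(map)); lj <- li
  kk <- 0L
  for (kmer in names(map)) {
    tp <- tab[[kmer]]
    if (is.null(tp)) next
    av <- map[[kmer]]
    kk <- kk + 1L
    li[[kk]] <- rep(av, each = length(tp))
    lj[[kk]] <- rep(tp, times = length(av))
  }
  out_i <- unlist(li[seq_len(kk)], use.names = FALSE)
  out_j <- unlist(lj[seq_len(kk)], use.names = FALSE)
  if (is.null(out_i)) { out_i <- integer(0); out_j <- integer(0) }
  keep <- if (self) out_j > out_i else rep(TRUE, length(out_i))
  data.frame(i = out_i[keep], j = out_j[keep])
}

## Ruzzo-Tompa-style maximal scoring segments of a logical match vector
## (match = +1, mismatch = -penalty); returns list of c(start, end) with
## matching ends
max_scoring_segments <- function(m, penalty) {
  score <- ifelse(m, 1, -penalty)
  segs <- list()
  n <- length(score)
  i <- 1L
  while (i <= n) {
    if (!m[i]) { i <- i + 1L; next }
    ## greedy x-drop style extension from the start of a match run
    best_j <- i; cur <- 0; best <- 0
    j <- i
    while (j <= n) {
      cur <- cur + score[j]
      if (cur > best) { best <- cur; best_j <- j }
      if (cur < best - penalty * 2) break    # x-drop
      j <- j + 1L
    }
    segs[[length(segs) + 1L]] <- c(i, best_j)
    i <- best_j + 1L
  }
  segs
}

#' Write repeat tables as TSV files
#'
#' @param ssr,tandem,dispersed Repeat data.frames from the three finders.
#' @param dir Output directory.
#' @return Named list of the three file paths.
#' @export
write_repeat_tsvs <- function(ssr, tandem, dispersed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "ssr.tsv")
  p2 <- file.path(dir, "tandem.tsv")
  p3 <- file.path(dir, "dispersed.tsv")
  utils::write.table(ssr, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tandem, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dispersed, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  list(ssr = p1, tandem = p2, dispersed = p3)
}
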