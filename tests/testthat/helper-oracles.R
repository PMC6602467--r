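## Independent brute-force oracles used to check the package's finders.
## These deliberately re-derive results by direct enumeration.

## --- Smith-Waterman local alignment (plain DP, no seeding) ---------------
sw_oracle <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = 5, gap_ext = 2) {
  q <- strsplit(query, "")[[1L]]; s <- strsplit(subject, "")[[1L]]
  nq <- length(q); ns <- length(s)
  H <- matrix(0, nq + 1L, ns + 1L)
  E <- matrix(-Inf, nq + 1L, ns + 1L)  # gap in query
  F <- matrix(-Inf, nq + 1L, ns + 1L)  # gap in subject
  best <- 0
  for (i in 2L:(nq + 1L)) {
    for (j in 2L:(ns + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_ext, E[i, j - 1L] - gap_ext)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_ext, F[i - 1L, j] - gap_ext)
      d <- H[i - 1L, j - 1L] + if (q[i - 1L] == s[j - 1L]) match else mismatch
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## --- chain oracle: enumerate every subset of <= n HSPs -------------------
chain_oracle <- function(hsps, max_intron) {
  n <- nrow(hsps)
  best <- 0
  ok_pair <- function(i, j) {   # i before j in target order
    if (hsps$strand[i] != hsps$strand[j]) return(FALSE)
    t_gap <- hsps$t_start[j] - hsps$t_end[i] - 1L
    if (t_gap < -10L || t_gap > max_intron) return(FALSE)
    li <- hsps$q_end[i] - hsps$q_start[i] + 1L
    lj <- hsps$q_end[j] - hsps$q_start[j] + 1L
    qg <- if (hsps$strand[i] == "+") hsps$q_start[j] - hsps$q_end[i] - 1L
          else hsps$q_start[i] - hsps$q_end[j] - 1L
    if (qg < 0L && -qg > 0.5 * min(li, lj)) return(FALSE)
    TRUE
  }
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) == 0L) next
    sel <- sel[order(hsps$t_start[sel])]
    valid <- TRUE
    if (length(sel) > 1L) {
      for (k in seq_len(length(sel) - 1L)) {
        if (!ok_pair(sel[k], sel[k + 1L])) { valid <- FALSE; break }
      }
    }
    if (valid) best <- max(best, sum(hsps$score[sel]))
  }
  best
}

## --- SSR oracle: direct enumeration of all (start, unit) runs ------------
ssr_oracle <- function(s, min_copies = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                         `4` = 5L, `5` = 5L, `6` = 5L)) {
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  prim <- function(m) {
    k <- nchar(m)
    for (p in seq_len(k - 1L)) {
      if (k %% p == 0L && m == strrep(substr(m, 1L, p), k %/% p)) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (u in 1:6) {
    thr <- min_copies[[as.character(u)]]
    a <- 1L
    while (a + u - 1L <= n) {
      motif <- paste(x[a:(a + u - 1L)], collapse = "")
      ## extendable left by one period? then not maximal here
      if (a > u && all(x[(a - u):(a - 1L)] == x[a:(a + u - 1L)])) { a <- a + 1L; next }
      if (!prim(motif)) { a <- a + 1L; next }
      cp <- 1L
      while (a + (cp + 1L) * u - 1L <= n &&
             all(x[(a + cp * u):(a + (cp + 1L) * u - 1L)] == x[a:(a + u - 1L)])) {
        cp <- cp + 1L
      }
      ## partial trailing period extends the maximal periodic region but
      ## not the copy count; also absorb it for maximality on the left edge
      if (cp >= thr) {
        cano <- min(vapply(seq_len(u), function(i)
          paste0(substr(motif, i, u), substr(motif, 1L, i - 1L)), character(1L)))
        rows[[length(rows) + 1L]] <- data.frame(
          motif = cano, unit_len = u, copies = cp,
          start = a, end = a + cp * u - 1L, stringsAsFactors = FALSE)
        a <- a + cp * u
      } else a <- a + 1L
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$start, out$unit_len), , drop = FALSE]
}

## --- dispersed oracle: every diagonal of both orientations ---------------
dispersed_oracle <- function(s, min_len = 30L, max_mismatch = 3L) {
  x <- strsplit(s, "")[[1L]]
  rc <- strsplit(revcomp_chr(s), "")[[1L]]
  n <- length(x)
  rows <- list()
  scan_diag <- function(m, map_pair) {
    ## maximal scoring segments (+1 / -3, x-drop 6), ends on matches
    i <- 1L
    while (i <= length(m)) {
      if (!m[i]) { i <- i + 1L; next }
      cur <- 0; best <- 0; best_j <- i; j <- i
      while (j <= length(m)) {
        cur <- cur + if (m[j]) 1 else -3
        if (cur > best) { best <- cur; best_j <- j }
        if (cur < best - 6) break
        j <- j + 1L
      }
      mm <- sum(!m[i:best_j])
      if (best_j - i + 1L >= min_len && mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <<- map_pair(i, best_j, mm)
      }
      i <- best_j + 1L
    }
  }
  for (d in 1L:(n - min_len)) {             # forward, j = i + d
    idx <- seq_len(n - d)
    m <- x[idx] == x[idx + d]
    scan_diag(m, function(a, b, mm) {
      data.frame(a_start = a, a_end = b, b_start = a + d, b_end = b + d,
                 orientation = "forward", length = b - a + 1L,
                 mismatches = mm, stringsAsFactors = FALSE)
    })
  }
  for (d in (1L - n):(n - 1L)) {            # palindromic vs revcomp
    lo <- max(1L, 1L - d); hi <- min(n, n - d)
    if (hi - lo + 1L < min_len) next
    idx <- lo:hi
    m <- x[idx] == rc[idx + d]
    scan_diag(m, function(a, b, mm) {
      a0 <- lo + a - 1L; a1 <- lo + b - 1L
      pb <- c(n - (a1 + d) + 1L, n - (a0 + d) + 1L)
      pa <- c(a0, a1)
      if (pa[1L] > pb[1L]) { t <- pa; pa <- pb; pb <- t }
      data.frame(a_start = pa[1L], a_end = pa[2L],
                 b_start = pb[1L], b_end = pb[2L],
                 orientation = "palindromic", length = b - a + 1L,
                 mismatches = mm, stringsAsFactors = FALSE)
    })
  }
  out <- unique(do.call(rbind, rows))
  out <- out[out$a_end < out$b_start, , drop = FALSE]
  ## maximality: drop pairs contained in a longer pair (independent
  ## restatement of the finders documented dedup rule)
  if (nrow(out) > 1L) {
    contained <- vapply(seq_len(nrow(out)), function(i) {
      any(vapply(seq_len(nrow(out)), function(j) {
        if (i == j || out$orientation[i] != out$orientation[j]) return(FALSE)
        if (out$length[j] < out$length[i]) return(FALSE)
        if (out$length[j] == out$length[i] && j > i) return(FALSE)
        out$a_start[i] >= out$a_start[j] && out$a_end[i] <= out$a_end[j] &&
          out$b_start[i] >= out$b_start[j] && out$b_end[i] <= out$b_end[j]
      }, logical(1L)))
    }, logical(1L))
    out <- out[!contained, , drop = FALSE]
  }
  out[order(out$a_start, out$b_start), , drop = FALSE]
}

## --- tandem oracle: every (start, unit) array ----------------------------
tandem_oracle <- function(s, min_unit = 7L, max_unit = 30L,
                          min_identity = 0.9, min_copies = 2.0,
                          min_score = 50) {
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  cands <- list()
  for (u in min_unit:max_unit) {
    for (a in seq_len(n - 2L * u + 1L)) {
      ## grow the array copy by copy while per-copy identity holds
      n_full <- 2L
      repeat {
        if (a + (n_full + 1L) * u - 1L > n) break
        mat <- matrix(x[a:(a + (n_full + 1L) * u - 1L)], ncol = u, byrow = TRUE)
        cons <- apply(mat, 2L, function(cc)
          names(sort(table(cc), decreasing = TRUE))[1L])
        pc <- rowMeans(mat == matrix(cons, nrow(mat), u, byrow = TRUE))
        if (any(pc < min_identity - 1e-9)) break
        n_full <- n_full + 1L
      }
      mat <- matrix(x[a:(a + n_full * u - 1L)], ncol = u, byrow = TRUE)
      cons <- apply(mat, 2L, function(cc)
        names(sort(table(cc), decreasing = TRUE))[1L])
      pc <- rowMeans(mat == matrix(cons, nrow(mat), u, byrow = TRUE))
      if (any(pc < min_identity - 1e-9)) next
      b <- a + n_full * u - 1L
      extra <- 0L
      while (b + 1L <= n && extra < u - 1L && x[b + 1L] == cons[extra + 1L]) {
        b <- b + 1L; extra <- extra + 1L
      }
      copies <- (b - a + 1L) / u
      if (copies < min_copies) next
      matches <- sum(mat == matrix(cons, nrow(mat), u, byrow = TRUE)) + extra
      mism <- n_full * u - (matches - extra)
      score <- 2 * matches - 7 * mism
      if (score < min_score) next
      ident <- matches / (b - a + 1L)
      if (ident < min_identity - 1e-9) next
      consensus <- paste(cons, collapse = "")
      p_ok <- TRUE
      for (p in seq_len(min(6L, u - 1L))) {
        if (mean(cons[seq_len(u - p)] == cons[seq_len(u - p) + p]) >= 0.9) p_ok <- FALSE
      }
      if (!p_ok) next
      cands[[length(cands) + 1L]] <- list(
        unit_len = u, copies = round(copies, 2), consensus = consensus,
        start = a, end = b, percent_identity = round(ident, 4), score = score)
    }
  }
  if (length(cands) == 0L) {
    return(data.frame(unit_len = integer(0), copies = numeric(0),
                      consensus = character(0), start = integer(0),
                      end = integer(0), percent_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
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
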