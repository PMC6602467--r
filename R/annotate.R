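## Similarity-driven gene identification: search, chain, refine, assemble.
##
## CDS genes are found by translated search (protein vs six-frame genome),
## rRNA genes by nucleotide search.  Chains of HSPs are turned into gene
## models by projecting the reference exon structure through each exon's
## own alignment diagonal, which preserves reference phase at every
## boundary, then polishing the ends: the 5' end must sit on an in-frame
## ATG (searched within +/- 90 bp when the projected codon is not ATG) and
## the 3' end on the first in-frame stop within 90 bp.

REFINE_START_WINDOW <- 90L   # bp searched for an in-frame start codon
REFINE_STOP_WINDOW <- 90L    # bp searched downstream for an in-frame stop

#' Refine a chained HSP structure into a gene model
#'
#' Projects the reference exon structure onto the genome through the
#' chain: each reference exon is placed via the alignment diagonal of the
#' HSP that covers it, so exon lengths (and hence splice phase) follow the
#' reference.  Terminal exons without any covering HSP yield partial
#' flags; for CDS models the start and stop codons are then verified and,
#' when absent, searched within a +/-90 bp in-frame window.
#'
#' @param chain A chain from [chain_hsps()].
#' @param genome A `plastome`.
#' @param ref A reference gene entry (element of `reference_db$genes`).
#' @param mode `"translated"` when chain query coordinates are amino
#'   acids, `"nucleotide"` when they are bases.
#' @return A `gene_model` (with a `score` attribute), or `NULL` when no
#'   reference exon is covered.
#' @export
refine_gene_model <- function(chain, genome, ref,
                              mode = c("translated", "nucleotide")) {
  mode <- match.arg(mode)
  stopifnot(nrow(chain$hsps) >= 1L)
  hs <- chain$hsps
  if (mode == "translated") {
    hs$qn_start <- 3L * (hs$q_start - 1L) + 1L
    hs$qn_end <- 3L * hs$q_end
  } else {
    hs$qn_start <- hs$q_start
    hs$qn_end <- hs$q_end
  }
  lens <- vapply(ref$exons, function(e) nchar(e$sequence), integer(1L))
  cum <- cumsum(c(0L, lens))
  n_ex <- length(lens)
  strand <- chain$strand
  notes <- character(0)

  placed <- vector("list", n_ex)
  for (j in seq_len(n_ex)) {
    cs <- cum[j] + 1L; ce <- cum[j + 1L]
    ## HSP with maximal overlap of this exon's CDS range
    ov <- pmin(hs$qn_end, ce) - pmax(hs$qn_start, cs) + 1L
    if (all(ov <= 0L)) next
    h <- hs[which.max(ov), ]
    if (strand == "+") {
      st <- h$t_start + (cs - h$qn_start)
      en <- h$t_start + (ce - h$qn_start)
    } else {
      en <- h$t_end - (cs - h$qn_start)
      st <- h$t_end - (ce - h$qn_start)
    }
    clip_5p <- FALSE; clip_3p <- FALSE
    if (st < 1L) {
      if (strand == "+") clip_5p <- TRUE else clip_3p <- TRUE
      st <- 1L
    }
    if (en > genome$length) {
      if (strand == "+") clip_3p <- TRUE else clip_5p <- TRUE
      en <- genome$length
    }
    if (en - st + 1L < 3L) {
      notes <- c(notes, sprintf("exon %d projected outside genome; dropped", j))
      next
    }
    if (clip_5p || clip_3p) {
      notes <- c(notes, sprintf("exon %d clipped at the genome edge", j))
    }
    placed[[j]] <- structure(interval(st, en, strand),
                             clip_5p = clip_5p, clip_3p = clip_3p)
  }
  mapped <- which(!vapply(placed, is.null, logical(1L)))
  if (length(mapped) == 0L) return(NULL)
  if (!all(diff(mapped) == 1L)) {
    notes <- c(notes, "internal exon unmapped; model may be fragmented")
    mapped <- mapped[seq_len(which(c(diff(mapped), 2L) > 1L)[1L])]
  }
  partial_5p <- mapped[1L] > 1L ||
    isTRUE(attr(placed[[mapped[1L]]], "clip_5p"))
  partial_3p <- mapped[length(mapped)] < n_ex ||
    isTRUE(attr(placed[[mapped[length(mapped)]]], "clip_3p"))

  ivs <- placed[mapped]
  if (ref$kind == "CDS") {
    res <- polish_cds_ends(ivs, genome, partial_5p, partial_3p)
    ivs <- res$ivs; partial_5p <- res$partial_5p; partial_3p <- res$partial_3p
    notes <- c(notes, res$notes)
  }
  exons <- make_phased_exons(ivs, genome)
  model <- gene_model(ref$name, ref$kind, exons, strand = strand,
                      partial_5p = partial_5p, partial_3p = partial_3p,
                      provenance = "core", product = ref$product,
                      notes = notes)
  attr(model, "score") <- chain$score
  model
}

## verify/repair start and stop codons of a cis CDS exon chain
polish_cds_ends <- function(ivs, genome, partial_5p, partial_3p) {
  notes <- character(0)
  strand <- ivs[[1L]]$strand
  cds_of <- function(ivs) paste(vapply(ivs, function(iv) extract_seq(genome, iv),
                                       character(1L)), collapse = "")
  shift_start <- function(ivs, d) {   # move CDS start by d bases (5'->3' positive)
    iv <- ivs[[1L]]
    if (strand == "+") ivs[[1L]] <- interval(iv$start + d, iv$end, "+")
    else ivs[[1L]] <- interval(iv$start, iv$end - d, "-")
    ivs
  }
  shift_end <- function(ivs, d) {     # move CDS end by d bases (positive = extend)
    iv <- ivs[[length(ivs)]]
    if (strand == "+") ivs[[length(ivs)]] <- interval(iv$start, iv$end + d, "+")
    else ivs[[length(ivs)]] <- interval(iv$start - d, iv$end, "-")
    ivs
  }
  ok_iv <- function(ivs) {
    all(vapply(ivs, function(iv) iv$start >= 1L && iv$end <= genome$length &&
                 iv$start <= iv$end, logical(1L)))
  }
  if (!partial_5p) {
    cds <- cds_of(ivs)
    if (substr(cds, 1L, 3L) != "ATG") {
      found <- FALSE
      offs <- seq(3L, REFINE_START_WINDOW, by = 3L)
      for (d in as.vector(rbind(-offs, offs))) {
        cand <- tryCatch(shift_start(ivs, d), error = function(e) NULL)
        if (is.null(cand) || !ok_iv(cand)) next
        if (interval_span(cand[[1L]]) < 3L) next
        if (substr(cds_of(cand), 1L, 3L) == "ATG") {
          ivs <- cand; found <- TRUE
          notes <- c(notes, sprintf("start codon adjusted by %+d bp", d))
          break
        }
      }
      if (!found) {
        partial_5p <- TRUE
        notes <- c(notes, "no in-frame start codon within window")
      }
    }
  }
  if (!partial_3p) {
    cds <- cds_of(ivs)
    tail3 <- function(s) substr(s, nchar(s) - 2L, nchar(s))
    if (nchar(cds) %% 3L != 0L || !tail3(cds) %in% STOP_CODONS) {
      found <- FALSE
      ## trim to frame first
      frame_fix <- -(nchar(cds) %% 3L)
      for (d in frame_fix + seq(0L, REFINE_STOP_WINDOW, by = 3L)) {
        cand <- tryCatch(shift_end(ivs, d), error = function(e) NULL)
        if (is.null(cand) || !ok_iv(cand)) break
        if (tail3(cds_of(cand)) %in% STOP_CODONS) {
          ivs <- cand; found <- TRUE
          if (d != 0L) notes <- c(notes, sprintf("stop codon adjusted by %+d bp", d))
          break
        }
      }
      if (!found) {
        partial_3p <- TRUE
        notes <- c(notes, "no in-frame stop codon within window")
      }
    }
  }
  cds <- cds_of(ivs)
  if (!partial_5p && !partial_3p && nchar(cds) %% 3L == 0L) {
    p <- translate_cds(cds)
    if (attr(p, "internal_stop")) {
      notes <- c(notes, "internal stop codon in refined CDS")
    }
  }
  list(ivs = ivs, partial_5p = partial_5p, partial_3p = partial_3p,
       notes = notes)
}

## build exon list with cumulative phase
make_phased_exons <- function(ivs, genome) {
  cumlen <- 0L
  out <- vector("list", length(ivs))
  for (i in seq_along(ivs)) {
    phase <- (3L - (cumlen %% 3L)) %% 3L
    out[[i]] <- exon(ivs[[i]], phase, i)
    cumlen <- cumlen + interval_span(ivs[[i]], genome$length)
  }
  out
}

#' Annotate a plastome against a reference database
#'
#' Runs the full gene-annotation pipeline: quadripartite layout
#' detection, translated similarity search + chaining + refinement for
#' every reference CDS gene, nucleotide search for rRNA genes, the
#' anchored micro-exon finder for petB/petD/rpl16 (whose results override
#' the core model's first exon) and trans-spliced rps12 assembly.  Genes
#' present in both IR copies are reported once per copy.
#'
#' @param genome A `plastome`.
#' @param db A `reference_db`.
#' @param min_evalue E-value cutoff for the core gene search (default
#'   1e-6).
#' @param anchor_evalue E-value cutoff for the anchored micro-exon scan
#'   (default 1e-20).
#' @param max_intron Maximum intron length in bp (default 2000).
#' @return An `annotation_set`.
#' @export
annotate_genome <- function(genome, db, min_evalue = 1e-6,
                            anchor_evalue = 1e-20, max_intron = 2000L) {
  stopifnot(inherits(genome, "plastome"), inherits(db, "reference_db"))
  warnings <- empty_warnings()
  layout <- withCallingHandlers(
    detect_inverted_repeats(genome),
    warning = function(w) {
      warnings <<- rbind(warnings, warning_record("layout", genome$id,
                                                  conditionMessage(w), "info"))
      invokeRestart("muffleWarning")
    })
  idx_pro <- build_search_index(genome, "translated")
  idx_nuc <- build_search_index(genome, "nucleotide")
  anchors <- suppressWarnings(build_anchor_table(db))

  targets <- unique(vapply(db$genes, function(g) paste(g$name, g$kind, sep = "\r"),
                           character(1L)))
  models <- list()
  for (key in targets) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    name <- parts[1L]; kind <- parts[2L]
    if (kind == "tRNA") next          # tRNA models come from the predictors
    if (name == "rps12") next         # handled by the trans-splicing assembler
    refs <- db_genes(db, name, kind)
    best <- NULL
    for (ref in refs) {
      if (kind == "CDS") {
        if (is.na(ref$protein) || nchar(ref$protein) < 5L) next
        hsps <- similarity_search(ref$protein, idx_pro, "translated",
                                  min_evalue, name)
      } else {
        hsps <- similarity_search(ref$cds, idx_nuc, "nucleotide",
                                  min_evalue, name)
      }
      chains <- chain_hsps(hsps, max_intron)
      if (length(chains) == 0L) next
      if (is.null(best) || chains[[1L]]$score > best$score) {
        best <- list(ref = ref, chains = chains, score = chains[[1L]]$score)
      }
    }
    if (is.null(best)) {
      warnings <- rbind(warnings, warning_record(
        "annotation", name, paste0("gene ", name, " not found in genome")))
      next
    }
    mode <- if (kind == "CDS") "translated" else "nucleotide"
    for (ch in best$chains) {
      if (ch$score < 0.25 * best$score) next   # weak residual loci
      m <- refine_gene_model(ch, genome, best$ref, mode)
      if (is.null(m)) next
      ## micro-exon genes: anchored finder supplies/overrides exon 1
      if (name %in% c("petB", "petD", "rpl16") && nrow(anchors)) {
        rows <- anchors[anchors$gene == name & anchors$side == "five_prime" &
                          anchors$valid, , drop = FALSE]
        if (nrow(rows)) {
          ref_n_ex <- length(best$ref$exons)
          ## which core exon plays the ref exon-2 role: the first when the
          ## micro-exon is missing from the chain, the second otherwise
          missing_first <- length(m$exons) == ref_n_ex - 1L
          partner <- if (missing_first || length(m$exons) < 2L)
            m$exons[[1L]]$interval else m$exons[[2L]]$interval
          e1 <- withCallingHandlers(
            find_small_exon(idx_nuc, rows, anchor_evalue, partner, max_intron),
            warning = function(w) {
              warnings <<- rbind(warnings, warning_record(
                "isecus", name, conditionMessage(w)))
              invokeRestart("muffleWarning")
            })
          if (!is.null(e1)) {
            core_rest <- if (missing_first) m$exons else m$exons[-1L]
            ivs <- c(list(e1$interval),
                     lapply(core_rest, `[[`, "interval"))
            m2 <- gene_model(name, "CDS", make_phased_exons(ivs, genome),
                             strand = m$strand,
                             partial_5p = FALSE, partial_3p = m$partial_3p,
                             provenance = "isecus", product = m$product,
                             notes = m$notes)
            attr(m2, "score") <- attr(m, "score")
            m <- m2
          }
        }
      }
      models[[length(models) + 1L]] <- m
    }
  }

  ## trans-spliced rps12
  if (length(db_genes(db, "rps12", "CDS"))) {
    r12 <- withCallingHandlers(
      assemble_rps12(genome, db, layout, max_intron = max_intron,
                     min_evalue = min_evalue, anchor_evalue = anchor_evalue,
                     idx_nuc = idx_nuc),
      warning = function(w) {
        warnings <<- rbind(warnings, warning_record(
          "itgie", "rps12", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    models <- c(models, r12)
  }

  ## per-gene duplicate suppression (IR twin copies are disjoint loci and
  ## therefore never overlap)
  models <- suppress_duplicate_models(models)
  models <- assign_copy_numbers(models)

  for (m in models) {
    bad <- validate_gene_model(m, genome)
    for (b in bad) {
      warnings <- rbind(warnings, warning_record("validation", m$name, b))
    }
  }
  if (length(models) == 0L) {
    warnings <- rbind(warnings, warning_record(
      "annotation", genome$id, "no genes found; empty annotation", "warn"))
  }
  annotation_set(genome$id, models, layout, warnings)
}

## drop same-name models overlapping >= 50% (keep higher score)
suppress_duplicate_models <- function(models) {
  if (length(models) <= 1L) return(models)
  drop <- rep(FALSE, length(models))
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (i >= j || drop[i] || drop[j]) next
      mi <- models[[i]]; mj <- models[[j]]
      if (mi$name != mj$name) next
      if (!is.null(mi$transcript_id) || !is.null(mj$transcript_id)) next
      si <- gene_model_span(mi); sj <- gene_model_span(mj)
      ov <- min(si$end, sj$end) - max(si$start, sj$start) + 1L
      if (ov <= 0L) next
      li <- si$end - si$start + 1L; lj <- sj$end - sj$start + 1L
      if (ov >= 0.5 * min(li, lj)) {
        sc_i <- attr(mi, "score") %||% 0; sc_j <- attr(mj, "score") %||% 0
        if (sc_i >= sc_j) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
  }
  models[!drop]
}
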