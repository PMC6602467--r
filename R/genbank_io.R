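## GenBank flat-file reader and writer.
##
## The reader covers the subset of the format needed for plastome
## references: LOCUS, FEATURES with join()/complement()/order() locations
## and quoted or bare qualifiers, and ORIGIN sequence lines.  No R package
## in the dependency stack parses GenBank flat files, so this is done here.

#' Parse a GenBank location string
#'
#' Handles `start..end`, `complement(...)`, `join(...)`, `order(...)`,
#' nesting of complement inside join and vice versa, and `<`/`>` partial
#' markers (recorded, not applied).
#'
#' @param loc Location string.
#' @return A list with `segments` (data.frame start, end, strand, in the
#'   order written in the file, i.e. transcription order), `partial_5p`,
#'   `partial_3p`.
#' @keywords internal
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  partial_5p <- grepl("<", loc, fixed = TRUE)
  partial_3p <- grepl(">", loc, fixed = TRUE)
  loc0 <- gsub("[<>]", "", loc)

  parse_node <- function(s, flip) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse_node(inner, !flip))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_top_level(inner)
      segs <- do.call(rbind, lapply(parts, parse_node, flip = flip))
      ## complement(join(a,b)) means the written order is reversed in
      ## transcription orientation
      if (flip) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
      return(segs)
    }
    m <- regmatches(s, regexec("^(\\d+)(\\.\\.(\\d+))?$", s))[[1L]]
    if (length(m) == 0L) stop("unparseable GenBank location component: ", s)
    st <- as.integer(m[2L])
    en <- if (nzchar(m[4L] %||% "")) as.integer(m[4L]) else st
    data.frame(start = st, end = en,
               strand = if (flip) "-" else "+",
               stringsAsFactors = FALSE)
  }
  segs <- parse_node(loc0, FALSE)
  rownames(segs) <- NULL
  list(segments = segs, partial_5p = partial_5p, partial_3p = partial_3p)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

## split "a,b(c,d),e" at top-level commas only
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L; cur <- character(0); out <- character(0); buf <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { out <- c(out, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  c(out, buf)
}

#' Read a GenBank flat file
#'
#' @param path Path to a GenBank file (one or more LOCUS records).
#' @return A list of `genbank_record` objects, each with `accession`,
#'   `definition`, `length`, `circular`, `sequence` and `features` (a list
#'   of lists with `type`, `location` (parsed), `qualifiers` (named
#'   character)).
#' @export
read_genbank <- function(path) {
  if (length(path) > 1L) {
    lines <- path
    path <- "<lines>"
  } else {
    if (!file.exists(path)) stop("GenBank file not found: ", path)
    lines <- readLines(path, warn = FALSE)
  }
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) stop("not a GenBank flat file (no LOCUS): ", path)
  ends <- c(locus_idx[-1L] - 1L, length(lines))
  records <- vector("list", length(locus_idx))
  for (r in seq_along(locus_idx)) {
    block <- lines[locus_idx[r]:ends[r]]
    records[[r]] <- parse_gb_record(block, path)
  }
  records
}

parse_gb_record <- function(block, path) {
  locus <- block[1L]
  toks <- strsplit(trimws(locus), "\\s+")[[1L]]
  accession <- if (length(toks) >= 2L) toks[2L] else "unknown"
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L][1L]))
  circular <- any(tolower(toks) == "circular")
  def_i <- grep("^DEFINITION", block)
  definition <- if (length(def_i)) trimws(sub("^DEFINITION", "", block[def_i[1L]])) else ""

  feat_i <- grep("^FEATURES", block)
  orig_i <- grep("^ORIGIN", block)
  end_i <- grep("^//\\s*$", block)
  if (length(end_i) == 0L) end_i <- length(block) + 1L

  ## --- sequence ---
  sequence <- ""
  if (length(orig_i)) {
    seq_lines <- block[(orig_i[1L] + 1L):(end_i[1L] - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (is.na(len) || len == 0L) len <- nchar(sequence)

  ## --- features ---
  features <- list()
  if (length(feat_i)) {
    fend <- if (length(orig_i)) orig_i[1L] - 1L else end_i[1L] - 1L
    flines <- block[(feat_i[1L] + 1L):fend]
    ## feature starts: 5 leading spaces + key; continuations: 21 spaces
    is_key <- grepl("^ {1,10}\\S", flines) & !grepl("^ {12,}", flines)
    starts <- which(is_key)
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(flines)
      fl <- flines[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", fl[1L])
      rest <- sub("^\\s*\\S+\\s*", "", fl[1L])
      body <- c(rest, trimws(fl[-1L]))
      ## location = leading lines until the first qualifier line
      qual_start <- grep("^/", body)
      loc_str <- paste(body[seq_len(if (length(qual_start)) qual_start[1L] - 1L else length(body))],
                       collapse = "")
      quals <- character(0)
      if (length(qual_start)) {
        qlines <- body[qual_start[1L]:length(body)]
        ## re-join continuation lines of quoted qualifiers
        joined <- character(0)
        for (q in qlines) {
          if (grepl("^/", q) || length(joined) == 0L) joined <- c(joined, q)
          else joined[length(joined)] <- paste0(joined[length(joined)],
                                                if (grepl("^/translation", joined[length(joined)])) "" else " ",
                                                q)
        }
        for (q in joined) {
          m <- regmatches(q, regexec('^/([A-Za-z_0-9]+)(=("?)(.*?)("?))?$', q))[[1L]]
          if (length(m)) {
            val <- if (nzchar(m[3L])) gsub('"', "", m[5L]) else "true"
            quals[m[2L]] <- val
          }
        }
      }
      if (!nzchar(gsub("[[:space:]]", "", loc_str))) next
      parsed <- tryCatch(parse_gb_location(loc_str),
                         error = function(e) NULL)
      if (is.null(parsed)) {
        warning("skipping feature with unparseable location in ", path, ": ", loc_str)
        next
      }
      spans <- parsed$segments$end - parsed$segments$start + 1L
      if (any(spans <= 0L)) {
        warning("skipping zero-length feature location in ", path, ": ", loc_str)
        next
      }
      features[[length(features) + 1L]] <-
        list(type = key, location = parsed, qualifiers = quals)
    }
  }
  structure(list(accession = accession, definition = definition,
                 length = len, circular = circular,
                 sequence = sequence, features = features),
            class = "genbank_record")
}

#' @export
print.genbank_record <- function(x, ...) {
  cat(sprintf("<genbank_record> %s: %d bp, %d features\n",
              x$accession, x$length, length(x$features)))
  invisible(x)
}

## ---- writer ---------------------------------------------------------------

format_gb_location <- function(model, genome_length = NULL) {
  segs <- lapply(model$exons, function(e) e$interval)
  one <- function(iv) {
    core <- if (iv$wraps_origin) {
      ## split into two segments at the origin; GenBank encodes this as a join
      sprintf("%d..%d,%d..%d", iv$start, genome_length, 1L, iv$end)
    } else if (iv$start == iv$end) {
      sprintf("%d", iv$start)
    } else {
      sprintf("%d..%d", iv$start, iv$end)
    }
    if (iv$strand == "-") {
      if (grepl(",", core)) sprintf("complement(join(%s))", core)
      else sprintf("complement(%s)", core)
    } else if (grepl(",", core)) sprintf("join(%s)", core) else core
  }
  parts <- vapply(segs, one, character(1L))
  if (length(parts) == 1L && !grepl("^complement\\(join", parts)) return(parts)
  ## uniform-strand multi-exon: complement(join(...)) with ascending coords
  strands <- vapply(segs, function(iv) iv$strand, character(1L))
  if (all(strands == "-") && !model$trans_spliced) {
    cores <- rev(vapply(segs, function(iv) {
      if (iv$wraps_origin) sprintf("%d..%d,%d..%d", iv$start, genome_length, 1L, iv$end)
      else sprintf("%d..%d", iv$start, iv$end)
    }, character(1L)))
    return(sprintf("complement(join(%s))", paste(cores, collapse = ",")))
  }
  if (all(strands == "+") && !model$trans_spliced) {
    cores <- vapply(segs, function(iv) {
      if (iv$wraps_origin) sprintf("%d..%d,%d..%d", iv$start, genome_length, 1L, iv$end)
      else sprintf("%d..%d", iv$start, iv$end)
    }, character(1L))
    return(sprintf("join(%s)", paste(cores, collapse = ",")))
  }
  ## mixed strand (trans-spliced): join of per-exon terms in transcript order
  sprintf("join(%s)", paste(parts, collapse = ","))
}

wrap_gb_qualifier <- function(text, width = 58L) {
  ## wrap a qualifier body for the 21-column feature block
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1L, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

#' Write an annotation set as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN.  Multi-exon features use `join(...)`,
#' minus-strand features `complement(...)`, and trans-spliced models carry
#' `/exception="trans-splicing"`.  A `/translation` qualifier is included
#' for complete CDS models.
#'
#' @param annotation An `annotation_set`.
#' @param genome A `plastome`.
#' @param path Output file; when `NULL` the text is returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_genbank <- function(annotation, genome, path = NULL) {
  n <- genome$length
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s PLN %s",
            genome$id, n, if (genome$circular) "circular" else "linear",
            "01-JAN-2000"),
    sprintf("DEFINITION  %s plastome annotation.", genome$id),
    sprintf("ACCESSION   %s", genome$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("                     /organism=\"%s\"", genome$id)
  )
  add_feature <- function(key, loc, quals) {
    first <- sprintf("     %-16s%s", key, loc)
    ## long locations wrap at commas
    while (nchar(first) > 79L) {
      cut <- max(gregexpr(",", substr(first, 1L, 79L))[[1L]])
      if (cut <= 21L) break
      lines <<- c(lines, substr(first, 1L, cut))
      first <- paste0(strrep(" ", 21L), substr(first, cut + 1L, nchar(first)))
    }
    lines <<- c(lines, first)
    for (qn in names(quals)) {
      body <- sprintf("/%s=\"%s\"", qn, quals[[qn]])
      for (piece in wrap_gb_qualifier(body)) {
        lines <<- c(lines, paste0(strrep(" ", 21L), piece))
      }
    }
  }
  for (model in annotation$models) {
    loc <- format_gb_location(model, n)
    wraps <- any(vapply(model$exons, function(e) e$interval$wraps_origin,
                        logical(1L)))
    gene_loc <- if (model$trans_spliced || wraps) loc else {
      ## gene feature spans the full extent on one strand
      sp <- gene_model_span(model)
      if (sp$strand == "-") sprintf("complement(%d..%d)", sp$start, sp$end)
      else sprintf("%d..%d", sp$start, sp$end)
    }
    add_feature("gene", gene_loc, c(gene = model$name))
    key <- switch(model$kind, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA")
    quals <- c(gene = model$name)
    if (!is.null(model$product) && nzchar(model$product %||% "")) {
      quals <- c(quals, product = model$product)
    }
    if (model$trans_spliced) quals <- c(quals, exception = "trans-splicing")
    if (model$kind == "CDS" && !model$partial_5p && !model$partial_3p) {
      cds <- gene_model_cds(model, genome)
      if (nchar(cds) >= 3L && nchar(cds) %% 3L == 0L) {
        prot <- translate_cds(cds)
        if (!attr(prot, "internal_stop")) {
          quals <- c(quals, translation = as.character(prot))
        }
      }
    }
    add_feature(key, loc, quals)
  }
  lines <- c(lines, "ORIGIN")
  seqchars <- genome$sequence
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(seqchars, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  lines <- c(lines, "//")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Convert a parsed GenBank record to an annotation set
#'
#' Maps CDS/rRNA/tRNA features back to gene models (the round-trip
#' inverse of [write_genbank()]).  Adjacent join segments that meet at
#' the origin are merged into one origin-wrapping exon.
#'
#' @param record A `genbank_record` from [read_genbank()].
#' @return An `annotation_set`.
#' @export
genbank_to_annotation <- function(record) {
  n <- record$length
  models <- list()
  qget <- function(q, key) if (key %in% names(q)) q[[key]] else NA_character_
  feats <- Filter(function(f) f$type %in% c("CDS", "rRNA", "tRNA"),
                  record$features)
  for (f in feats) {
    nm <- qget(f$qualifiers, "gene")
    if (is.na(nm)) next
    segs <- f$location$segments
    ## merge origin-split segment pairs (.., n) + (1, ..)
    ivs <- list()
    i <- 1L
    while (i <= nrow(segs)) {
      if (i < nrow(segs) && segs$strand[i] == segs$strand[i + 1L] &&
          ((segs$strand[i] == "+" && segs$end[i] == n && segs$start[i + 1L] == 1L) ||
           (segs$strand[i] == "-" && segs$start[i] == 1L && segs$end[i + 1L] == n))) {
        if (segs$strand[i] == "+") {
          ivs[[length(ivs) + 1L]] <- interval(segs$start[i], segs$end[i + 1L],
                                              "+", wraps_origin = TRUE)
        } else {
          ivs[[length(ivs) + 1L]] <- interval(segs$start[i + 1L], segs$end[i],
                                              "-", wraps_origin = TRUE)
        }
        i <- i + 2L
      } else {
        ivs[[length(ivs) + 1L]] <- interval(segs$start[i], segs$end[i],
                                            segs$strand[i])
        i <- i + 1L
      }
    }
    trans <- identical(qget(f$qualifiers, "exception"), "trans-splicing")
    exl <- list()
    cumlen <- 0L
    for (k in seq_along(ivs)) {
      exl[[k]] <- exon(ivs[[k]], (3L - (cumlen %% 3L)) %% 3L, k)
      cumlen <- cumlen + interval_span(ivs[[k]], n)
    }
    prod <- qget(f$qualifiers, "product")
    m <- gene_model(nm, f$type, exl, trans_spliced = trans,
                    partial_5p = f$location$partial_5p,
                    partial_3p = f$location$partial_3p,
                    provenance = "core",
                    product = if (is.na(prod)) NULL else prod)
    models[[length(models) + 1L]] <- m
  }
  ## trans-spliced same-name features become transcripts t1, t2, ...
  nm_all <- vapply(models, function(m) m$name, character(1L))
  for (u in unique(nm_all)) {
    idx <- which(nm_all == u)
    if (length(idx) > 1L &&
        all(vapply(models[idx], function(m) m$trans_spliced, logical(1L)))) {
      for (r in seq_along(idx)) {
        models[[idx[r]]]$transcript_id <- sprintf("%s.t%d", u, r)
        models[[idx[r]]]$shared_exon <- 1L
      }
    }
  }
  annotation_set(record$accession, assign_copy_numbers(models))
}
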