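## Circular genome map as SVG: four concentric rings, inside out --
## dispersed repeat arcs (forward red, palindromic green), tandem repeat
## bars, SSR ticks, and genes colored by functional category.  Output is
## deterministic for fixed input.

GENE_CATEGORY_COLORS <- c(
  photosystem = "#2E8B57",     # psa/psb
  cytochrome = "#B8860B",      # pet
  atp_synthase = "#4169E1",    # atp
  ndh = "#8B4513",             # ndh
  rubisco = "#228B22",         # rbcL
  rna_polymerase = "#A0522D",  # rpo
  ribosomal_protein = "#DAA520", # rps/rpl
  rrna = "#CD5C5C",            # rrn
  trna = "#6A5ACD",            # trn
  other = "#808080"
)

gene_category <- function(name) {
  if (grepl("^ps[ab]", name)) "photosystem"
  else if (grepl("^pet", name)) "cytochrome"
  else if (grepl("^atp", name)) "atp_synthase"
  else if (grepl("^ndh", name)) "ndh"
  else if (grepl("^rbc", name)) "rubisco"
  else if (grepl("^rpo", name)) "rna_polymerase"
  else if (grepl("^(rps|rpl)", name)) "ribosomal_protein"
  else if (grepl("^rrn", name)) "rrna"
  else if (grepl("^trn", name)) "trna"
  else "other"
}

svg_num <- function(x) sprintf("%.2f", x)

polar_xy <- function(cx, cy, r, pos, n) {
  theta <- 2 * pi * (pos - 1) / n - pi / 2
  c(cx + r * cos(theta), cy + r * sin(theta))
}

svg_ring_arc <- function(cx, cy, r, from, to, n, stroke, width, fill = "none") {
  p1 <- polar_xy(cx, cy, r, from, n)
  p2 <- polar_xy(cx, cy, r, to, n)
  large <- if (((to - from) %% n) / n > 0.5) 1L else 0L
  sprintf('<path d="M %s %s A %s %s 0 %d 1 %s %s" stroke="%s" stroke-width="%s" fill="%s"/>',
          svg_num(p1[1L]), svg_num(p1[2L]), svg_num(r), svg_num(r), large,
          svg_num(p2[1L]), svg_num(p2[2L]), stroke, svg_num(width), fill)
}

#' Render the circular annotation + repeat map as SVG
#'
#' @param annotation An `annotation_set`.
#' @param repeats List with `ssr`, `tandem`, `dispersed` data.frames (any
#'   may be zero-row).
#' @param genome A `plastome`.
#' @param path Output path; `NULL` returns the SVG text.
#' @param size Canvas size in px (default 800).
#' @return Character vector of SVG lines, invisibly.
#' @export
render_map <- function(annotation, repeats, genome, path = NULL, size = 800) {
  n <- genome$length
  cx <- size / 2; cy <- size / 2
  r_disp <- size * 0.18; r_tandem <- size * 0.26
  r_ssr <- size * 0.31; r_gene <- size * 0.38
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('<title>%s circular map</title>', genome$id),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size)
  )
  ## ring guides, inside out
  for (r in c(r_disp, r_tandem, r_ssr, r_gene)) {
    out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" stroke="#DDDDDD" stroke-width="0.8" fill="none"/>',
                          svg_num(cx), svg_num(cy), svg_num(r)))
  }
  out <- c(out, '<g id="ring-dispersed">')
  dr <- repeats$dispersed
  if (!is.null(dr) && nrow(dr)) {
    for (i in seq_len(nrow(dr))) {
      col <- if (dr$orientation[i] == "forward") "red" else "green"
      p1 <- polar_xy(cx, cy, r_disp, (dr$a_start[i] + dr$a_end[i]) / 2, n)
      p2 <- polar_xy(cx, cy, r_disp, (dr$b_start[i] + dr$b_end[i]) / 2, n)
      out <- c(out, sprintf('<path d="M %s %s Q %s %s %s %s" stroke="%s" stroke-width="1.2" fill="none" class="dispersed-%s"/>',
                            svg_num(p1[1L]), svg_num(p1[2L]), svg_num(cx),
                            svg_num(cy), svg_num(p2[1L]), svg_num(p2[2L]),
                            col, dr$orientation[i]))
    }
  }
  out <- c(out, '</g>', '<g id="ring-tandem">')
  tr <- repeats$tandem
  if (!is.null(tr) && nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      out <- c(out, svg_ring_arc(cx, cy, r_tandem, tr$start[i],
                                 max(tr$end[i], tr$start[i] + n / 400), n,
                                 "#FF8C00", 6))
    }
  }
  out <- c(out, '</g>', '<g id="ring-ssr">')
  sr <- repeats$ssr
  if (!is.null(sr) && nrow(sr)) {
    for (i in seq_len(nrow(sr))) {
      p1 <- polar_xy(cx, cy, r_ssr - 5, sr$start[i], n)
      p2 <- polar_xy(cx, cy, r_ssr + 5, sr$start[i], n)
      out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#9932CC" stroke-width="1.5"/>',
                            svg_num(p1[1L]), svg_num(p1[2L]),
                            svg_num(p2[1L]), svg_num(p2[2L])))
    }
  }
  out <- c(out, '</g>', '<g id="ring-genes">')
  cats_seen <- character(0)
  for (m in annotation$models) {
    cat_m <- gene_category(m$name)
    cats_seen <- union(cats_seen, cat_m)
    col <- GENE_CATEGORY_COLORS[[cat_m]]
    ## strand offsets: plus outside, minus inside
    roff <- if (m$strand == "-") -7 else 7
    for (e in m$exons) {
      iv <- e$interval
      out <- c(out, svg_ring_arc(cx, cy, r_gene + roff, iv$start,
                                 max(iv$end, iv$start + n / 800), n, col, 8))
    }
    sp <- gene_model_span(m)
    pl <- polar_xy(cx, cy, r_gene + 26, (sp$start + sp$end) / 2, n)
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="8" font-family="monospace" text-anchor="middle" fill="%s">%s</text>',
                          svg_num(pl[1L]), svg_num(pl[2L]), col, m$name))
  }
  out <- c(out, '</g>', '<g id="legend">')
  ypos <- 18
  for (cat_m in names(GENE_CATEGORY_COLORS)) {
    if (!cat_m %in% cats_seen) next
    out <- c(out, sprintf('<rect x="10" y="%d" width="12" height="8" fill="%s"/>',
                          ypos - 8, GENE_CATEGORY_COLORS[[cat_m]]),
             sprintf('<text x="26" y="%d" font-size="10" font-family="sans-serif">%s</text>',
                     ypos, gsub("_", " ", cat_m)))
    ypos <- ypos + 14
  }
  out <- c(out,
           sprintf('<text x="%s" y="%s" font-size="14" font-family="sans-serif" text-anchor="middle">%s</text>',
                   svg_num(cx), svg_num(cy - 6), genome$id),
           sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle">%d bp</text>',
                   svg_num(cx), svg_num(cy + 10), n),
           '</g>', '</svg>')
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
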