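# ---------------------------------------------------------------------------
# Gene-model visualization
#
# A gene is drawn as an intron baseline with exon boxes (UTR regions in a
# distinct style) and one track row per peptide, colored by
# genomic-context cluster. Layout is computed as plain data first, so both
# the SVG and the PNG renderers draw the same deterministic geometry.
# ---------------------------------------------------------------------------

DEFAULT_PALETTE <- c(known = "#808080", intronic = "#CC0000",
                     exon_donor_spanning = "#E69500",
                     exon_acceptor_spanning = "#0066CC",
                     intergenic = "#7B2D8E")

# vertical geometry (pixels)
.VIZ <- list(margin = 20L, gene_track_h = 24L, exon_h = 16L, utr_h = 10L,
             pep_h = 8L, pep_gap = 4L, label_h = 14L)

#' Compute a deterministic drawing layout for a gene and its peptides
#'
#' Produces a data.frame of drawables (boxes, lines, labels) with pixel
#' coordinates: a gene baseline spanning the gene, exon boxes, UTR boxes
#' in a thinner style, and one row per peptide, with non-overlapping
#' peptides packed greedily onto the same row. Pixel x positions are
#' \code{round((pos - gene_start) * scale)}, so positions are monotone in
#' genomic coordinates. Peptides overhanging the gene span are clipped
#' and marked.
#'
#' @param gene A gene model.
#' @param calls data.frame of peptide calls to draw, with columns
#'   peptide_id, start, end (chromosome coordinates) and cluster.
#' @param scale Pixels per base (> 0).
#' @param palette Named cluster-to-color map.
#' @return list(width, height, drawables) where drawables has columns
#'   kind (baseline/exon/utr/peptide/clip), x0, x1, y0, y1, color, label.
#' @export
layout_gene <- function(gene, calls = NULL, scale = 0.2,
                        palette = DEFAULT_PALETTE) {
  if (scale <= 0) stop("scale must be > 0")
  span <- gene$end - gene$start + 1L
  if (span <= 0L) stop("zero-length render window")
  px <- function(pos) round((pos - gene$start) * scale)
  m <- .VIZ$margin
  width <- px(gene$end + 1L) + 2L * m
  y_gene <- m + .VIZ$label_h
  mid <- y_gene + .VIZ$gene_track_h %/% 2L

  d <- list()
  add <- function(kind, x0, x1, y0, y1, color, label = "") {
    d[[length(d) + 1L]] <<- data.frame(
      kind = kind, x0 = x0, x1 = x1, y0 = y0, y1 = y1, color = color,
      label = label, stringsAsFactors = FALSE)
  }
  add("label", m, m, m, m + .VIZ$label_h, "#000000",
      paste0(gene$gene_id, " (", gene$strand, ") ", gene$seqid, ":",
             gene$start, "-", gene$end))
  add("baseline", m + px(gene$start), m + px(gene$end + 1L), mid, mid,
      "#000000")
  eh <- .VIZ$exon_h %/% 2L
  for (i in seq_len(nrow(gene$exon_union))) {
    add("exon", m + px(gene$exon_union$start[i]),
        m + px(gene$exon_union$end[i] + 1L), mid - eh, mid + eh, "#2F4F7F")
  }
  uh <- .VIZ$utr_h %/% 2L
  for (tx in gene$transcripts) {
    for (utr in list(tx$utr5, tx$utr3)) {
      for (i in seq_len(nrow(utr))) {
        add("utr", m + px(utr$start[i]), m + px(utr$end[i] + 1L),
            mid - uh, mid + uh, "#9FB6CD")
      }
    }
  }

  # greedy interval packing of peptides onto rows
  y_pep0 <- y_gene + .VIZ$gene_track_h + .VIZ$pep_gap
  n_rows <- 0L
  if (!is.null(calls) && nrow(calls)) {
    calls <- calls[order(calls$start, calls$end, calls$peptide_id), ,
                   drop = FALSE]
    row_end <- numeric()   # rightmost occupied pixel per row
    for (i in seq_len(nrow(calls))) {
      s <- max(calls$start[i], gene$start)
      e <- min(calls$end[i], gene$end)
      clipped <- calls$start[i] < gene$start || calls$end[i] > gene$end
      x0 <- m + px(s); x1 <- m + px(e + 1L)
      r <- which(row_end < x0)[1L]
      if (is.na(r)) { row_end <- c(row_end, -Inf); r <- length(row_end) }
      row_end[r] <- x1 + 2L
      y0 <- y_pep0 + (r - 1L) * (.VIZ$pep_h + .VIZ$pep_gap)
      col <- palette[[calls$cluster[i]]]
      if (is.null(col)) col <- "#000000"
      add("peptide", x0, x1, y0, y0 + .VIZ$pep_h, col, calls$peptide_id[i])
      if (clipped) {
        add("clip", x1, x1 + 4L, y0, y0 + .VIZ$pep_h, "#000000")
      }
    }
    n_rows <- length(row_end)
  }
  height <- y_pep0 + n_rows * (.VIZ$pep_h + .VIZ$pep_gap) + m
  list(width = as.integer(width), height = as.integer(height),
       drawables = do.call(rbind, c(d, list(empty_drawables()))))
}

empty_drawables <- function() {
  data.frame(kind = character(), x0 = numeric(), x1 = numeric(),
             y0 = numeric(), y1 = numeric(), color = character(),
             label = character(), stringsAsFactors = FALSE)
}

#' Render a layout to SVG text
#'
#' Output is byte-deterministic for a fixed layout: one SVG element per
#' drawable, serialized in layout order with fixed formatting.
#'
#' @param layout Layout from \code{layout_gene}.
#' @param path Optional output path; when NULL the SVG lines are returned.
#' @return Invisibly (or visibly when path is NULL), the SVG text lines.
#' @export
render_svg <- function(layout, path = NULL) {
  d <- layout$drawables
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    layout$width, layout$height, layout$width, layout$height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            layout$width, layout$height))
  for (i in seq_len(nrow(d))) {
    lines <- c(lines, switch(
      d$kind[i],
      baseline = sprintf(
        '<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="%s" stroke-width="2"/>',
        d$x0[i], d$y0[i], d$x1[i], d$y1[i], d$color[i]),
      label = sprintf(
        '<text x="%d" y="%d" font-family="monospace" font-size="12" fill="%s">%s</text>',
        d$x0[i], d$y1[i], d$color[i], d$label[i]),
      sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
              d$x0[i], d$y0[i], max(d$x1[i] - d$x0[i], 1L),
              max(d$y1[i] - d$y0[i], 1L), d$color[i])
    ))
  }
  lines <- c(lines, "</svg>")
  if (is.null(path)) return(lines)
  writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Render a layout to a PNG file
#'
#' Rasterizes the layout into an RGB array drawable-by-drawable and
#' writes it with \code{png::writePNG}, so pixels are deterministic for a
#' fixed layout and palette (text labels are not rasterized).
#'
#' @param layout Layout from \code{layout_gene}.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
render_png <- function(layout, path) {
  w <- layout$width; h <- layout$height
  img <- array(1, dim = c(h, w, 3L))
  d <- layout$drawables
  for (i in seq_len(nrow(d))) {
    if (d$kind[i] == "label") next
    rgbv <- grDevices::col2rgb(d$color[i])[, 1L] / 255
    x0 <- max(d$x0[i], 0L); x1 <- min(max(d$x1[i], x0 + 1L), w)
    y0 <- max(d$y0[i], 0L); y1 <- min(max(d$y1[i], y0 + 1L), h)
    if (d$kind[i] == "baseline") { y0 <- d$y0[i] - 1L; y1 <- d$y0[i] + 1L }
    rows <- (y0 + 1L):y1; cols <- (x0 + 1L):x1
    for (ch in 1:3) img[rows, cols, ch] <- rgbv[ch]
  }
  png::writePNG(img, target = path)
  invisible(path)
}

#' Draw a gene figure in one call
#'
#' @param gene A gene model.
#' @param calls Peptide calls for the gene (see \code{layout_gene}).
#' @param path Output path; format chosen by extension (.svg or .png)
#'   unless \code{format} is given.
#' @param format "svg" or "png".
#' @param scale Pixels per base.
#' @param palette Cluster-to-color map.
#' @return Invisibly, the path.
#' @export
render_gene_figure <- function(gene, calls, path, format = NULL,
                               scale = 0.2, palette = DEFAULT_PALETTE) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  layout <- layout_gene(gene, calls, scale = scale, palette = palette)
  switch(format,
         svg = render_svg(layout, path),
         png = render_png(layout, path),
         stop("unsupported figure format: ", format))
  invisible(path)
}
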