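#' Deterministic vector-graphic documents
#'
#' Figures are built as a flat list of drawing primitives (rect, line,
#' polyline, circle, text) in an abstract canvas coordinate system
#' (y grows downward, as in SVG). The same primitive list serializes to a
#' byte-stable SVG string or rasterizes to PNG, so both export formats are
#' views of one rendering. All numeric attributes are formatted with fixed
#' precision, making SVG output a pure function of the input with no
#' timestamps or random ids.
#'
#' @name graphic-documents
NULL

new_document <- function(width, height) {
  structure(list(width = width, height = height, elements = list()),
            class = "trace_document")
}

#' @export
print.trace_document <- function(x, ...) {
  cat("<trace_document> ", x$width, " x ", x$height, ", ",
      length(x$elements), " element(s)\n", sep = "")
  invisible(x)
}

doc_add <- function(doc, el) {
  doc$elements[[length(doc$elements) + 1L]] <- el
  doc
}

doc_rect <- function(doc, x, y, w, h, fill = "none", stroke = "none",
                     stroke_width = 1) {
  doc_add(doc, list(type = "rect", x = x, y = y, w = w, h = h, fill = fill,
                    stroke = stroke, stroke_width = stroke_width))
}

doc_line <- function(doc, x1, y1, x2, y2, stroke = "#000000", stroke_width = 1) {
  doc_add(doc, list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                    stroke = stroke, stroke_width = stroke_width))
}

doc_polyline <- function(doc, xs, ys, stroke = "#000000", stroke_width = 1.5) {
  doc_add(doc, list(type = "polyline", xs = xs, ys = ys, stroke = stroke,
                    stroke_width = stroke_width))
}

doc_circle <- function(doc, cx, cy, r, fill = "#000000", stroke = "none",
                       stroke_width = 1) {
  doc_add(doc, list(type = "circle", cx = cx, cy = cy, r = r, fill = fill,
                    stroke = stroke, stroke_width = stroke_width))
}

doc_text <- function(doc, x, y, text, size = 11, anchor = "start",
                     fill = "#000000", rotate = 0) {
  doc_add(doc, list(type = "text", x = x, y = y, text = text, size = size,
                    anchor = anchor, fill = fill, rotate = rotate))
}

# merge child document into parent at an offset
doc_place <- function(parent, child, dx, dy) {
  for (el in child$elements) {
    el <- shift_element(el, dx, dy)
    parent <- doc_add(parent, el)
  }
  parent
}

shift_element <- function(el, dx, dy) {
  switch(el$type,
    rect = { el$x <- el$x + dx; el$y <- el$y + dy; el },
    line = { el$x1 <- el$x1 + dx; el$x2 <- el$x2 + dx
             el$y1 <- el$y1 + dy; el$y2 <- el$y2 + dy; el },
    polyline = { el$xs <- el$xs + dx; el$ys <- el$ys + dy; el },
    circle = { el$cx <- el$cx + dx; el$cy <- el$cy + dy; el },
    text = { el$x <- el$x + dx; el$y <- el$y + dy; el },
    stop("unknown element type '", el$type, "'")
  )
}

num <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialize a document to SVG
#'
#' @param doc A rendered document.
#' @return A single character string: a standalone SVG, byte-identical for
#'   identical input.
#' @export
svg_serialize <- function(doc) {
  stopifnot(inherits(doc, "trace_document"))
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
                   "height=\"%s\" viewBox=\"0 0 %s %s\">"),
            num(doc$width), num(doc$height), num(doc$width), num(doc$height)),
    vapply(doc$elements, svg_element, character(1L)),
    "</svg>"
  )
  paste0(paste(out, collapse = "\n"), "\n")
}

svg_element <- function(el) {
  switch(el$type,
    rect = sprintf(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
      num(el$x), num(el$y), num(el$w), num(el$h), el$fill, el$stroke,
      num(el$stroke_width)),
    line = sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
      num(el$x1), num(el$y1), num(el$x2), num(el$y2), el$stroke,
      num(el$stroke_width)),
    polyline = sprintf(
      "<polyline points=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"/>",
      paste(paste(num(el$xs), num(el$ys), sep = ","), collapse = " "),
      el$stroke, num(el$stroke_width)),
    circle = sprintf(
      "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
      num(el$cx), num(el$cy), num(el$r), el$fill, el$stroke,
      num(el$stroke_width)),
    text = sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"%s\" font-family=\"Helvetica, Arial, sans-serif\" text-anchor=\"%s\" fill=\"%s\"%s>%s</text>",
      num(el$x), num(el$y), num(el$size), el$anchor, el$fill,
      if (el$rotate != 0) sprintf(" transform=\"rotate(%s %s %s)\"",
                                  num(el$rotate), num(el$x), num(el$y)) else "",
      xml_escape(el$text)),
    stop("unknown element type '", el$type, "'")
  )
}

#' Export a document as SVG or PNG
#'
#' SVG output is byte-stable across runs for identical input; PNG is
#' rasterized from the same primitive list at a configurable resolution.
#'
#' @param doc A rendered document.
#' @param path Output file path.
#' @param format `"svg"` or `"png"`; defaults to the file extension.
#' @param dpi Raster resolution for PNG (canvas units are taken as 1/96").
#' @return `path`, invisibly.
#' @export
export_figure <- function(doc, path, format = tools::file_ext(path), dpi = 96) {
  stopifnot(inherits(doc, "trace_document"))
  format <- tolower(format)
  if (identical(format, "svg")) {
    con <- file(path, open = "wb")  # binary: no platform newline translation
    on.exit(close(con))
    writeChar(svg_serialize(doc), con, eos = NULL)
  } else if (identical(format, "png")) {
    scale <- dpi / 96
    grDevices::png(path, width = round(doc$width * scale),
                   height = round(doc$height * scale))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, doc$width), ylim = c(doc$height, 0))
    for (el in doc$elements) draw_element_base(el)
  } else {
    stop("unsupported export format '", format, "' (use svg or png)")
  }
  invisible(path)
}

draw_element_base <- function(el) {
  col_or_na <- function(x) if (identical(x, "none")) NA else x
  switch(el$type,
    rect = graphics::rect(el$x, el$y + el$h, el$x + el$w, el$y,
                          col = col_or_na(el$fill),
                          border = col_or_na(el$stroke),
                          lwd = el$stroke_width),
    line = graphics::segments(el$x1, el$y1, el$x2, el$y2,
                              col = el$stroke, lwd = el$stroke_width),
    polyline = graphics::lines(el$xs, el$ys, col = el$stroke,
                               lwd = el$stroke_width),
    circle = graphics::symbols(el$cx, el$cy, circles = el$r, inches = FALSE,
                               add = TRUE, fg = col_or_na(el$stroke),
                               bg = col_or_na(el$fill)),
    text = graphics::text(el$x, el$y, el$text,
                          adj = switch(el$anchor, start = 0, middle = 0.5,
                                       end = 1),
                          cex = el$size / 12, col = el$fill,
                          srt = -el$rotate)
  )
}
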