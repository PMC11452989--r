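#' Write a pagoda render model as SVG
#'
#' Emits deterministic SVG 1.1: identical models give byte-identical
#' files (stable element order, ids and number formatting). Layers are
#' stacked rows of blocks, widest row at the bottom, centred like the
#' pagoda. Each block is split into a coloured rectangle of width
#' `fraction x block width` and, when the fraction is below 1, a
#' lighter-hued rectangle covering the remainder; the two widths always
#' sum to the block width. The energy label is a bar at the foot filled
#' per [energy_label_state()]. Every layer group carries its colour
#' fraction as a `data-fraction` attribute so the model can be
#' back-parsed with [read_svg_fractions()].
#'
#' @param model A `pagoda_render_model` from [render_model()].
#' @param path Output path.
#' @param geometry List of geometry knobs: `block_w`, `block_h`, `gap`,
#'   `margin`, `label_h` (pixels).
#' @return `path`, invisibly.
#' @export
write_svg <- function(model, path,
                      geometry = list(block_w = 48, block_h = 26,
                                      gap = 6, margin = 24,
                                      label_h = 30)) {
  stopifnot(inherits(model, "pagoda_render_model"))
  g <- geometry
  lay <- model$layers
  n <- nrow(lay)
  max_blocks <- max(lay$block_count)
  width <- 2 * g$margin + max_blocks * g$block_w + (ceiling(max_blocks) - 1) * g$gap
  height <- 2 * g$margin + 30 + n * (g$block_h + g$gap) + g$label_h + g$gap
  num <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(width), num(height), num(width), num(height)),
    sprintf('<title>%s</title>', xml_escape(model$title)),
    sprintf('<text x="%s" y="%s" font-size="16" text-anchor="middle">%s</text>',
            num(width / 2), num(g$margin), xml_escape(model$title))
  )
  # draw top layer of the model first (narrow top, wide base)
  for (i in seq_len(n)) {
    l <- lay[i, ]
    y <- g$margin + 30 + (i - 1) * (g$block_h + g$gap)
    row_w <- l$block_count * g$block_w +
      (ceiling(l$block_count) - 1) * g$gap
    x0 <- (width - row_w) / 2
    fill <- color_hex(l$base_color)
    blocks <- character(0)
    remaining <- l$block_count
    b <- 0
    while (remaining > 1e-9) {
      bw <- min(1, remaining) * g$block_w
      x <- x0 + b * (g$block_w + g$gap)
      cw <- bw * l$color_fraction
      blocks <- c(blocks, sprintf(
        '<rect class="colored" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        num(x), num(y), num(cw), num(g$block_h), fill))
      if (l$color_fraction < 1) {
        blocks <- c(blocks, sprintf(
          '<rect class="light" x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="0.25"/>',
          num(x + cw), num(y), num(bw - cw), num(g$block_h), fill))
      }
      remaining <- remaining - min(1, remaining)
      b <- b + 1
    }
    lines <- c(lines,
      sprintf('<g id="layer-%s" data-group="%s" data-points="%d" data-fraction="%s">',
              l$food_group, l$food_group, l$points,
              format(l$color_fraction, trim = TRUE)),
      blocks,
      '</g>')
  }
  # energy label bar
  e <- model$energy_label
  y <- g$margin + 30 + n * (g$block_h + g$gap) + g$gap
  bar_w <- width - 2 * g$margin
  label_fill <- c(dark = "#333333", gray = "#9e9e9e",
                  white = "#ffffff")[[e$fill_color]]
  lines <- c(lines,
    sprintf('<g id="energy-label" data-state="%s" data-fraction="%s">',
            e$state, format(e$fill_fraction, trim = TRUE)),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#333333"/>',
            num(g$margin), num(y), num(bar_w), num(g$label_h)),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#333333"/>',
            num(g$margin), num(y), num(bar_w * e$fill_fraction),
            num(g$label_h), label_fill),
    sprintf('<text x="%s" y="%s" font-size="12" text-anchor="middle">%s kcal / preset %s kcal (%s)</text>',
            num(width / 2), num(y + g$label_h + 14),
            format(round(e$diet_kcal), trim = TRUE),
            format(round(e$preset_kcal), trim = TRUE), e$state),
    '</g>',
    '</svg>')
  con <- file(path, open = "wb") # byte-stable newlines on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# fixed token -> hex lookup used by the writer; tokens themselves are the
# configurable surface
color_hex <- function(token) {
  map <- c(brown = "#8d5a2b", green = "#3e8e41", darkgreen = "#1e5e20",
           lightgreen = "#8bc34a", red = "#c0392b", orange = "#e67e22",
           blue = "#2980b9", lavender = "#b39ddb", khaki = "#bdb76b",
           tan = "#d2b48c", gold = "#d4af37", gray = "#9e9e9e")
  ifelse(token %in% names(map), unname(map[token]), token)
}

#' Back-parse layer colour fractions from a written SVG
#'
#' @param path An SVG file written by [write_svg()].
#' @return Named numeric vector: food group to colour fraction, in
#'   document order. The energy label's fill fraction is returned as
#'   attribute `energy_fill`.
#' @export
read_svg_fractions <- function(path) {
  doc <- xml2::read_xml(path)
  groups <- xml2::xml_find_all(doc, "//*[@data-group]")
  out <- stats::setNames(
    as.numeric(xml2::xml_attr(groups, "data-fraction")),
    xml2::xml_attr(groups, "data-group")
  )
  label <- xml2::xml_find_first(doc, "//*[@id='energy-label']")
  attr(out, "energy_fill") <- as.numeric(xml2::xml_attr(label,
                                                        "data-fraction"))
  out
}
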