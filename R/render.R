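#' Visual style settings for SVG rendering
#'
#' @param palette Named character vector mapping all six colour
#'   categories (`green`, `light_green`, `orange`, `light_red`, `red`,
#'   `grey`) to hex colours.
#' @param canvas Canvas edge length in pixels (plots are square).
#' @param font_family,font_size Label typography.
#' @param ring_stroke Stroke colour for rings and sector dividers.
#' @param legend Draw the impact-score legend?
#' @return An object of class `style_config`.
#' @export
style_config <- function(palette = default_palette(), canvas = 640,
                         font_family = "Helvetica", font_size = 12,
                         ring_stroke = "#888888", legend = TRUE) {
  needed <- c("green", "light_green", "orange", "light_red", "red", "grey")
  if (!all(needed %in% names(palette))) {
    stop_value(sprintf("palette must name all of: %s",
                       paste(needed, collapse = ", ")))
  }
  if (canvas <= 0) stop_value("canvas must be positive")
  structure(list(palette = palette[needed], canvas = canvas,
                 font_family = font_family, font_size = font_size,
                 ring_stroke = ring_stroke, legend = isTRUE(legend)),
            class = "style_config")
}

#' @rdname style_config
#' @export
default_palette <- function() {
  c(green = "#1a9641", light_green = "#a6d96a", orange = "#ff8c00",
    light_red = "#f4a582", red = "#d7191c", grey = "#bdbdbd")
}

mechanism_short <- c(
  equity_funds_discount_cards      = "Equity funds",
  tax_funded                       = "Tax-funded",
  private_health_insurance         = "Private HI",
  user_fees_implementation         = "Fees (impl.)",
  user_fees_removal                = "Fees (removal)",
  community_based_health_insurance = "CBHI",
  national_health_insurance        = "NHI"
)

fmt <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# SVG fragment for one scattar plot centred at (cx, cy). Pure string
# templating so identical inputs give byte-identical output.
scattar_group_svg <- function(layout, style, cx, cy, label_scale = 1) {
  g <- layout$geometry
  out <- character()
  emit <- function(...) out <<- c(out, sprintf(...))

  emit('<g class="scattar" data-country="%s" data-goal="%s">',
       layout$country, layout$goal)
  emit('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
       fmt(cx), fmt(cy), fmt(g$outer_radius), style$ring_stroke)
  emit('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
       fmt(cx), fmt(cy), fmt(g$inner_radius), style$ring_stroke)
  for (k in seq_len(nrow(layout$sectors))) {
    a <- layout$sectors$start[k]
    emit('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.75"/>',
         fmt(cx + g$inner_radius * sin(a)), fmt(cy - g$inner_radius * cos(a)),
         fmt(cx + g$outer_radius * sin(a)), fmt(cy - g$outer_radius * cos(a)),
         style$ring_stroke)
    if (label_scale > 0) {
      mid <- (layout$sectors$start[k] + layout$sectors$end[k]) / 2
      lr <- g$outer_radius + 14 * label_scale
      emit('<text x="%s" y="%s" text-anchor="middle" font-family="%s" font-size="%s">%s</text>',
           fmt(cx + lr * sin(mid)), fmt(cy - lr * cos(mid)),
           style$font_family, fmt(style$font_size * label_scale),
           xml_escape(mechanism_short[[layout$sectors$mechanism[k]]]))
    }
  }
  dots <- layout$dots
  half <- g$dot_diameter / 2
  for (i in seq_len(nrow(dots))) {
    r <- g$inner_radius + dots$radius_norm[i] * (g$outer_radius - g$inner_radius)
    x <- cx + r * sin(dots$angle[i])
    y <- cy - r * cos(dots$angle[i])
    fill <- style$palette[[dots$color[i]]]
    if (dots$shape[i] == "square") {
      emit(paste0('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" ',
                  'data-study-id="%s" data-mechanism="%s"/>'),
           fmt(x - half), fmt(y - half), fmt(g$dot_diameter),
           fmt(g$dot_diameter), fill, xml_escape(dots$study_id[i]),
           dots$mechanism[i])
    } else {
      emit(paste0('<circle cx="%s" cy="%s" r="%s" fill="%s" ',
                  'data-study-id="%s" data-mechanism="%s"/>'),
           fmt(x), fmt(y), fmt(half), fill, xml_escape(dots$study_id[i]),
           dots$mechanism[i])
    }
  }
  emit('</g>')
  out
}

legend_svg <- function(style, x, y) {
  out <- character()
  scores <- c("evidence_for", "some_evidence_for", "no_evidence_of_impact",
              "some_evidence_against", "evidence_against", "not_considered")
  for (i in seq_along(scores)) {
    yy <- y + (i - 1) * 16
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="10" height="10" fill="%s"/>',
              fmt(x), fmt(yy), style$palette[[dot_color(scores[i])]]),
      sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s">%s</text>',
              fmt(x + 14), fmt(yy + 9), style$font_family,
              fmt(style$font_size * 0.85), xml_escape(impact_labels[[scores[i]]])))
  }
  c('<g class="legend">', out, '</g>')
}

#' Render one scattar layout to an SVG document
#'
#' Emits the inner and outer rings, the 7 labelled mechanism sectors
#' and one marker element per dot — `<rect>` for review squares,
#' `<circle>` for evaluation dots — each carrying its `study_id` in a
#' `data-study-id` attribute so a downstream renderer can attach
#' hover/click behaviour. Output is deterministic: identical inputs
#' give byte-identical documents.
#'
#' @param layout A [layout_scattar()] result.
#' @param style A [style_config()].
#' @param path Optional output path.
#' @return The SVG document as a single string (invisibly if written
#'   to `path`).
#' @export
render_svg <- function(layout, style = style_config(), path = NULL) {
  w <- style$canvas
  cx <- w / 2
  cy <- w / 2 + style$font_size  # headroom for the title
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            w, w + 2 * style$font_size, w, w + 2 * style$font_size),
    sprintf('<rect width="100%%" height="100%%" fill="#ffffff"/>'),
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-family="%s" font-size="%s" font-weight="bold">%s</text>',
            fmt(cx), fmt(style$font_size + 4), style$font_family,
            fmt(style$font_size * 1.2),
            xml_escape(sprintf("%s — %s", layout$country,
                               goal_labels[[layout$goal]]))),
    scattar_group_svg(layout, style, cx, cy))
  if (style$legend) out <- c(out, legend_svg(style, 8, 28))
  out <- c(out, '</svg>')
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Render the main plot with its five goal thumbnails
#'
#' The composite page mirrors the tool's main display: the chosen
#' goal's plot on top and small thumbnails of all five goals in a row
#' beneath it, giving an immediate visual impression of how the
#' distribution of evidence shifts between goals. Thumbnails share the
#' main plot's dot positions and counts; only colours differ.
#'
#' @param main A [layout_scattar()] result for the chosen goal.
#' @param thumbs The list of five per-goal layouts from
#'   [layout_thumbnails()]; must cover all five goals for the same
#'   country.
#' @param style A [style_config()].
#' @param path Optional output path.
#' @return The SVG document as a single string (invisibly if written
#'   to `path`).
#' @export
render_page <- function(main, thumbs, style = style_config(), path = NULL) {
  if (!setequal(names(thumbs), goal_levels())) {
    stop_usage("thumbs must be a named list covering all 5 goals")
  }
  if (!all(vapply(thumbs, function(t) t$country == main$country, logical(1)))) {
    stop_usage("thumbnails must be for the same country as the main plot")
  }
  w <- style$canvas
  scale <- 0.17
  thumb_h <- w * scale + 24
  h <- w + 2 * style$font_size + thumb_h
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            w, h, w, h),
    '<rect width="100%" height="100%" fill="#ffffff"/>',
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-family="%s" font-size="%s" font-weight="bold">%s</text>',
            fmt(w / 2), fmt(style$font_size + 4), style$font_family,
            fmt(style$font_size * 1.2),
            xml_escape(sprintf("%s — %s", main$country,
                               goal_labels[[main$goal]]))),
    sprintf('<g class="main">'),
    scattar_group_svg(main, style, w / 2, w / 2 + style$font_size),
    '</g>')
  if (style$legend) out <- c(out, legend_svg(style, 8, 28))
  slot <- w / 5
  for (i in seq_along(goal_levels())) {
    g <- goal_levels()[i]
    tx <- (i - 1) * slot + slot / 2
    ty <- w + 2 * style$font_size + 8
    out <- c(out,
      sprintf('<g class="thumbnail" data-goal="%s" transform="translate(%s,%s) scale(%s)">',
              g, fmt(tx), fmt(ty + slot * scale * 1.1), fmt(scale)),
      scattar_group_svg(thumbs[[g]], style, 0, 0, label_scale = 0),
      '</g>',
      sprintf('<text x="%s" y="%s" text-anchor="middle" font-family="%s" font-size="%s">%s</text>',
              fmt(tx), fmt(h - 6), style$font_family,
              fmt(style$font_size * 0.85), xml_escape(goal_labels[[g]])))
  }
  out <- c(out, '</svg>')
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
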