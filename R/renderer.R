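# Semantic-zoom visibility and SVG / PNG emission. SVG is generated as text
# with fixed numeric formatting, so identical input yields identical bytes.
# PNG rasterization re-draws the SVG primitives on a cairo bitmap device.

# does this enzyme label have a time-series grid occupying its space?
replaced_by_grid <- function(lay, uid) {
  for (g in lay$glyphs)
    if (g$kind == "omics-grid" && identical(g$parent_uid, uid))
      return(TRUE)
  FALSE
}

#' Resolve which elements are visible at a zoom level
#'
#' Metabolite nodes and edges are always included (subject to style
#' toggles); a label of kind `k` is included iff `zoom >= policy[k]` and its
#' style toggle is on (thresholds are inclusive); omics grids are included
#' iff `show_omics`; enzyme labels whose space is occupied by a gene
#' expression grid are hidden while `show_omics` is on. Inclusion is
#' monotone non-decreasing in zoom.
#'
#' @param collage A `pc_collage`.
#' @param zoom Positive zoom factor.
#' @param policy A [zoom_policy()].
#' @param style A [style_config()]; defaults to the collage's own style.
#' @return Character vector of visible glyph and edge uids.
#' @export
visible_elements <- function(collage, zoom, policy = zoom_policy(),
                             style = collage$style) {
  if (!is.numeric(zoom) || zoom <= 0) stop_user("zoom must be > 0")
  vis <- character()
  for (pl in collage$layouts) {
    lay <- pl$layout
    for (g in lay$glyphs) {
      show <- switch(g$kind,
        "metabolite-node" = TRUE,
        "pathway-box" = style$show_pathway_boxes,
        "pathway-label" = style$show_pathway_labels &&
          zoom >= policy[["pathway-label"]],
        "enzyme-label" = style$show_enzyme_labels &&
          zoom >= policy[["enzyme-label"]] &&
          !(style$show_omics && replaced_by_grid(lay, g$uid)),
        "gene-label" = style$show_enzyme_labels &&
          zoom >= policy[["gene-label"]],
        "omics-grid" = style$show_omics,
        "omics-box" = style$show_omics,
        FALSE)
      if (show && g$visible) vis <- c(vis, g$uid)
    }
    for (e in lay$edges) vis <- c(vis, e$uid)
  }
  if (style$show_connections)
    vis <- c(vis, vapply(collage$connections, function(e) e$uid, ""))
  unname(vis)
}

fmt <- function(x) sprintf("%.3f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

arrow_head <- function(tip, dirv, size) {
  # triangle polygon at `tip` pointing along dirv
  left <- c(-dirv[2], dirv[1])
  p1 <- tip
  p2 <- tip - dirv * size + left * size * 0.45
  p3 <- tip - dirv * size - left * size * 0.45
  sprintf('<polygon points="%s,%s %s,%s %s,%s"',
          fmt(p1[1]), fmt(p1[2]), fmt(p2[1]), fmt(p2[2]),
          fmt(p3[1]), fmt(p3[2]))
}

#' Render a collage to an SVG document
#'
#' One SVG group per visible glyph/edge, tagged with `role` ("glyph" or
#' "edge") and `data-uid` attributes. Coordinates are
#' `(layout coordinate + offset) * zoom`; the canvas is the collage
#' bounding box scaled by zoom plus a margin. Output is byte-deterministic
#' for identical input.
#'
#' @param collage A `pc_collage`.
#' @param zoom Positive zoom factor.
#' @param policy A [zoom_policy()].
#' @param style A [style_config()].
#' @param margin Canvas margin in output units.
#' @return A single SVG string (class `pc_svg`).
#' @export
render_svg <- function(collage, zoom = 1, policy = zoom_policy(),
                       style = collage$style, margin = 10) {
  vis <- visible_elements(collage, zoom, policy, style)
  bb <- collage_bbox(collage)
  w <- (bb[3] - bb[1]) * zoom + 2 * margin
  h <- (bb[4] - bb[2]) * zoom + 2 * margin
  tx <- function(p) c((p[1] - bb[1]) * zoom + margin,
                      (p[2] - bb[2]) * zoom + margin)

  # absolute glyph records for endpoint lookup
  abs_glyphs <- list()
  for (pl in collage$layouts) {
    for (g in pl$layout$glyphs) {
      g$x <- g$x + pl$offset[1]; g$y <- g$y + pl$offset[2]
      abs_glyphs[[g$uid]] <- g
    }
  }

  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   fmt(w), fmt(h), fmt(w), fmt(h)))

  emit_edge <- function(e) {
    s <- abs_glyphs[[e$source_uid]]; t <- abs_glyphs[[e$target_uid]]
    if (is.null(s) || is.null(t)) return(character())
    a <- tx(glyph_center(s)); b <- tx(glyph_center(t))
    col <- e$overlay_color %||% e$color
    th <- e$thickness * zoom
    body <- if (isTRUE(e$curved)) {
      mid <- (a + b) / 2
      v <- b - a; nv <- sqrt(sum(v^2)); if (nv < 1e-9) nv <- 1
      ctrl <- mid + c(-v[2], v[1]) / nv * 12 * zoom
      sprintf('<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s"/>',
              fmt(a[1]), fmt(a[2]), fmt(ctrl[1]), fmt(ctrl[2]),
              fmt(b[1]), fmt(b[2]), col, fmt(th))
    } else {
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
              fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]), col, fmt(th))
    }
    heads <- character()
    v <- b - a; nv <- sqrt(sum(v^2))
    if (nv > 1e-9 && e$arrow != "none") {
      dirv <- v / nv; sz <- 6 * zoom
      heads <- sprintf('%s fill="%s"/>', arrow_head(b, dirv, sz), col)
      if (e$arrow == "both")
        heads <- c(heads, sprintf('%s fill="%s"/>',
                                  arrow_head(a, -dirv, sz), col))
    }
    c(sprintf('<g role="edge" data-uid="%s">', xml_escape(e$uid)),
      body, heads, "</g>")
  }

  emit_glyph <- function(g) {
    p <- tx(c(g$x, g$y))
    gw <- g$width * zoom; gh <- g$height * zoom
    col <- g$overlay_color %||% g$color
    inner <- character()
    if (g$kind == "metabolite-node") {
      c0 <- tx(glyph_center(g))
      inner <- sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                       fmt(c0[1]), fmt(c0[2]), fmt(gw / 2), col)
      if (zoom >= policy[["metabolite-label"]] && nzchar(g$label_text)) {
        fs <- style$font_sizes[["metabolite-label"]] * zoom
        inner <- c(inner, sprintf(
          '<text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
          fmt(c0[1]), fmt(p[2] + gh + fs), fmt(fs),
          xml_escape(g$label_text)))
      }
    } else if (g$kind %in% c("pathway-box", "omics-box", "omics-grid")) {
      stroke <- if (g$kind == "pathway-box") "#cccccc" else "#666666"
      fill <- if (g$kind == "omics-grid") "none" else col
      inner <- sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
                       fmt(p[1]), fmt(p[2]), fmt(gw), fmt(gh), fill,
                       stroke, fmt(0.5 * zoom))
    } else {  # text labels
      fs <- style$font_sizes[[g$kind]] * zoom
      inner <- sprintf('<text x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="%s">%s</text>',
                       fmt(p[1]), fmt(p[2] + fs), fmt(fs), col,
                       xml_escape(g$label_text))
    }
    c(sprintf('<g role="glyph" data-uid="%s">', xml_escape(g$uid)),
      inner, "</g>")
  }

  # draw order: boxes (background), edges, connections, nodes/grids, labels
  vset <- vis
  ordered <- list()
  kinds_order <- list(c("pathway-box"),
                      NULL,  # edges slot
                      c("metabolite-node", "omics-grid", "omics-box"),
                      c("pathway-label", "enzyme-label", "gene-label"))
  for (g in abs_glyphs) if (g$uid %in% vset && g$kind == "pathway-box")
    out <- c(out, emit_glyph(g))
  for (pl in collage$layouts) for (e in pl$layout$edges)
    if (e$uid %in% vset) out <- c(out, emit_edge(e))
  for (e in collage$connections) if (e$uid %in% vset)
    out <- c(out, emit_edge(e))
  for (g in abs_glyphs) if (g$uid %in% vset &&
                            g$kind %in% kinds_order[[3]])
    out <- c(out, emit_glyph(g))
  for (g in abs_glyphs) if (g$uid %in% vset &&
                            g$kind %in% kinds_order[[4]])
    out <- c(out, emit_glyph(g))
  out <- c(out, "</svg>")
  structure(paste(out, collapse = "\n"), class = "pc_svg")
}

#' Rasterize an SVG document to a PNG file
#'
#' Raster dimensions are `ceiling(canvas * scale)`, uniformly downscaled to
#' preserve aspect ratio if either dimension would exceed `max_dim`.
#'
#' @param svg An SVG string produced by [render_svg()].
#' @param path Output PNG path.
#' @param scale Positive scale factor (canvas units to pixels).
#' @param max_dim Maximum dimension in pixels (default 8192).
#' @return Invisibly, `path`.
#' @export
export_png <- function(svg, path, scale = 1, max_dim = 8192) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop_user("scale must be a positive number")
  if (!is.numeric(max_dim) || max_dim < 1)
    stop_user("max_dim must be a positive integer")
  doc <- xml2::read_xml(as.character(svg))
  w <- as.numeric(xml2::xml_attr(doc, "width"))
  h <- as.numeric(xml2::xml_attr(doc, "height"))
  dims <- ceiling(c(w, h) * scale)
  if (max(dims) > max_dim) dims <- pmax(1, floor(dims * max_dim / max(dims)))

  grDevices::png(path, width = dims[1], height = dims[2], type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, max(w, 1)), ylim = c(max(h, 1), 0))
  draw_node <- function(nd) {
    tag <- xml2::xml_name(nd)
    at <- function(a, def = NA_character_) {
      v <- xml2::xml_attr(nd, a)
      if (is.na(v)) def else v
    }
    num <- function(a) suppressWarnings(as.numeric(at(a)))
    if (tag == "g") {
      for (ch in xml2::xml_children(nd)) draw_node(ch)
    } else if (tag == "rect") {
      fill <- at("fill"); if (identical(fill, "none")) fill <- NA
      graphics::rect(num("x"), num("y") + num("height"),
                     num("x") + num("width"), num("y"),
                     col = fill, border = at("stroke"))
    } else if (tag == "circle") {
      graphics::symbols(num("cx"), num("cy"), circles = num("r"),
                        inches = FALSE, add = TRUE, fg = at("fill"),
                        bg = at("fill"))
    } else if (tag == "line") {
      graphics::segments(num("x1"), num("y1"), num("x2"), num("y2"),
                         col = at("stroke"),
                         lwd = max(0.5, num("stroke-width")))
    } else if (tag == "path") {
      d <- at("d")
      m <- regmatches(d, gregexpr("-?[0-9.]+", d))[[1]]
      v <- as.numeric(m)
      if (length(v) >= 6) {
        tt <- seq(0, 1, length.out = 24)
        bx <- (1 - tt)^2 * v[1] + 2 * (1 - tt) * tt * v[3] + tt^2 * v[5]
        by <- (1 - tt)^2 * v[2] + 2 * (1 - tt) * tt * v[4] + tt^2 * v[6]
        graphics::lines(bx, by, col = at("stroke"),
                        lwd = max(0.5, num("stroke-width")))
      }
    } else if (tag == "polygon") {
      pts <- as.numeric(strsplit(gsub(",", " ", at("points")), "\\s+")[[1]])
      graphics::polygon(pts[c(TRUE, FALSE)], pts[c(FALSE, TRUE)],
                        col = at("fill"), border = NA)
    } else if (tag == "text") {
      fs <- num("font-size")
      adj <- if (identical(at("text-anchor"), "middle")) c(0.5, 0) else c(0, 0)
      graphics::text(num("x"), num("y"), xml2::xml_text(nd),
                     col = at("fill", "#000000"),
                     cex = max(0.2, fs / 12), adj = adj)
    }
  }
  for (ch in xml2::xml_children(doc)) draw_node(ch)
  invisible(path)
}

#' @export
print.pc_svg <- function(x, ...) {
  cat(sprintf("<SVG document, %d bytes>\n", nchar(x)))
  invisible(x)
}

#' @export
print.pc_collage <- function(x, ...) {
  ng <- sum(vapply(x$layouts, function(pl) length(pl$layout$glyphs), 1L))
  ne <- sum(vapply(x$layouts, function(pl) length(pl$layout$edges), 1L))
  cat(sprintf(
    "pathway collage: %d pathways, %d glyphs, %d edges, %d connections%s\n",
    length(x$layouts), ng, ne, length(x$connections),
    if (!is.null(x$omics)) sprintf(" [%s %s overlay]", x$omics$mode,
                                   x$omics$dataset$data_type) else ""))
  invisible(x)
}
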