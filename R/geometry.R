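# Rectangle and bbox helpers. All geometry is in screen coordinates:
# origin top-left, y increases downward, real-valued layout units.
# Glyph position = top-left corner of its rectangle.

#' Layout geometry constants
#'
#' Every geometric constant used by the layout engine, in one place.
#' Node spacing along a backbone is three node diameters; the circle radius
#' for a cyclic pathway of n reactions is `spacing * n / (2 * pi)` so that
#' arc length between adjacent backbone nodes equals the linear spacing.
#'
#' @param node_diameter Metabolite node diameter (layout units).
#' @param spacing Backbone node spacing (center to center).
#' @param arm_dx Horizontal offset between branch columns.
#' @param label_gap Gap between an edge and its labels.
#' @param char_width_factor Label width is estimated as
#'   `nchar(text) * char_width_factor * font_size` (font-metric free).
#' @param box_pad Padding between pathway content and its background box.
#' @param side_offset Perpendicular offset for side-metabolite nodes.
#' @param omics_box_w,omics_box_h Size of one time-series omics box.
#' @return A list of class `pc_layout_config`.
#' @export
layout_config <- function(node_diameter = 12,
                          spacing = 3 * node_diameter,
                          arm_dx = 6 * node_diameter,
                          label_gap = 4,
                          char_width_factor = 0.6,
                          box_pad = 10,
                          side_offset = 20,
                          omics_box_w = 10,
                          omics_box_h = 8) {
  structure(list(node_diameter = node_diameter, spacing = spacing,
                 arm_dx = arm_dx, label_gap = label_gap,
                 char_width_factor = char_width_factor, box_pad = box_pad,
                 side_offset = side_offset, omics_box_w = omics_box_w,
                 omics_box_h = omics_box_h),
            class = "pc_layout_config")
}

glyph_rect <- function(g) c(g$x, g$y, g$x + g$width, g$y + g$height)

glyph_center <- function(g) c(g$x + g$width / 2, g$y + g$height / 2)

# strict interior overlap: rectangles sharing only an edge do not overlap
rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

rect_union <- function(rects) {
  if (length(rects) == 0) return(c(0, 0, 0, 0))
  m <- do.call(rbind, rects)
  c(min(m[, 1]), min(m[, 2]), max(m[, 3]), max(m[, 4]))
}

# Glyph kinds that are containers/backgrounds by design: they enclose other
# glyphs, so they are exempt from pairwise overlap-freedom.
container_kinds <- c("pathway-box", "omics-grid", "omics-box")

#' Bounding box of a pathway layout
#'
#' Recomputed from the glyphs so it stays correct after edits.
#'
#' @param layout A `pc_layout`.
#' @return Numeric vector `c(min_x, min_y, max_x, max_y)`.
#' @export
layout_bbox <- function(layout) {
  rect_union(lapply(layout$glyphs, glyph_rect))
}

# Greedy deterministic overlap resolution: each glyph in `uids` (processed in
# the given order) slides along its `dir` unit vector in small steps until its
# rectangle is disjoint from every rectangle in `fixed` and every previously
# placed glyph. Terminates because sliding is monotone away from a bounded set.
resolve_overlaps <- function(glyphs, uids, dirs, fixed_rects, step = 2) {
  placed <- fixed_rects
  for (i in seq_along(uids)) {
    uid <- uids[[i]]
    g <- glyphs[[uid]]
    dir <- dirs[[i]]
    guard <- 0L
    repeat {
      r <- glyph_rect(g)
      hit <- any(vapply(placed, function(p) rects_overlap(r, p), TRUE))
      if (!hit || guard > 10000L) break
      g$x <- g$x + dir[1] * step
      g$y <- g$y + dir[2] * step
      guard <- guard + 1L
    }
    glyphs[[uid]] <- g
    placed[[length(placed) + 1L]] <- glyph_rect(g)
  }
  glyphs
}

est_text_width <- function(text, font_size, config) {
  max(1, nchar(text)) * config$char_width_factor * font_size
}
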