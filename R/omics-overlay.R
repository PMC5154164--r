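# Omics overlays: single-value coloring of matched elements, or time-series
# grids of colored boxes. Values are displayed as given (no normalization),
# and the pathway layout is never recomputed to accommodate the overlay.

#' Map a value to a display color
#'
#' Half-open binning: `NA` maps to the scheme's `missing_color`; a value
#' below the first breakpoint to `colors[1]`; a value in
#' `[breakpoints[i], breakpoints[i+1])` to `colors[i+1]`; a value at or
#' above the last breakpoint to the last color. A value exactly equal to a
#' breakpoint falls in the bin whose lower bound it is.
#'
#' @param value Numeric value or `NA`.
#' @param scheme A [color_scheme()].
#' @return A color string.
#' @export
color_for <- function(value, scheme) {
  if (is.null(value) || length(value) == 0 || is.na(value))
    return(scheme$missing_color)
  scheme$colors[findInterval(value, scheme$breakpoints) + 1]
}

#' Match omics dataset rows to collage elements
#'
#' Exact, case-sensitive id matching: gene rows match reaction `gene_ids`
#' (targets: the reaction's enzyme-label glyph and its primary reaction
#' edge), metabolite rows match compound ids (targets: every metabolite-node
#' occurrence), flux rows match reaction ids (targets: primary reaction
#' edges). Rows matching nothing are reported in the coverage summary.
#'
#' @param collage A `pc_collage`.
#' @param dataset An [omics_dataset()].
#' @return List with `matches` (named list: entity id -> uids) and
#'   `unmatched` (entity ids with no target).
#' @export
match_entities <- function(collage, dataset) {
  ids <- names(dataset$rows)
  matches <- setNames(vector("list", length(ids)), ids)
  for (pl in collage$layouts) {
    lay <- pl$layout
    if (dataset$data_type == "metabolite") {
      for (g in lay$glyphs) {
        if (g$kind == "metabolite-node" && g$ref_id %in% ids)
          matches[[g$ref_id]] <- c(matches[[g$ref_id]], g$uid)
      }
    } else {
      for (rid in names(lay$reaction_info)) {
        info <- lay$reaction_info[[rid]]
        enz_uid <- sprintf("%s::enz::%s", lay$pathway_id, rid)
        edge_uid <- sprintf("%s::rxn::%s", lay$pathway_id, rid)
        has_enz <- !is.null(lay$glyphs[[enz_uid]])
        has_edge <- !is.null(lay$edges[[edge_uid]])
        if (dataset$data_type == "gene") {
          for (gid in intersect(info$gene_ids, ids)) {
            tg <- c(if (has_enz) enz_uid, if (has_edge) edge_uid)
            matches[[gid]] <- c(matches[[gid]], tg)
          }
        } else if (dataset$data_type == "flux" && rid %in% ids && has_edge) {
          matches[[rid]] <- c(matches[[rid]], edge_uid)
        }
      }
    }
  }
  hit <- vapply(matches, function(x) length(x) > 0, TRUE)
  list(matches = matches[hit], unmatched = ids[!hit])
}

# strip any previous overlay: grids and boxes removed, overlay colors
# dropped, attached omics metadata cleared
clear_overlay <- function(collage) {
  for (j in seq_along(collage$layouts)) {
    lay <- collage$layouts[[j]]$layout
    grids <- names(Filter(function(g)
      g$kind %in% c("omics-grid", "omics-box"), lay$glyphs))
    lay$glyphs[grids] <- NULL
    for (u in names(lay$glyphs)) lay$glyphs[[u]]$overlay_color <- NULL
    for (u in names(lay$edges)) lay$edges[[u]]$overlay_color <- NULL
    lay$bbox <- layout_bbox(lay)
    collage$layouts[[j]]$layout <- lay
  }
  for (u in names(collage$connections))
    collage$connections[[u]]$overlay_color <- NULL
  collage$omics <- NULL
  collage
}

coverage_of <- function(m) {
  list(matched = sort(names(m$matches)), unmatched = sort(m$unmatched))
}

#' Apply a single-value omics overlay
#'
#' Colors every matched glyph/edge by the bin rule of the scheme; any
#' previous overlay is cleared first. Unmatched elements keep their default
#' colors. Overlay colors live in a separate slot, so highlights survive.
#'
#' @param collage A `pc_collage`.
#' @param dataset An [omics_dataset()] with exactly one column.
#' @param scheme A [color_scheme()].
#' @return The updated collage, with `collage$omics` holding the dataset,
#'   scheme, mode and coverage summary.
#' @export
apply_single_overlay <- function(collage, dataset, scheme) {
  if (length(dataset$columns) != 1)
    stop_user(paste("dataset has %d columns: use apply_timeseries_overlay()",
                    "for multi-column data"), length(dataset$columns))
  collage <- clear_overlay(collage)
  m <- match_entities(collage, dataset)
  for (id in names(m$matches)) {
    col <- color_for(dataset$rows[[id]][1], scheme)
    for (uid in m$matches[[id]]) {
      i <- glyph_layout_index(collage, uid)
      if (!is.na(i)) {
        collage$layouts[[i]]$layout$glyphs[[uid]]$overlay_color <- col
      } else {
        i <- edge_layout_index(collage, uid)
        if (!is.na(i))
          collage$layouts[[i]]$layout$edges[[uid]]$overlay_color <- col
      }
    }
  }
  collage$omics <- list(dataset = dataset, scheme = scheme, mode = "single",
                        coverage = coverage_of(m))
  collage
}

#' Apply a time-series omics overlay
#'
#' For each matched entity occurrence, creates one omics-grid glyph holding
#' exactly one colored box per dataset column, in a single row ordered
#' left-to-right by column (the leftmost box is the first condition).
#' Placement: metabolite data below the metabolite node; gene expression
#' data at the enzyme label's position, with the enzyme label hidden while
#' `show_omics` is on (the boxes occupy the space formerly used by the
#' enzyme name); flux data beside the reaction edge midpoint. Grids are
#' attached glyphs and can be repositioned with [move_node()]. Any previous
#' overlay is cleared first.
#'
#' @param collage A `pc_collage`.
#' @param dataset An [omics_dataset()] with at least two columns.
#' @param scheme A [color_scheme()].
#' @param config A [layout_config()] (box sizes).
#' @return The updated collage.
#' @export
apply_timeseries_overlay <- function(collage, dataset, scheme,
                                     config = layout_config()) {
  if (length(dataset$columns) < 2)
    stop_user(paste("dataset has 1 column: use apply_single_overlay()",
                    "for single-value data"))
  collage <- clear_overlay(collage)
  m <- match_entities(collage, dataset)
  bw <- config$omics_box_w; bh <- config$omics_box_h
  nc <- length(dataset$columns)

  place_grid <- function(collage, entity_id, anchor_uid, x, y, lay_i,
                         parent = NULL) {
    guid <- sprintf("%s::grid::%s", anchor_uid, entity_id)
    lay <- collage$layouts[[lay_i]]$layout
    lay$glyphs[[guid]] <- make_glyph(guid, "omics-grid", ref_id = entity_id,
                                     x = x, y = y, width = nc * bw,
                                     height = bh,
                                     color = collage$style$colors[["omics-grid"]],
                                     parent_uid = parent)
    vals <- dataset$rows[[entity_id]]
    for (k in seq_len(nc)) {
      buid <- sprintf("%s::box%d", guid, k)
      lay$glyphs[[buid]] <- make_glyph(buid, "omics-box",
                                       ref_id = entity_id,
                                       x = x + (k - 1) * bw, y = y,
                                       width = bw, height = bh,
                                       color = color_for(vals[k], scheme),
                                       parent_uid = guid)
    }
    collage$layouts[[lay_i]]$layout <- lay
    collage
  }

  for (id in names(m$matches)) {
    for (uid in m$matches[[id]]) {
      gi <- glyph_layout_index(collage, uid)
      if (!is.na(gi)) {
        g <- collage$layouts[[gi]]$layout$glyphs[[uid]]
        if (dataset$data_type == "metabolite" &&
            g$kind == "metabolite-node") {
          ctr <- glyph_center(g)
          collage <- place_grid(collage, id, uid, ctr[1] - nc * bw / 2,
                                g$y + g$height + 2, gi, parent = uid)
        } else if (dataset$data_type == "gene" &&
                   g$kind == "enzyme-label") {
          collage <- place_grid(collage, id, uid, g$x, g$y, gi,
                                parent = uid)
        }
      } else if (dataset$data_type == "flux") {
        ei <- edge_layout_index(collage, uid)
        if (is.na(ei)) next
        e <- collage$layouts[[ei]]$layout$edges[[uid]]
        pl <- collage$layouts[[ei]]
        a <- abs_center(collage, e$source_uid)
        b <- abs_center(collage, e$target_uid)
        mid <- (a + b) / 2 - pl$offset  # back to layout-local coordinates
        collage <- place_grid(collage, id, uid,
                              mid[1] + config$node_diameter / 2 +
                                config$label_gap,
                              mid[2] + 2, ei)
      }
    }
  }
  for (j in seq_along(collage$layouts))
    collage$layouts[[j]]$layout$bbox <-
      layout_bbox(collage$layouts[[j]]$layout)
  collage$omics <- list(dataset = dataset, scheme = scheme,
                        mode = "timeseries", coverage = coverage_of(m))
  collage
}

#' Read a color scheme from a JSON file
#'
#' Expected shape: `{"breakpoints": [...], "colors": [...],
#' "missing_color": "#rrggbb"}`.
#'
#' @param path File path.
#' @return A [color_scheme()].
#' @export
load_color_scheme <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_user("cannot parse scheme '%s': %s", path,
                              conditionMessage(e)))
  color_scheme(doc$breakpoints, doc$colors,
               doc$missing_color %||% "#c0c0c0")
}
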