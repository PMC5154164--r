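# Assembly of many pathway layouts into one collage: functional-class
# grouping, shelf packing, inter-pathway metabolite connections, and the
# pathways-for-metabolite query.

#' Functional placement category of a pathway
#'
#' Mapped from the root label of the pathway's ontology class path by a
#' keyword table: a root containing "Biosynthesis" maps to `biosynthesis`,
#' "Degradation" to `degradation`, "Energy" (as in "Generation of Precursor
#' Metabolites and Energy") to `energy`; anything else — including an empty
#' class path — maps to `other`.
#'
#' @param pw A [pathway()].
#' @return One of `"biosynthesis"`, `"degradation"`, `"energy"`, `"other"`.
#' @export
category_of <- function(pw) {
  root <- if (length(pw$class_path)) pw$class_path[1] else ""
  if (grepl("Biosynthesis", root, fixed = TRUE)) return("biosynthesis")
  if (grepl("Degradation", root, fixed = TRUE)) return("degradation")
  if (grepl("Energy", root, fixed = TRUE)) return("energy")
  "other"
}

# left-to-right order of category blocks; the two extremes are fixed
# (biosynthesis left, degradation right), the middle order is a convention
category_order <- c("biosynthesis", "energy", "other", "degradation")

new_collage <- function(style = style_config()) {
  structure(list(schema_version = "1.0", layouts = list(),
                 connections = list(), merges = list(), style = style,
                 omics = NULL),
            class = "pc_collage")
}

#' Assemble pathway layouts into a collage
#'
#' Layouts are grouped into contiguous blocks by functional category,
#' blocks placed left-to-right in the order biosynthesis, energy, other,
#' degradation (so biosynthetic pathways end up to the left of degradative
#' ones whenever both are present). Within a block, deterministic shelf
#' packing: rows filled left-to-right, a new row when `max_width` would be
#' exceeded, layouts ordered by descending height with ties broken by
#' pathway id. Bounding boxes stay pairwise disjoint with at least `gap`
#' separation. Shared metabolites deliberately do not influence placement.
#'
#' @param layouts List of `pc_layout` objects.
#' @param pathways Matching list of [pathway()] objects (for categories).
#' @param max_width Maximum collage width; must be at least the widest
#'   layout plus `2 * gap`.
#' @param gap Minimum separation between layout bounding boxes.
#' @param style Collage-wide [style_config()].
#' @return A `pc_collage`.
#' @export
assemble_collage <- function(layouts, pathways, max_width = 1200, gap = 30,
                             style = style_config()) {
  if (length(layouts) == 0) stop_user("no layouts to assemble")
  if (length(layouts) != length(pathways))
    stop_user("layouts and pathways must match 1:1")
  bboxes <- lapply(layouts, layout_bbox)
  widths <- vapply(bboxes, function(b) b[3] - b[1], 1)
  heights <- vapply(bboxes, function(b) b[4] - b[2], 1)
  if (max_width < max(widths) + 2 * gap)
    stop_user("max_width %.1f is smaller than widest layout %.1f + 2*gap",
              max_width, max(widths))
  cats <- vapply(pathways, category_of, "")
  pids <- vapply(layouts, function(l) l$pathway_id, "")
  if (anyDuplicated(pids))
    stop_user("duplicate pathway ids in collage: %s",
              paste(unique(pids[duplicated(pids)]), collapse = ", "))

  collage <- new_collage(style)
  x_block <- gap
  for (cat in category_order) {
    idx <- which(cats == cat)
    if (length(idx) == 0) next
    idx <- idx[order(-heights[idx], pids[idx])]
    shelf_x <- x_block; shelf_y <- gap; row_h <- 0; block_max_x <- x_block
    for (i in idx) {
      w <- widths[i]; h <- heights[i]
      if (shelf_x > x_block && shelf_x + w + gap > max_width) {
        shelf_x <- x_block
        shelf_y <- shelf_y + row_h + gap
        row_h <- 0
      }
      off <- c(shelf_x - bboxes[[i]][1], shelf_y - bboxes[[i]][2])
      collage$layouts[[length(collage$layouts) + 1L]] <-
        list(layout = layouts[[i]], offset = off)
      shelf_x <- shelf_x + w + gap
      row_h <- max(row_h, h)
      block_max_x <- max(block_max_x, shelf_x - gap)
    }
    x_block <- block_max_x + gap
  }
  collage
}

# collage-wide helpers -------------------------------------------------------

#' Bounding box of a collage
#'
#' @param collage A `pc_collage`.
#' @return `c(min_x, min_y, max_x, max_y)` over all placed layouts.
#' @export
collage_bbox <- function(collage) {
  if (length(collage$layouts) == 0) return(c(0, 0, 0, 0))
  rect_union(lapply(collage$layouts, function(pl) {
    b <- layout_bbox(pl$layout)
    c(b[1] + pl$offset[1], b[2] + pl$offset[2],
      b[3] + pl$offset[1], b[4] + pl$offset[2])
  }))
}

# index of the layout containing a glyph uid, or NA
glyph_layout_index <- function(collage, uid) {
  for (i in seq_along(collage$layouts))
    if (!is.null(collage$layouts[[i]]$layout$glyphs[[uid]])) return(i)
  NA_integer_
}

edge_layout_index <- function(collage, uid) {
  for (i in seq_along(collage$layouts))
    if (!is.null(collage$layouts[[i]]$layout$edges[[uid]])) return(i)
  NA_integer_
}

get_glyph <- function(collage, uid) {
  i <- glyph_layout_index(collage, uid)
  if (is.na(i)) NULL else collage$layouts[[i]]$layout$glyphs[[uid]]
}

# absolute center of a glyph (layout coordinates + layout offset)
abs_center <- function(collage, uid) {
  i <- glyph_layout_index(collage, uid)
  if (is.na(i)) stop_user("unknown glyph uid '%s'", uid)
  glyph_center(collage$layouts[[i]]$layout$glyphs[[uid]]) +
    collage$layouts[[i]]$offset
}

# all metabolite-node glyph uids, optionally restricted to one compound
metabolite_uids <- function(collage, compound_id = NULL) {
  out <- character()
  for (pl in collage$layouts) {
    for (g in pl$layout$glyphs) {
      if (g$kind == "metabolite-node" &&
          (is.null(compound_id) || g$ref_id == compound_id))
        out <- c(out, g$uid)
    }
  }
  out
}

connection_uid <- function(a, b) {
  p <- sort(c(a, b))
  sprintf("conn::%s__%s", p[1], p[2])
}

add_connection <- function(collage, a, b, compound_id) {
  uid <- connection_uid(a, b)
  if (is.null(collage$connections[[uid]])) {
    collage$connections[[uid]] <- make_edge(
      uid, "connection-edge", a, b, ref_id = compound_id,
      color = collage$style$colors[["connection-edge"]],
      thickness = collage$style$edge_thickness)
  }
  collage
}

#' Connect one metabolite node to all its other occurrences
#'
#' Adds a green connection edge from the given node to every other
#' metabolite-node glyph with the same compound; repeat calls add nothing.
#'
#' @param collage A `pc_collage`.
#' @param node_uid Uid of a metabolite-node glyph.
#' @return The updated collage.
#' @export
connect_metabolite <- function(collage, node_uid) {
  g <- get_glyph(collage, node_uid)
  if (is.null(g)) stop_user("unknown glyph uid '%s'", node_uid)
  if (g$kind != "metabolite-node")
    stop_user("glyph '%s' is not a metabolite node", node_uid)
  for (other in setdiff(metabolite_uids(collage, g$ref_id), node_uid))
    collage <- add_connection(collage, node_uid, other, g$ref_id)
  collage
}

#' Connect all duplicated metabolites in one operation
#'
#' For every compound with two or more node occurrences, adds the Euclidean
#' minimum-spanning-tree edges over the occurrence positions (`k - 1` edges
#' per compound), so each duplicated metabolite's occurrences form a
#' connected, acyclic set of connection lines. Edges never join nodes of
#' different compounds.
#'
#' @param collage A `pc_collage`.
#' @param exclude Character vector of compound ids to skip (e.g. currency
#'   metabolites such as ATP).
#' @return The updated collage.
#' @export
connect_all <- function(collage, exclude = character()) {
  uids <- metabolite_uids(collage)
  cids <- vapply(uids, function(u) get_glyph(collage, u)$ref_id, "")
  for (cid in sort(setdiff(unique(cids[duplicated(cids)]), exclude))) {
    grp <- sort(uids[cids == cid])
    pts <- t(vapply(grp, function(u) abs_center(collage, u), c(0, 0)))
    for (e in prim_mst(pts))
      collage <- add_connection(collage, grp[e[1]], grp[e[2]], cid)
  }
  collage
}

# Prim's algorithm on a complete Euclidean graph; deterministic: starts at
# vertex 1, ties resolved by smallest (cost, from, to) in index order.
prim_mst <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(list())
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_cost <- sqrt(colSums((t(pts) - pts[1, ])^2))
  best_from <- rep(1L, n)
  edges <- list()
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[order(best_cost[cand], best_from[cand], cand)][1]
    edges[[step]] <- c(best_from[j], j)
    in_tree[j] <- TRUE
    dj <- sqrt(colSums((t(pts) - pts[j, ])^2))
    upd <- !in_tree & dj < best_cost
    best_cost[upd] <- dj[upd]
    best_from[upd] <- j
  }
  edges
}

#' All pathways a metabolite participates in
#'
#' The query behind building a collage from a metabolite list: every pathway
#' containing a reaction in which the compound participates, in either
#' direction and either role (main or side).
#'
#' @param compound_id Compound id (must exist in the collection).
#' @param collection A [pathway_collection()].
#' @return Sorted character vector of pathway ids.
#' @export
pathways_for_metabolite <- function(compound_id, collection) {
  if (is.null(find_compound(collection, compound_id)))
    stop_user("unknown compound id '%s'", compound_id)
  hits <- character()
  for (pw in collection$pathways) {
    found <- FALSE
    for (r in pw$reactions) for (p in r$participants)
      if (p$compound_id == compound_id) { found <- TRUE; break }
    if (found) hits <- c(hits, pw$id)
  }
  sort(unique(hits))
}

#' Add a pathway layout below an existing collage
#'
#' Newly added pathways are placed below the collage (left-aligned to its
#' minimum x) and can then be repositioned with [move_pathway()].
#'
#' @param collage A `pc_collage`.
#' @param layout A `pc_layout` for a pathway not already in the collage.
#' @param gap Vertical gap to the existing collage.
#' @return The updated collage.
#' @export
add_pathway_to_collage <- function(collage, layout, gap = 30) {
  pids <- vapply(collage$layouts, function(pl) pl$layout$pathway_id, "")
  if (layout$pathway_id %in% pids)
    stop_user("pathway '%s' is already in the collage", layout$pathway_id)
  b <- layout_bbox(layout)
  if (length(collage$layouts) == 0) {
    off <- c(gap - b[1], gap - b[2])
  } else {
    cb <- collage_bbox(collage)
    off <- c(cb[1] - b[1], cb[4] + gap - b[2])
  }
  collage$layouts[[length(collage$layouts) + 1L]] <-
    list(layout = layout, offset = off)
  collage
}
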