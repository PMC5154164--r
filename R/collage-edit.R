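# Scripted equivalents of the viewer's interactive refinements. Every edit
# is pure: it returns an updated copy of the collage and never mutates its
# argument, so scripts can diff states.

# uids of glyphs attached (directly or transitively) to `uid` in layout i
descendant_uids <- function(layout, uid) {
  out <- character()
  frontier <- uid
  repeat {
    kids <- names(Filter(function(g) !is.null(g$parent_uid) &&
                           g$parent_uid %in% frontier, layout$glyphs))
    kids <- setdiff(kids, out)
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Move a single node
#'
#' Translates one glyph by `(dx, dy)`; glyphs attached to it (omics grids
#' and their boxes) move with it. Nothing else moves.
#'
#' @param collage A `pc_collage`.
#' @param uid Glyph uid.
#' @param dx,dy Translation in layout units (y grows downward).
#' @return The updated collage.
#' @export
move_node <- function(collage, uid, dx, dy) {
  i <- glyph_layout_index(collage, uid)
  if (is.na(i)) stop_user("unknown glyph uid '%s'", uid)
  lay <- collage$layouts[[i]]$layout
  for (u in c(uid, descendant_uids(lay, uid))) {
    lay$glyphs[[u]]$x <- lay$glyphs[[u]]$x + dx
    lay$glyphs[[u]]$y <- lay$glyphs[[u]]$y + dy
  }
  lay$bbox <- layout_bbox(lay)
  collage$layouts[[i]]$layout <- lay
  collage
}

#' Move an entire pathway
#'
#' Translates every glyph of the pathway by `(dx, dy)` (implemented as an
#' offset change, so it is exactly invertible). Connection-edge endpoints
#' follow automatically because edge geometry is derived from node positions.
#'
#' @param collage A `pc_collage`.
#' @param pathway_id Pathway id present in the collage.
#' @param dx,dy Translation.
#' @return The updated collage.
#' @export
move_pathway <- function(collage, pathway_id, dx, dy) {
  pids <- vapply(collage$layouts, function(pl) pl$layout$pathway_id, "")
  i <- match(pathway_id, pids)
  if (is.na(i)) stop_user("unknown pathway id '%s'", pathway_id)
  collage$layouts[[i]]$offset <- collage$layouts[[i]]$offset + c(dx, dy)
  collage
}

remove_glyphs_from_layout <- function(lay, uids) {
  all_gone <- unique(unlist(c(uids, lapply(uids, descendant_uids,
                                           layout = lay))))
  lay$glyphs[all_gone] <- NULL
  keep <- vapply(lay$edges, function(e)
    !(e$source_uid %in% all_gone || e$target_uid %in% all_gone), TRUE)
  lay$edges <- lay$edges[keep]
  lay$backbone <- setdiff(lay$backbone, all_gone)
  lay$bbox <- layout_bbox(lay)
  list(layout = lay, removed = all_gone)
}

drop_connections_touching <- function(collage, uids) {
  keep <- vapply(collage$connections, function(e)
    !(e$source_uid %in% uids || e$target_uid %in% uids), TRUE)
  collage$connections <- collage$connections[keep]
  collage
}

#' Delete a node, edge or pathway
#'
#' Deleting a node also removes its incident edges and attached omics grids;
#' deleting a pathway removes all its glyphs and edges plus any connection
#' edges touching them; deleting an edge leaves its endpoints in place.
#'
#' @param collage A `pc_collage`.
#' @param id A glyph uid, an edge uid (reaction or connection), or a
#'   pathway id.
#' @return The updated collage.
#' @export
delete_element <- function(collage, id) {
  pids <- vapply(collage$layouts, function(pl) pl$layout$pathway_id, "")
  if (id %in% pids) {
    i <- match(id, pids)
    uids <- names(collage$layouts[[i]]$layout$glyphs)
    collage$layouts[[i]] <- NULL
    return(drop_connections_touching(collage, uids))
  }
  if (!is.null(collage$connections[[id]])) {
    collage$connections[[id]] <- NULL
    return(collage)
  }
  i <- glyph_layout_index(collage, id)
  if (!is.na(i)) {
    res <- remove_glyphs_from_layout(collage$layouts[[i]]$layout, id)
    collage$layouts[[i]]$layout <- res$layout
    # cross-layout edges (possible after merges) and connections
    for (j in seq_along(collage$layouts)) {
      lay <- collage$layouts[[j]]$layout
      keep <- vapply(lay$edges, function(e)
        !(e$source_uid %in% res$removed || e$target_uid %in% res$removed),
        TRUE)
      collage$layouts[[j]]$layout$edges <- lay$edges[keep]
    }
    return(drop_connections_touching(collage, res$removed))
  }
  i <- edge_layout_index(collage, id)
  if (!is.na(i)) {
    collage$layouts[[i]]$layout$edges[[id]] <- NULL
    return(collage)
  }
  stop_user("unknown element '%s'", id)
}

#' Merge node occurrences of the same metabolite
#'
#' The first-listed node survives at its position; all edges incident to the
#' absorbed nodes are re-targeted to the survivor, parallel duplicates
#' (same kind, same endpoints) collapse to one, and connection edges that
#' become self-loops are removed. The merge is recorded in `collage$merges`.
#'
#' @param collage A `pc_collage`.
#' @param uids Character vector (length >= 2) of metabolite-node glyph uids,
#'   all referring to the same compound.
#' @return The updated collage.
#' @export
merge_nodes <- function(collage, uids) {
  if (length(uids) < 2) stop_user("merge needs at least 2 node uids")
  gl <- lapply(uids, function(u) get_glyph(collage, u))
  missing <- uids[vapply(gl, is.null, TRUE)]
  if (length(missing)) stop_user("unknown glyph uid '%s'", missing[1])
  kinds <- vapply(gl, function(g) g$kind, "")
  if (any(kinds != "metabolite-node"))
    stop_user("merge targets must all be metabolite nodes")
  cids <- vapply(gl, function(g) g$ref_id, "")
  if (length(unique(cids)) != 1)
    stop_user("cannot merge nodes of different compounds: %s",
              paste(unique(cids), collapse = ", "))
  survivor <- uids[1]
  absorbed <- unique(uids[-1])

  # retarget every edge that touches an absorbed node
  retarget <- function(e) {
    if (e$source_uid %in% absorbed) e$source_uid <- survivor
    if (e$target_uid %in% absorbed) e$target_uid <- survivor
    e
  }
  for (j in seq_along(collage$layouts))
    collage$layouts[[j]]$layout$edges <-
      lapply(collage$layouts[[j]]$layout$edges, retarget)
  collage$connections <- lapply(collage$connections, retarget)

  # drop absorbed glyphs (and their attached grids)
  for (u in absorbed) {
    i <- glyph_layout_index(collage, u)
    res <- remove_glyphs_from_layout_keep_edges(collage$layouts[[i]]$layout, u)
    collage$layouts[[i]]$layout <- res
  }

  # self-loops out, parallel duplicates collapsed
  dedupe <- function(edges) {
    keys <- character(); keep <- logical(length(edges))
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      if (identical(e$source_uid, e$target_uid)) { keep[k] <- FALSE; next }
      key <- paste(e$kind, paste(sort(c(e$source_uid, e$target_uid)),
                                 collapse = "|"))
      keep[k] <- !(key %in% keys)
      keys <- c(keys, key)
    }
    edges[keep]
  }
  for (j in seq_along(collage$layouts))
    collage$layouts[[j]]$layout$edges <-
      dedupe(collage$layouts[[j]]$layout$edges)
  collage$connections <- dedupe(collage$connections)

  collage$merges[[length(collage$merges) + 1L]] <-
    list(survivor = survivor, absorbed = absorbed)
  collage
}

# remove glyph + descendants but leave (already retargeted) edges alone
remove_glyphs_from_layout_keep_edges <- function(lay, uid) {
  gone <- c(uid, descendant_uids(lay, uid))
  lay$glyphs[gone] <- NULL
  lay$backbone <- setdiff(lay$backbone, gone)
  lay$bbox <- layout_bbox(lay)
  lay
}

#' Highlight a node or edge in a user-specified color
#'
#' @param collage A `pc_collage`.
#' @param uid Glyph or edge uid.
#' @param color Display color.
#' @return The updated collage.
#' @export
highlight <- function(collage, uid, color) {
  i <- glyph_layout_index(collage, uid)
  if (!is.na(i)) {
    collage$layouts[[i]]$layout$glyphs[[uid]]$color <- as.character(color)
    return(collage)
  }
  if (!is.null(collage$connections[[uid]])) {
    collage$connections[[uid]]$color <- as.character(color)
    return(collage)
  }
  i <- edge_layout_index(collage, uid)
  if (!is.na(i)) {
    collage$layouts[[i]]$layout$edges[[uid]]$color <- as.character(color)
    return(collage)
  }
  stop_user("unknown element '%s'", uid)
}

#' Edit the text of a label
#'
#' @param collage A `pc_collage`.
#' @param uid Glyph uid (metabolite node or any label glyph).
#' @param text Replacement text, used verbatim.
#' @return The updated collage.
#' @export
relabel <- function(collage, uid, text) {
  i <- glyph_layout_index(collage, uid)
  if (is.na(i)) stop_user("unknown glyph uid '%s'", uid)
  collage$layouts[[i]]$layout$glyphs[[uid]]$label_text <- as.character(text)
  collage
}

#' Update collage style settings
#'
#' Only the named fields change. Toggling `show_pathway_boxes` also flips
#' the `visible` flag of every pathway-box glyph.
#'
#' @param collage A `pc_collage`.
#' @param updates Named list of [style_config()] fields.
#' @return The updated collage.
#' @export
set_style <- function(collage, updates) {
  unknown <- setdiff(names(updates), names(collage$style))
  if (length(unknown))
    stop_user("unknown style field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(updates)) collage$style[[nm]] <- updates[[nm]]
  if ("show_pathway_boxes" %in% names(updates)) {
    vis <- isTRUE(updates$show_pathway_boxes)
    for (j in seq_along(collage$layouts)) {
      lay <- collage$layouts[[j]]$layout
      for (u in names(lay$glyphs)) {
        if (lay$glyphs[[u]]$kind == "pathway-box")
          collage$layouts[[j]]$layout$glyphs[[u]]$visible <- vis
      }
    }
  }
  collage
}
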