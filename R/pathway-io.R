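# Reading/writing the native pathway-collection schema, omics TSV tables,
# saved collage JSON (schema version "1.0"; unknown versions are rejected,
# not guessed), and the Cytoscape-style viewer graph dialect.
#
# Native collection schema (shipped in inst/schema/collection-schema.json):
#   {schema_version, compounds: [{id, name, synonyms}],
#    reactions: [{id, participants: [{compound_id, side, role, coefficient}],
#                 direction, enzyme_labels, gene_ids}],
#    pathways: [{id, name, reaction_ids, links: [[pred, succ], ...],
#                class_path}]}

SCHEMA_VERSION <- "1.0"

parse_json_file <- function(path) {
  if (!file.exists(path)) stop_user("file not found: %s", path)
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e)
             stop_user("malformed JSON in '%s': %s", path,
                       conditionMessage(e)))
}

chr <- function(x) as.character(unlist(x))

#' Read a pathway collection from its native JSON schema
#'
#' Parses, resolves pathway reaction references against the top-level
#' reaction table, and validates every domain invariant; all breaches are
#' reported together.
#'
#' @param path Path to a collection JSON file.
#' @return A validated [pathway_collection()].
#' @export
read_pathway_collection <- function(path) {
  doc <- parse_json_file(path)
  ver <- doc$schema_version %||% "<missing>"
  if (!identical(ver, SCHEMA_VERSION))
    stop_user("unsupported collection schema_version '%s' (expected '%s')",
              ver, SCHEMA_VERSION)
  compounds <- lapply(doc$compounds, function(cp)
    compound(cp$id, cp$name %||% cp$id, chr(cp$synonyms)))
  rx_tab <- list()
  for (r in doc$reactions) {
    parts <- lapply(r$participants, function(p)
      reaction_participant(p$compound_id, p$side, p$role %||% "main",
                           p$coefficient %||% 1))
    rx_tab[[r$id]] <- reaction(r$id, parts, r$direction %||% "forward",
                               chr(r$enzyme_labels), chr(r$gene_ids))
  }
  problems <- character()
  pathways <- lapply(doc$pathways, function(pd) {
    rids <- chr(pd$reaction_ids)
    unknown <- setdiff(rids, names(rx_tab))
    if (length(unknown))
      problems <<- c(problems,
                     sprintf("pathway '%s' references undeclared reaction '%s'",
                             pd$id, unknown))
    pathway(pd$id, unname(rx_tab[intersect(rids, names(rx_tab))]),
            links = lapply(pd$links, chr), name = pd$name %||% pd$id,
            class_path = chr(pd$class_path))
  })
  if (length(problems))
    stop_user("invalid collection '%s':\n  %s", path,
              paste(problems, collapse = "\n  "))
  coll <- pathway_collection(compounds, pathways)
  v <- validate_collection(coll)
  if (nrow(v))
    stop_user("invalid collection '%s':\n  %s", path,
              paste(v$message, collapse = "\n  "))
  coll
}

#' Write a pathway collection to its native JSON schema
#'
#' @param collection A [pathway_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_collection <- function(collection, path) {
  rx_tab <- list()
  pws <- lapply(collection$pathways, function(pw) {
    for (r in pw$reactions) {
      rx_tab[[r$id]] <<- list(
        id = r$id,
        participants = lapply(r$participants, function(p)
          list(compound_id = p$compound_id, side = p$side, role = p$role,
               coefficient = p$coefficient)),
        direction = r$direction, enzyme_labels = I(r$enzyme_labels),
        gene_ids = I(r$gene_ids))
    }
    list(id = pw$id, name = pw$name,
         reaction_ids = I(vapply(pw$reactions, function(r) r$id, "")),
         links = lapply(pw$links, I), class_path = I(pw$class_path))
  })
  doc <- list(schema_version = SCHEMA_VERSION,
              compounds = lapply(collection$compounds, function(cp)
                list(id = cp$id, name = cp$name, synonyms = I(cp$synonyms))),
              reactions = unname(rx_tab), pathways = pws)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read an omics table from TSV
#'
#' Tab-delimited UTF-8 with a header row; first column entity id, remaining
#' columns numeric values per condition/timepoint. Non-numeric and empty
#' cells become missing values. Duplicate entity ids: the last row wins,
#' with a warning.
#'
#' @param path TSV path.
#' @param data_type `"gene"`, `"metabolite"` or `"flux"`.
#' @return An [omics_dataset()].
#' @export
read_omics_table <- function(path, data_type) {
  if (!file.exists(path)) stop_user("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    stop_user("omics table '%s' needs an id column plus >= 1 value column",
              path)
  if (nrow(df) == 0) stop_user("omics table '%s' has no data rows", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    warning(sprintf("duplicate entity ids in '%s' (last row wins): %s",
                    path, paste(dup, collapse = ", ")))
  rows <- list()
  for (i in seq_len(nrow(df))) {  # later rows overwrite earlier: last wins
    vals <- suppressWarnings(as.numeric(as.character(df[i, -1])))
    rows[[ids[i]]] <- vals
  }
  omics_dataset(data_type, colnames(df)[-1], rows)
}

#' Write an omics dataset to TSV
#'
#' @param dataset An [omics_dataset()].
#' @param path Output path.
#' @param id_header Header label for the entity-id column.
#' @return Invisibly, `path`.
#' @export
write_omics_table <- function(dataset, path, id_header = "id") {
  m <- do.call(rbind, dataset$rows)
  df <- data.frame(names(dataset$rows), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, dataset$columns)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Saved collage JSON (round-trip format)

glyph_to_list <- function(g) g  # plain lists already

edge_to_list <- function(e) e

collage_to_list <- function(collage) {
  list(
    schema_version = collage$schema_version,
    layouts = lapply(collage$layouts, function(pl) list(
      offset = pl$offset,
      layout = list(
        pathway_id = pl$layout$pathway_id,
        glyphs = unname(pl$layout$glyphs),
        edges = unname(pl$layout$edges),
        bbox = pl$layout$bbox,
        backbone = I(pl$layout$backbone),
        reaction_info = lapply(pl$layout$reaction_info, function(info)
          list(gene_ids = I(info$gene_ids),
               enzyme_labels = I(info$enzyme_labels),
               direction = info$direction, in_uid = info$in_uid,
               out_uid = info$out_uid))))),
    connections = unname(collage$connections),
    merges = lapply(collage$merges, function(m)
      list(survivor = m$survivor, absorbed = I(m$absorbed))),
    style = style_to_list(collage$style),
    omics = if (is.null(collage$omics)) NULL else list(
      mode = collage$omics$mode,
      dataset = list(data_type = collage$omics$dataset$data_type,
                     columns = I(collage$omics$dataset$columns),
                     rows = lapply(collage$omics$dataset$rows, I)),
      scheme = list(breakpoints = I(collage$omics$scheme$breakpoints),
                    colors = I(collage$omics$scheme$colors),
                    missing_color = collage$omics$scheme$missing_color),
      coverage = list(matched = I(collage$omics$coverage$matched),
                      unmatched = I(collage$omics$coverage$unmatched))))
}

style_to_list <- function(style) {
  list(show_pathway_boxes = style$show_pathway_boxes,
       show_pathway_labels = style$show_pathway_labels,
       show_enzyme_labels = style$show_enzyme_labels,
       show_omics = style$show_omics,
       show_connections = style$show_connections,
       font_sizes = as.list(style$font_sizes),
       colors = style$colors,
       edge_thickness = style$edge_thickness)
}

style_from_list <- function(sl) {
  style_config(show_pathway_boxes = isTRUE(sl$show_pathway_boxes),
               show_pathway_labels = isTRUE(sl$show_pathway_labels),
               show_enzyme_labels = isTRUE(sl$show_enzyme_labels),
               show_omics = isTRUE(sl$show_omics),
               show_connections = isTRUE(sl$show_connections),
               font_sizes = unlist(sl$font_sizes),
               colors = sl$colors,
               edge_thickness = as.numeric(sl$edge_thickness))
}

glyph_from_list <- function(gl) {
  make_glyph(gl$uid, gl$kind, ref_id = gl$ref_id, x = gl$x, y = gl$y,
             width = gl$width, height = gl$height, color = gl$color,
             label_text = gl$label_text, visible = isTRUE(gl$visible),
             parent_uid = gl$parent_uid) |>
    (\(g) { if (!is.null(gl$overlay_color))
      g$overlay_color <- gl$overlay_color; g })()
}

edge_from_list <- function(el) {
  e <- make_edge(el$uid, el$kind, el$source_uid, el$target_uid,
                 ref_id = el$ref_id, color = el$color,
                 thickness = el$thickness, arrow = el$arrow,
                 curved = isTRUE(el$curved),
                 primary = isTRUE(el$primary %||% TRUE))
  if (!is.null(el$overlay_color)) e$overlay_color <- el$overlay_color
  e
}

collage_from_list <- function(doc) {
  collage <- new_collage(style_from_list(doc$style))
  collage$layouts <- lapply(doc$layouts, function(pl) {
    glyphs <- lapply(pl$layout$glyphs, glyph_from_list)
    names(glyphs) <- vapply(glyphs, function(g) g$uid, "")
    edges <- lapply(pl$layout$edges, edge_from_list)
    names(edges) <- vapply(edges, function(e) e$uid, "")
    list(offset = as.numeric(unlist(pl$offset)),
         layout = structure(list(
           pathway_id = pl$layout$pathway_id,
           glyphs = glyphs, edges = edges,
           bbox = as.numeric(unlist(pl$layout$bbox)),
           backbone = chr(pl$layout$backbone),
           reaction_info = lapply(pl$layout$reaction_info, function(info)
             list(gene_ids = chr(info$gene_ids),
                  enzyme_labels = chr(info$enzyme_labels),
                  direction = info$direction, in_uid = info$in_uid,
                  out_uid = info$out_uid))),
           class = "pc_layout"))
  })
  conns <- lapply(doc$connections, edge_from_list)
  names(conns) <- vapply(conns, function(e) e$uid, character(1)) |>
    (\(x) if (length(x)) x else NULL)()
  collage$connections <- if (length(conns)) conns else list()
  collage$merges <- lapply(doc$merges, function(m)
    list(survivor = m$survivor, absorbed = chr(m$absorbed)))
  if (!is.null(doc$omics)) {
    rows <- lapply(doc$omics$dataset$rows, function(v)
      vapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x), 0))
    collage$omics <- list(
      dataset = omics_dataset(doc$omics$dataset$data_type,
                              chr(doc$omics$dataset$columns), rows),
      scheme = color_scheme(as.numeric(unlist(doc$omics$scheme$breakpoints)),
                            chr(doc$omics$scheme$colors),
                            doc$omics$scheme$missing_color),
      mode = doc$omics$mode,
      coverage = list(matched = chr(doc$omics$coverage$matched),
                      unmatched = chr(doc$omics$coverage$unmatched)))
  }
  collage
}

#' Save a collage as a JSON graph file
#'
#' `load_collage(save_collage(c))` is deep-equal to `c`, including offsets,
#' merges, style and any attached omics overlay. Numbers are serialized at
#' full precision.
#'
#' @param collage A `pc_collage`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_collage <- function(collage, path) {
  jsonlite::write_json(collage_to_list(collage), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' Load a collage saved by [save_collage()]
#'
#' @param path Path to a collage JSON file.
#' @return A `pc_collage`.
#' @export
load_collage <- function(path) {
  doc <- parse_json_file(path)
  ver <- doc$schema_version %||% "<missing>"
  if (!identical(ver, SCHEMA_VERSION))
    stop_user("unsupported collage schema_version '%s' (expected '%s')",
              ver, SCHEMA_VERSION)
  collage_from_list(doc)
}

# ---------------------------------------------------------------------------
# Deep equality with numeric tolerance (1e-9 on coordinates, exact on ids)

#' Compare two collages for deep equality
#'
#' Exact comparison for strings and logicals, tolerance `tol` for numbers.
#'
#' @param a,b Collages.
#' @param tol Numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
collage_equal <- function(a, b, tol = 1e-9) {
  deep_equal(a, b, tol)
}

deep_equal <- function(a, b, tol) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.list(a) || is.list(b)) {
    if (!is.list(a) || !is.list(b)) return(FALSE)
    na <- names(a) %||% rep("", length(a))
    nb <- names(b) %||% rep("", length(b))
    if (length(a) != length(b)) return(FALSE)
    if (!identical(sort(na), sort(nb))) return(FALSE)
    if (any(nzchar(na))) {
      for (nm in na) if (!deep_equal(a[[nm]], b[[nm]], tol)) return(FALSE)
    } else {
      for (i in seq_along(a)) if (!deep_equal(a[[i]], b[[i]], tol))
        return(FALSE)
    }
    return(TRUE)
  }
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b)) return(FALSE)
    same_na <- is.na(a) == is.na(b)
    return(all(same_na) &&
             all(abs(a[!is.na(a)] - b[!is.na(b)]) <= tol))
  }
  isTRUE(all.equal(unclass(a), unclass(b), check.attributes = FALSE))
}

# ---------------------------------------------------------------------------
# Viewer (Cytoscape-style elements/style) export

#' Export a collage to viewer graph JSON
#'
#' Emits a Cytoscape-style document: `elements$nodes` (each with
#' `data: {id, label, kind, ref}` and `position: {x, y}` — the absolute
#' center), `elements$edges` (each with `data: {id, source, target, kind}`)
#' and a `style` section derived from the collage style. Nodes are the
#' glyphs visible under the style toggles (zoom is a viewer concern);
#' absorbed merge targets are gone from the collage and hence absent here.
#'
#' @param collage A `pc_collage`.
#' @return A list (JSON-ready document).
#' @export
export_viewer_json <- function(collage) {
  style <- collage$style
  nodes <- list()
  edges <- list()
  for (pl in collage$layouts) {
    lay <- pl$layout
    for (g in lay$glyphs) {
      show <- switch(g$kind,
        "metabolite-node" = TRUE,
        "pathway-box" = style$show_pathway_boxes,
        "pathway-label" = style$show_pathway_labels,
        "enzyme-label" = style$show_enzyme_labels &&
          !(style$show_omics && replaced_by_grid(lay, g$uid)),
        "gene-label" = style$show_enzyme_labels,
        "omics-grid" = style$show_omics,
        "omics-box" = style$show_omics,
        FALSE)
      if (!show || !g$visible) next
      ctr <- glyph_center(g) + pl$offset
      nodes[[length(nodes) + 1L]] <- list(
        data = list(id = g$uid, label = g$label_text, kind = g$kind,
                    ref = g$ref_id),
        position = list(x = ctr[1], y = ctr[2]))
    }
    for (e in lay$edges)
      edges[[length(edges) + 1L]] <- list(
        data = list(id = e$uid, source = e$source_uid,
                    target = e$target_uid,
                    kind = sub("-edge$", "", e$kind)))
  }
  if (style$show_connections) {
    for (e in collage$connections)
      edges[[length(edges) + 1L]] <- list(
        data = list(id = e$uid, source = e$source_uid,
                    target = e$target_uid,
                    kind = sub("-edge$", "", e$kind)))
  }
  list(elements = list(nodes = nodes, edges = edges),
       style = style_to_list(style))
}

#' Validate a document against a minimal JSON schema
#'
#' Supports the subset of JSON Schema used by the shipped schemas: `type`
#' (object / array / string / number / boolean), `required`, `properties`,
#' `items` and `enum`.
#'
#' @param doc An R list (as parsed from / ready to write as JSON).
#' @param schema_path Path to the schema JSON; defaults to the viewer graph
#'   schema shipped with the package.
#' @return Character vector of violations; empty iff valid.
#' @export
validate_against_schema <- function(doc,
                                    schema_path = system.file(
                                      "schema", "viewer-graph-schema.json",
                                      package = "pathcollage")) {
  schema <- parse_json_file(schema_path)
  check <- function(x, sch, where) {
    errs <- character()
    ty <- sch$type
    if (!is.null(ty)) {
      ok <- switch(ty,
        "object" = is.list(x) && (length(x) == 0 || !is.null(names(x))),
        "array" = is.list(x) && is.null(names(x)) || length(x) == 0,
        "string" = is.character(x) && length(x) == 1,
        "number" = is.numeric(x) && length(x) == 1,
        "boolean" = is.logical(x) && length(x) == 1,
        TRUE)
      if (!ok) return(sprintf("%s: expected %s", where, ty))
    }
    if (!is.null(sch$enum) && !(x %in% unlist(sch$enum)))
      errs <- c(errs, sprintf("%s: value '%s' not in enum", where, x))
    for (req in unlist(sch$required))
      if (!(req %in% names(x)))
        errs <- c(errs, sprintf("%s: missing required property '%s'",
                                where, req))
    for (nm in names(sch$properties)) {
      if (!is.null(x[[nm]]))
        errs <- c(errs, check(x[[nm]], sch$properties[[nm]],
                              paste0(where, ".", nm)))
    }
    if (!is.null(sch$items) && is.list(x)) {
      for (i in seq_along(x))
        errs <- c(errs, check(x[[i]], sch$items,
                              sprintf("%s[%d]", where, i)))
    }
    errs
  }
  check(doc, schema, "$")
}
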