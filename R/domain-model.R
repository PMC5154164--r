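# Shared domain types. All containers are plain S3 lists: cheap to build in
# tests, serialize losslessly to JSON, and diff well under all.equal-style
# comparison. Identifiers are case-sensitive throughout.

#' Create a compound record
#'
#' A compound is a chemical species that can participate in reactions. The
#' same compound may occur in many pathways; every occurrence becomes its own
#' metabolite-node glyph until explicitly merged.
#'
#' @param id Non-empty string identifier, unique within a collection.
#' @param name Display name (defaults to `id`).
#' @param synonyms Character vector of alternative names.
#' @return A list of class `pc_compound`.
#' @export
compound <- function(id, name = id, synonyms = character()) {
  structure(list(id = as.character(id), name = as.character(name),
                 synonyms = as.character(synonyms)),
            class = "pc_compound")
}

#' Create a reaction participant
#'
#' @param compound_id Compound identifier.
#' @param side `"substrate"` or `"product"`.
#' @param role `"main"` (on the pathway backbone, always drawn) or `"side"`
#'   (currency-style co-substrate, hidden by default).
#' @param coefficient Positive stoichiometric coefficient.
#' @return A list of class `pc_participant`.
#' @export
reaction_participant <- function(compound_id, side, role = "main",
                                 coefficient = 1) {
  side <- match.arg(side, c("substrate", "product"))
  role <- match.arg(role, c("main", "side"))
  structure(list(compound_id = as.character(compound_id), side = side,
                 role = role, coefficient = as.numeric(coefficient)),
            class = "pc_participant")
}

#' Create a reaction record
#'
#' @param id Reaction identifier.
#' @param participants List of [reaction_participant()] records. A valid
#'   reaction has at least one substrate and one product, with at least one
#'   `main` participant on each side.
#' @param direction `"forward"` or `"reversible"`.
#' @param enzyme_labels Character vector of enzyme display names.
#' @param gene_ids Character vector of gene identifiers (targets for gene
#'   expression overlays).
#' @return A list of class `pc_reaction`.
#' @export
reaction <- function(id, participants, direction = "forward",
                     enzyme_labels = character(), gene_ids = character()) {
  direction <- match.arg(direction, c("forward", "reversible"))
  structure(list(id = as.character(id), participants = participants,
                 direction = direction,
                 enzyme_labels = as.character(enzyme_labels),
                 gene_ids = as.character(gene_ids)),
            class = "pc_reaction")
}

#' Create a pathway record
#'
#' @param id Pathway identifier.
#' @param reactions List of [reaction()] records (ids unique within the
#'   pathway).
#' @param links List of length-2 character vectors `c(predecessor_reaction,
#'   successor_reaction)` giving the reaction ordering; the link graph must be
#'   weakly connected when the pathway has two or more reactions.
#' @param name Display name.
#' @param class_path Character vector of ontology labels, general to
#'   specific; the root label determines the placement category (see
#'   [category_of()]).
#' @return A list of class `pc_pathway`.
#' @export
pathway <- function(id, reactions, links = list(), name = id,
                    class_path = character()) {
  structure(list(id = as.character(id), name = as.character(name),
                 reactions = reactions,
                 links = lapply(links, as.character),
                 class_path = as.character(class_path)),
            class = "pc_pathway")
}

#' Create a pathway collection
#'
#' The unit of input: the compounds and pathways extracted from (or standing
#' in for) a pathway/genome database.
#'
#' @param compounds List of [compound()] records.
#' @param pathways List of [pathway()] records.
#' @param schema_version Schema version string; only `"1.0"` is understood.
#' @return A list of class `pc_collection`.
#' @export
pathway_collection <- function(compounds, pathways, schema_version = "1.0") {
  structure(list(schema_version = schema_version, compounds = compounds,
                 pathways = pathways),
            class = "pc_collection")
}

#' Display style configuration
#'
#' Toggles and numeric style parameters applied collage-wide. All numeric
#' fields must be positive.
#'
#' @param show_pathway_boxes,show_pathway_labels,show_enzyme_labels,show_omics,show_connections
#'   Visibility toggles.
#' @param font_sizes Named numeric vector of font sizes (layout units) for
#'   `pathway-label`, `metabolite-label`, `enzyme-label`, `gene-label`.
#' @param colors Named list of default colors per glyph/edge kind.
#' @param edge_thickness Default edge stroke width.
#' @return A list of class `pc_style`.
#' @export
style_config <- function(show_pathway_boxes = TRUE,
                         show_pathway_labels = TRUE,
                         show_enzyme_labels = TRUE,
                         show_omics = TRUE,
                         show_connections = TRUE,
                         font_sizes = c(`pathway-label` = 13,
                                        `metabolite-label` = 9,
                                        `enzyme-label` = 8,
                                        `gene-label` = 7),
                         colors = list(`metabolite-node` = "#33527b",
                                       `enzyme-label` = "#7b3356",
                                       `gene-label` = "#555555",
                                       `pathway-label` = "#1a1a1a",
                                       `pathway-box` = "#f2f4f8",
                                       `omics-grid` = "#888888",
                                       `reaction-edge` = "#2b6cb0",
                                       `connection-edge` = "#009933"),
                         edge_thickness = 1.5) {
  stopifnot(all(font_sizes > 0), edge_thickness > 0)
  structure(list(show_pathway_boxes = isTRUE(show_pathway_boxes),
                 show_pathway_labels = isTRUE(show_pathway_labels),
                 show_enzyme_labels = isTRUE(show_enzyme_labels),
                 show_omics = isTRUE(show_omics),
                 show_connections = isTRUE(show_connections),
                 font_sizes = font_sizes, colors = colors,
                 edge_thickness = edge_thickness),
            class = "pc_style")
}

#' Semantic-zoom policy
#'
#' Minimum zoom factor at which each label kind is drawn. Thresholds are
#' inclusive: a label is shown when `zoom >= threshold`. The defaults are
#' declared, not derived: pathway labels are large and appear first, enzyme
#' and gene labels are small and appear last.
#'
#' @param pathway_label,metabolite_label,enzyme_label,gene_label Positive
#'   zoom thresholds.
#' @return Named numeric vector of class `pc_zoom_policy`.
#' @export
zoom_policy <- function(pathway_label = 0.25, metabolite_label = 0.5,
                        enzyme_label = 0.75, gene_label = 0.75) {
  p <- c(`pathway-label` = pathway_label,
         `metabolite-label` = metabolite_label,
         `enzyme-label` = enzyme_label,
         `gene-label` = gene_label)
  stopifnot(all(p > 0))
  structure(p, class = "pc_zoom_policy")
}

#' Color scheme mapping values to display colors
#'
#' Values are binned with a half-open convention: a value below the first
#' breakpoint gets `colors[1]`; a value in `[breakpoints[i], breakpoints[i+1])`
#' gets `colors[i+1]`; a value at or above the last breakpoint gets the last
#' color. Missing values map to `missing_color`.
#'
#' @param breakpoints Strictly ascending numeric vector (length >= 1).
#' @param colors Character vector of length `length(breakpoints) + 1`.
#' @param missing_color Color used for missing data.
#' @return A list of class `pc_color_scheme`.
#' @export
color_scheme <- function(breakpoints, colors, missing_color = "#c0c0c0") {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 1 || any(diff(breakpoints) <= 0))
    stop_user("color scheme breakpoints must be strictly ascending (n >= 1)")
  if (length(colors) != length(breakpoints) + 1)
    stop_user("color scheme needs %d colors for %d breakpoints, got %d",
              length(breakpoints) + 1, length(breakpoints), length(colors))
  structure(list(breakpoints = breakpoints, colors = as.character(colors),
                 missing_color = as.character(missing_color)),
            class = "pc_color_scheme")
}

#' Omics dataset
#'
#' @param data_type `"gene"`, `"metabolite"` or `"flux"`; decides which
#'   collage elements the rows are matched to.
#' @param columns Ordered character vector of condition/timepoint labels.
#' @param rows Named list, entity id to numeric vector of
#'   `length(columns)` values (`NA` allowed for missing cells).
#' @return A list of class `pc_omics`.
#' @export
omics_dataset <- function(data_type, columns, rows) {
  data_type <- match.arg(data_type, c("gene", "metabolite", "flux"))
  columns <- as.character(columns)
  if (length(columns) < 1) stop_user("omics dataset needs >= 1 column")
  rows <- lapply(rows, as.numeric)
  bad <- names(rows)[vapply(rows, length, 1L) != length(columns)]
  if (length(bad))
    stop_user("omics rows with wrong length (expected %d): %s",
              length(columns), paste(bad, collapse = ", "))
  structure(list(data_type = data_type, columns = columns, rows = rows),
            class = "pc_omics")
}

# ---------------------------------------------------------------------------
# Glyphs: positioned drawable rectangles. position = top-left corner, screen
# coordinates (y grows downward), real-valued layout units.

glyph_kinds <- c("metabolite-node", "enzyme-label", "gene-label",
                 "pathway-label", "pathway-box", "omics-grid", "omics-box")

#' Create a glyph (positioned drawable element)
#'
#' @param uid Unique id within a collage.
#' @param kind One of `metabolite-node`, `enzyme-label`, `gene-label`,
#'   `pathway-label`, `pathway-box`, `omics-grid`, `omics-box`.
#' @param ref_id Id of the underlying compound / reaction / pathway / entity.
#' @param x,y Top-left corner in layout units (y increases downward).
#' @param width,height Rectangle size; must be positive for every kind except
#'   the `omics-grid` container.
#' @param color Display color (hex string).
#' @param label_text Text content, or `""`.
#' @param visible Logical.
#' @param parent_uid Optional uid of the glyph this one is attached to
#'   (omics grids attach to their anchor glyph, omics boxes to their grid);
#'   attached glyphs move with their parent.
#' @return A plain list; glyph kind is carried in the `kind` field.
#' @export
make_glyph <- function(uid, kind, ref_id = "", x = 0, y = 0, width = 1,
                       height = 1, color = "#000000", label_text = "",
                       visible = TRUE, parent_uid = NULL) {
  kind <- match.arg(kind, glyph_kinds)
  if (kind != "omics-grid" && (width <= 0 || height <= 0))
    stop_user("glyph %s: width and height must be > 0", uid)
  g <- list(uid = as.character(uid), kind = kind,
            ref_id = as.character(ref_id),
            x = as.numeric(x), y = as.numeric(y),
            width = as.numeric(width), height = as.numeric(height),
            color = as.character(color), label_text = as.character(label_text),
            visible = isTRUE(visible))
  if (!is.null(parent_uid)) g$parent_uid <- as.character(parent_uid)
  g
}

#' Create an edge glyph
#'
#' @param uid Unique id within a collage.
#' @param kind `"reaction-edge"` or `"connection-edge"`.
#' @param source_uid,target_uid Glyph uids (must differ).
#' @param ref_id Reaction or compound id.
#' @param color Display color.
#' @param thickness Positive stroke width.
#' @param arrow `"none"`, `"forward"` or `"both"`.
#' @param curved Logical; side-metabolite stubs render as short curves.
#' @param primary Logical; `TRUE` for the main backbone edge of a reaction
#'   (flux overlays target primary edges only).
#' @return A plain list.
#' @export
make_edge <- function(uid, kind, source_uid, target_uid, ref_id = "",
                      color = "#000000", thickness = 1, arrow = "none",
                      curved = FALSE, primary = TRUE) {
  kind <- match.arg(kind, c("reaction-edge", "connection-edge"))
  arrow <- match.arg(arrow, c("none", "forward", "both"))
  if (identical(source_uid, target_uid))
    stop_user("edge %s: source and target must differ", uid)
  if (thickness <= 0) stop_user("edge %s: thickness must be > 0", uid)
  list(uid = as.character(uid), kind = kind,
       source_uid = as.character(source_uid),
       target_uid = as.character(target_uid),
       ref_id = as.character(ref_id), color = as.character(color),
       thickness = as.numeric(thickness), arrow = arrow,
       curved = isTRUE(curved), primary = isTRUE(primary))
}

# ---------------------------------------------------------------------------
# Validation. Violations are data, not exceptions: one record per breach.

violation <- function(entity, rule, message) {
  data.frame(entity = entity, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(entity = character(), rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a pathway collection
#'
#' Checks every domain-type invariant: compound id uniqueness, reaction
#' participant structure (>= 1 substrate and product, >= 1 `main` on each
#' side, positive coefficients, declared compound references), reaction-id
#' uniqueness within a pathway, and link-graph integrity (links reference
#' existing reactions; the link graph is weakly connected when the pathway
#' has >= 2 reactions). Side-effect free and idempotent.
#'
#' @param collection A [pathway_collection()].
#' @return A data frame with columns `entity`, `rule`, `message`; zero rows
#'   iff the collection is valid.
#' @export
validate_collection <- function(collection) {
  v <- list(no_violations())
  cids <- vapply(collection$compounds, function(cp) cp$id, "")
  if (any(!nzchar(cids)))
    v[[length(v) + 1L]] <- violation("<compound>", "compound-id-nonempty",
                                     "compound with empty id")
  dup <- unique(cids[duplicated(cids)])
  for (d in dup)
    v[[length(v) + 1L]] <- violation(d, "compound-id-unique",
                                     sprintf("compound id '%s' declared more than once", d))
  declared <- unique(cids)

  for (pw in collection$pathways) {
    rids <- vapply(pw$reactions, function(r) r$id, "")
    dupr <- unique(rids[duplicated(rids)])
    for (d in dupr)
      v[[length(v) + 1L]] <- violation(pw$id, "reaction-id-unique",
                                       sprintf("pathway '%s': duplicate reaction id '%s'", pw$id, d))
    for (r in pw$reactions) {
      sides <- vapply(r$participants, function(p) p$side, "")
      roles <- vapply(r$participants, function(p) p$role, "")
      coefs <- vapply(r$participants, function(p) p$coefficient, 1)
      pcids <- vapply(r$participants, function(p) p$compound_id, "")
      if (!any(sides == "substrate"))
        v[[length(v) + 1L]] <- violation(r$id, "reaction-has-substrate",
                                         sprintf("reaction '%s' has no substrate participant", r$id))
      if (!any(sides == "product"))
        v[[length(v) + 1L]] <- violation(r$id, "reaction-has-product",
                                         sprintf("reaction '%s' has no product participant", r$id))
      if (any(sides == "substrate") && !any(sides == "substrate" & roles == "main"))
        v[[length(v) + 1L]] <- violation(r$id, "reaction-main-substrate",
                                         sprintf("reaction '%s' has no main substrate", r$id))
      if (any(sides == "product") && !any(sides == "product" & roles == "main"))
        v[[length(v) + 1L]] <- violation(r$id, "reaction-main-product",
                                         sprintf("reaction '%s' has no main product", r$id))
      if (any(coefs <= 0))
        v[[length(v) + 1L]] <- violation(r$id, "coefficient-positive",
                                         sprintf("reaction '%s' has a non-positive coefficient", r$id))
      for (u in setdiff(unique(pcids), declared))
        v[[length(v) + 1L]] <- violation(r$id, "compound-declared",
                                         sprintf("reaction '%s' references undeclared compound '%s'", r$id, u))
    }
    # link integrity + weak connectivity
    for (lk in pw$links) {
      for (end in lk) if (!(end %in% rids))
        v[[length(v) + 1L]] <- violation(pw$id, "link-refs-reaction",
                                         sprintf("pathway '%s': link references unknown reaction '%s'", pw$id, end))
    }
    if (length(pw$reactions) >= 2) {
      ok_links <- Filter(function(lk) all(lk %in% rids), pw$links)
      g <- link_graph(rids, ok_links)
      if (igraph::components(g, mode = "weak")$no > 1)
        v[[length(v) + 1L]] <- violation(pw$id, "links-weakly-connected",
                                         sprintf("pathway '%s': link graph is not weakly connected", pw$id))
    }
  }
  do.call(rbind, v)
}

# directed igraph over reaction ids
link_graph <- function(reaction_ids, links) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(reaction_ids), name = reaction_ids)
  if (length(links)) {
    el <- do.call(rbind, lapply(links, function(lk) lk[1:2]))
    g <- igraph::add_edges(g, t(matrix(match(el, reaction_ids),
                                       ncol = 2)))
  }
  g
}

# lookup helpers -------------------------------------------------------------

find_compound <- function(collection, id) {
  for (cp in collection$compounds) if (cp$id == id) return(cp)
  NULL
}

find_pathway <- function(collection, id) {
  for (pw in collection$pathways) if (pw$id == id) return(pw)
  NULL
}

find_reaction <- function(pathway, id) {
  for (r in pathway$reactions) if (r$id == id) return(r)
  NULL
}

participants_of <- function(r, side, role = NULL) {
  out <- Filter(function(p) p$side == side &&
                  (is.null(role) || p$role == role), r$participants)
  sort(vapply(out, function(p) p$compound_id, ""))
}

#' @export
print.pc_collection <- function(x, ...) {
  cat(sprintf("pathway collection (schema %s): %d compounds, %d pathways\n",
              x$schema_version, length(x$compounds), length(x$pathways)))
  invisible(x)
}

#' @export
print.pc_pathway <- function(x, ...) {
  cat(sprintf("pathway '%s' (%s): %d reactions, %d links\n", x$id, x$name,
              length(x$reactions), length(x$links)))
  invisible(x)
}
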