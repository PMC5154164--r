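# Automatic layout of one pathway. Geometry rules (all constants in
# layout_config()):
#   linear   -> backbone nodes equally spaced on a vertical line
#   cyclic   -> backbone nodes equally spaced on a circle, first node at
#               12 o'clock, order clockwise
#   branched -> layered top-down tree, branch arms offset horizontally
# Layout is fully deterministic: no randomness anywhere.

#' Classify the topology of a pathway's link graph
#'
#' @param pw A [pathway()].
#' @return `"cyclic"` if the reaction link graph contains a directed cycle;
#'   `"linear"` if it is acyclic and every reaction has at most one
#'   predecessor and one successor; `"branched"` otherwise.
#' @export
classify_topology <- function(pw) {
  rids <- vapply(pw$reactions, function(r) r$id, "")
  g <- link_graph(rids, pw$links)
  if (!igraph::is_dag(g)) return("cyclic")
  if (all(igraph::degree(g, mode = "in") <= 1) &&
      all(igraph::degree(g, mode = "out") <= 1)) return("linear")
  "branched"
}

main_subs <- function(r) participants_of(r, "substrate", "main")
main_prods <- function(r) participants_of(r, "product", "main")

# compound occurrence shared between consecutive chain reactions p -> s:
# a main product of p that is also a main substrate of s, else p's first
# main product (lexicographic). Deterministic.
chain_between <- function(p, s) {
  shared <- intersect(main_prods(p), main_subs(s))
  if (length(shared)) sort(shared)[1] else main_prods(p)[1]
}

#' Extract the main-compound backbone of a pathway
#'
#' The backbone is the ordered chain of main compounds along the pathway's
#' principal axis. For a linear pathway it follows the link order; for a
#' cyclic pathway it is the directed cycle's compounds, rotated so the
#' lexicographically smallest compound id comes first, following link
#' direction; for a branched pathway it follows the longest directed reaction
#' path (ties broken lexicographically by the concatenated reaction ids).
#'
#' @param pw A [pathway()].
#' @return A list with `compounds` (ordered character vector of compound
#'   ids, one per backbone occurrence), `reactions` (the backbone reaction
#'   chain) and `topology`.
#' @export
extract_backbone <- function(pw) {
  topo <- classify_topology(pw)
  rids <- vapply(pw$reactions, function(r) r$id, "")
  rx <- setNames(pw$reactions, rids)
  g <- link_graph(rids, pw$links)

  if (topo == "cyclic") {
    chain <- find_directed_cycle(g, rids)
    k <- length(chain)
    # occurrence i sits between chain[i-1] and chain[i] (cyclically), i.e.
    # it is the input occurrence of reactions[i]
    comps <- vapply(seq_len(k), function(i) {
      prev <- chain[if (i == 1) k else i - 1]
      chain_between(rx[[prev]], rx[[chain[i]]])
    }, "")
    rot <- which(comps == sort(comps)[1])[1]
    idx <- ((seq_len(k) + rot - 2) %% k) + 1
    return(list(compounds = comps[idx], reactions = chain[idx],
                topology = topo))
  }

  chain <- if (topo == "linear") {
    start <- rids[igraph::degree(g, mode = "in") == 0]
    if (length(start) != 1 && length(rids) > 1)
      stop_user("pathway '%s': cannot resolve a backbone chain", pw$id)
    cur <- if (length(rids) == 1) rids else start
    out <- cur
    repeat {
      nxt <- succ_ids(g, cur, rids)
      if (length(nxt) == 0) break
      cur <- nxt[1]
      out <- c(out, cur)
    }
    out
  } else {
    longest_dag_path(g, rids)
  }
  if (length(chain) == 0)
    stop_user("pathway '%s': cannot resolve a backbone chain", pw$id)

  comps <- main_subs(rx[[chain[1]]])[1]
  if (length(chain) >= 2) {
    for (i in seq_len(length(chain) - 1))
      comps <- c(comps, chain_between(rx[[chain[i]]], rx[[chain[i + 1]]]))
  }
  comps <- c(comps, main_prods(rx[[chain[length(chain)]]])[1])
  if (anyNA(comps))
    stop_user("pathway '%s': cannot resolve a backbone chain", pw$id)
  list(compounds = comps, reactions = chain, topology = topo)
}

succ_ids <- function(g, rid, rids) {
  nb <- igraph::neighbors(g, rid, mode = "out")
  sort(rids[as.integer(nb)])
}

pred_ids <- function(g, rid, rids) {
  nb <- igraph::neighbors(g, rid, mode = "in")
  sort(rids[as.integer(nb)])
}

# Deterministic directed cycle: pick the non-trivial strongly connected
# component containing the smallest reaction id, walk from that id choosing
# the smallest in-component successor until revisiting the start.
find_directed_cycle <- function(g, rids) {
  sc <- igraph::components(g, mode = "strong")
  sizes <- tabulate(sc$membership, nbins = sc$no)
  nontriv <- which(sizes > 1)
  # self-loop members count as their own cycle
  if (length(nontriv) == 0) {
    for (rid in sort(rids)) {
      if (rid %in% succ_ids(g, rid, rids)) return(rid)
    }
    stop_user("no directed cycle found")
  }
  members <- rids[sc$membership %in% nontriv]
  start <- sort(members)[1]
  comp <- sc$membership[match(start, rids)]
  in_comp <- rids[sc$membership == comp]
  chain <- start
  cur <- start
  repeat {
    nxt <- intersect(succ_ids(g, cur, rids), in_comp)
    nxt <- setdiff(nxt, setdiff(chain, start))
    if (length(nxt) == 0) stop_user("no directed cycle found")
    if (start %in% nxt) break
    cur <- nxt[1]
    chain <- c(chain, cur)
  }
  chain
}

# Longest directed path in a DAG; ties broken by the lexicographically
# smallest concatenation of reaction ids along the path.
longest_dag_path <- function(g, rids) {
  ord <- rids[as.integer(igraph::topo_sort(g, mode = "out"))]
  best <- setNames(vector("list", length(rids)), rids)
  for (v in ord) {
    cand <- list(v)
    for (u in pred_ids(g, v, rids)) cand[[length(cand) + 1L]] <- c(best[[u]], v)
    lens <- vapply(cand, length, 1L)
    cand <- cand[lens == max(lens)]
    keys <- vapply(cand, function(p) paste(p, collapse = "\x01"), "")
    best[[v]] <- cand[[order(keys)[1]]]
  }
  lens <- vapply(best, length, 1L)
  finals <- best[lens == max(lens)]
  keys <- vapply(finals, function(p) paste(p, collapse = "\x01"), "")
  finals[[order(keys)[1]]]
}

# ---------------------------------------------------------------------------
# Occurrence model: every drawn metabolite node is one "occurrence" of a
# compound. Chain reactions share occurrences; off-chain reactions attach to
# existing occurrences by compound id or create new ones.

build_occurrences <- function(pw, bb) {
  rids <- vapply(pw$reactions, function(r) r$id, "")
  rx <- setNames(pw$reactions, rids)
  cyclic <- bb$topology == "cyclic"
  k <- length(bb$reactions)

  occs <- lapply(seq_along(bb$compounds), function(i)
    list(compound_id = bb$compounds[i], backbone = TRUE))
  rxn_map <- list()
  for (i in seq_len(k)) {
    rxn_map[[bb$reactions[i]]] <-
      if (cyclic) c(i, i %% k + 1) else c(i, i + 1)
  }

  new_occ <- function(cid) {
    occs[[length(occs) + 1L]] <<- list(compound_id = cid, backbone = FALSE)
    length(occs)
  }
  occ_matching <- function(cids, exclude = integer()) {
    hits <- which(vapply(occs, function(o) o$compound_id %in% cids, TRUE))
    hits <- setdiff(hits, exclude)
    if (length(hits) == 0) return(NA_integer_)
    bb_hits <- hits[vapply(hits, function(i) occs[[i]]$backbone, TRUE)]
    if (length(bb_hits)) bb_hits[1] else hits[1]
  }

  for (rid in sort(setdiff(rids, bb$reactions))) {
    r <- rx[[rid]]
    i_in <- occ_matching(main_subs(r))
    if (is.na(i_in)) i_in <- new_occ(main_subs(r)[1])
    i_out <- occ_matching(main_prods(r), exclude = i_in)
    if (is.na(i_out)) i_out <- new_occ(main_prods(r)[1])
    rxn_map[[rid]] <- c(i_in, i_out)
  }

  # auxiliary main participants: extra mains beyond the chain occurrences
  aux <- list()
  for (rid in names(rxn_map)) {
    r <- rx[[rid]]
    io <- rxn_map[[rid]]
    for (cid in setdiff(main_subs(r), occs[[io[1]]]$compound_id)) {
      j <- new_occ(cid)
      aux[[length(aux) + 1L]] <- list(rid = rid, side = "substrate", occ = j)
    }
    for (cid in setdiff(main_prods(r), occs[[io[2]]]$compound_id)) {
      j <- new_occ(cid)
      aux[[length(aux) + 1L]] <- list(rid = rid, side = "product", occ = j)
    }
  }
  list(occs = occs, rxn_map = rxn_map, aux = aux)
}

# longest-path depth in the occurrence graph, robust to (pathological)
# cycles by capping relaxation passes
occ_depths <- function(n, edges) {
  depth <- rep(0, n)
  if (length(edges) == 0 || n == 0) return(depth)
  for (pass in seq_len(n + 1)) {
    changed <- FALSE
    for (e in edges) {
      if (depth[e[2]] < depth[e[1]] + 1) {
        depth[e[2]] <- depth[e[1]] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  depth
}

#' Lay out a single pathway
#'
#' Produces one metabolite-node glyph per main-compound occurrence, one
#' reaction edge per backbone step (arrow per reaction direction), enzyme and
#' gene labels beside each reaction edge, a pathway label and a pathway
#' background box. Side metabolites are excluded (add them afterwards with
#' [add_side_metabolites()]). No two non-container glyph rectangles overlap.
#'
#' @param pw A valid [pathway()].
#' @param style A [style_config()].
#' @param config A [layout_config()].
#' @return A `pc_layout`: list with `pathway_id`, `glyphs` (named by uid),
#'   `edges` (named by uid), `bbox`, `backbone` (ordered metabolite-node
#'   uids) and `reaction_info`.
#' @export
layout_pathway <- function(pw, style = style_config(),
                           config = layout_config()) {
  bb <- extract_backbone(pw)
  occ <- build_occurrences(pw, bb)
  occs <- occ$occs
  rxn_map <- occ$rxn_map
  d <- config$node_diameter
  sp <- config$spacing
  n_bb <- length(bb$compounds)
  bb_idx <- seq_len(n_bb)
  centers <- matrix(NA_real_, nrow = length(occs), ncol = 2)

  if (bb$topology == "cyclic") {
    R <- sp * n_bb / (2 * pi)
    cx <- R + d; cy <- R + d
    th <- (bb_idx - 1) * 2 * pi / n_bb
    centers[bb_idx, 1] <- cx + R * sin(th)
    centers[bb_idx, 2] <- cy - R * cos(th)
    extras <- setdiff(seq_along(occs), bb_idx)
    for (j in seq_along(extras))
      centers[extras[j], ] <- c(2 * R + 2 * d + j * config$arm_dx, cy)
  } else {
    edges <- lapply(names(rxn_map), function(rid) rxn_map[[rid]])
    depth <- occ_depths(length(occs), edges)
    cx0 <- d
    for (dep in sort(unique(depth))) {
      at <- which(depth == dep)
      bb_at <- intersect(at, bb_idx)
      others <- sort(setdiff(at, bb_idx))
      for (i in bb_at) centers[i, ] <- c(cx0, d + dep * sp)
      for (j in seq_along(others))
        centers[others[j], ] <- c(cx0 + j * config$arm_dx, d + dep * sp)
    }
  }

  pid <- pw$id
  glyphs <- list()
  met_uid <- function(i) sprintf("%s::met::%d", pid, i)
  for (i in seq_along(occs)) {
    uid <- met_uid(i)
    glyphs[[uid]] <- make_glyph(uid, "metabolite-node",
                                ref_id = occs[[i]]$compound_id,
                                x = centers[i, 1] - d / 2,
                                y = centers[i, 2] - d / 2,
                                width = d, height = d,
                                color = style$colors[["metabolite-node"]],
                                label_text = occs[[i]]$compound_id)
  }

  # reaction edges + labels ------------------------------------------------
  rids <- vapply(pw$reactions, function(r) r$id, "")
  rx <- setNames(pw$reactions, rids)
  edge_list <- list()
  reaction_info <- list()
  label_uids <- character(); label_dirs <- list()
  if (bb$topology == "cyclic") {
    R <- sp * n_bb / (2 * pi); circ_c <- c(R + d, R + d)
  }
  ordered_rids <- c(bb$reactions, sort(setdiff(rids, bb$reactions)))
  for (rid in ordered_rids) {
    io <- rxn_map[[rid]]
    r <- rx[[rid]]
    src <- met_uid(io[1]); dst <- met_uid(io[2])
    euid <- sprintf("%s::rxn::%s", pid, rid)
    edge_list[[euid]] <- make_edge(euid, "reaction-edge", src, dst,
                                   ref_id = rid,
                                   color = style$colors[["reaction-edge"]],
                                   thickness = style$edge_thickness,
                                   arrow = if (r$direction == "reversible")
                                     "both" else "forward")
    reaction_info[[rid]] <- list(gene_ids = r$gene_ids,
                                 enzyme_labels = r$enzyme_labels,
                                 direction = r$direction,
                                 in_uid = src, out_uid = dst)
    mid <- (centers[io[1], ] + centers[io[2], ]) / 2
    if (bb$topology == "cyclic") {
      v <- mid - circ_c
      nv <- sqrt(sum(v^2))
      dir <- if (nv < 1e-9) c(1, 0) else v / nv
    } else dir <- c(1, 0)
    anchor <- mid + dir * (d / 2 + config$label_gap)
    mk_label <- function(kind, text, dy) {
      fs <- style$font_sizes[[kind]]
      w <- est_text_width(text, fs, config)
      h <- fs * 1.2
      uid <- sprintf("%s::%s::%s", pid,
                     if (kind == "enzyme-label") "enz" else "gene", rid)
      x <- if (dir[1] < 0) anchor[1] - w else anchor[1]
      glyphs[[uid]] <<- make_glyph(uid, kind, ref_id = rid, x = x,
                                   y = anchor[2] + dy, width = w, height = h,
                                   color = style$colors[[kind]],
                                   label_text = text)
      label_uids <<- c(label_uids, uid)
      label_dirs[[length(label_dirs) + 1L]] <<- dir
    }
    if (length(r$enzyme_labels))
      mk_label("enzyme-label", paste(r$enzyme_labels, collapse = ", "),
               dy = -style$font_sizes[["enzyme-label"]] * 1.2 - 1)
    if (length(r$gene_ids))
      mk_label("gene-label", paste(r$gene_ids, collapse = ", "), dy = 1)
  }

  # auxiliary main-participant stubs ---------------------------------------
  for (a in occ$aux) {
    io <- rxn_map[[a$rid]]
    side_uid <- met_uid(a$occ)
    main_uid <- met_uid(if (a$side == "substrate") io[2] else io[1])
    euid <- sprintf("%s::aux::%s::%s", pid, a$rid,
                    occs[[a$occ]]$compound_id)
    edge_list[[euid]] <- make_edge(
      euid, "reaction-edge",
      source_uid = if (a$side == "substrate") side_uid else main_uid,
      target_uid = if (a$side == "substrate") main_uid else side_uid,
      ref_id = a$rid, color = style$colors[["reaction-edge"]],
      thickness = style$edge_thickness * 0.7, arrow = "none",
      curved = TRUE, primary = FALSE)
  }

  # de-overlap labels (nodes are fixed by construction)
  node_rects <- lapply(glyphs[vapply(glyphs, function(g)
    g$kind == "metabolite-node", TRUE)], glyph_rect)
  if (length(label_uids)) {
    ord <- order(label_uids)
    glyphs <- resolve_overlaps(glyphs, label_uids[ord], label_dirs[ord],
                               node_rects)
  }

  # pathway label + background box -----------------------------------------
  content <- rect_union(lapply(glyphs, glyph_rect))
  fs <- style$font_sizes[["pathway-label"]]
  lab_uid <- sprintf("%s::label", pid)
  glyphs[[lab_uid]] <- make_glyph(lab_uid, "pathway-label", ref_id = pid,
                                  x = content[1],
                                  y = content[2] - fs * 1.4 - config$label_gap,
                                  width = est_text_width(pw$name, fs, config),
                                  height = fs * 1.4,
                                  color = style$colors[["pathway-label"]],
                                  label_text = pw$name)
  allr <- rect_union(lapply(glyphs, glyph_rect))
  pad <- config$box_pad
  box_uid <- sprintf("%s::box", pid)
  glyphs[[box_uid]] <- make_glyph(box_uid, "pathway-box", ref_id = pid,
                                  x = allr[1] - pad, y = allr[2] - pad,
                                  width = allr[3] - allr[1] + 2 * pad,
                                  height = allr[4] - allr[2] + 2 * pad,
                                  color = style$colors[["pathway-box"]])

  structure(list(pathway_id = pid, glyphs = glyphs, edges = edge_list,
                 bbox = rect_union(lapply(glyphs, glyph_rect)),
                 backbone = vapply(bb_idx, met_uid, ""),
                 reaction_info = reaction_info),
            class = "pc_layout")
}

#' Add side metabolites to a laid-out pathway
#'
#' Side (currency) metabolites are excluded from the automatic layout; this
#' adds them back, either for one reaction (`reaction_id`: one new node per
#' side participant of that reaction) or for one compound (`compound_id`: one
#' new node per reaction in which the compound has role `side` — it is added
#' everywhere it appears as a side metabolite). New nodes are offset
#' perpendicular to the reaction edge — side substrates on the incoming half,
#' side products on the outgoing half — joined by a short curved stub, and
#' slide along the perpendicular to avoid overlaps. Idempotent.
#'
#' @param layout A `pc_layout` produced by [layout_pathway()].
#' @param pw The pathway the layout was built from.
#' @param reaction_id,compound_id Exactly one must be given.
#' @param style,config Style and geometry settings.
#' @return The updated layout.
#' @export
add_side_metabolites <- function(layout, pw, reaction_id = NULL,
                                 compound_id = NULL, style = style_config(),
                                 config = layout_config()) {
  if (is.null(reaction_id) == is.null(compound_id))
    stop_user("give exactly one of reaction_id / compound_id")
  targets <- list()  # list of (rid, compound_id, side)
  if (!is.null(reaction_id)) {
    r <- find_reaction(pw, reaction_id)
    if (is.null(r)) stop_user("unknown reaction id '%s'", reaction_id)
    for (p in r$participants) if (p$role == "side")
      targets[[length(targets) + 1L]] <- list(rid = r$id,
                                              cid = p$compound_id,
                                              side = p$side)
  } else {
    seen <- FALSE
    for (r in pw$reactions) for (p in r$participants) {
      if (p$compound_id == compound_id) {
        seen <- TRUE
        if (p$role == "side")
          targets[[length(targets) + 1L]] <- list(rid = r$id,
                                                  cid = p$compound_id,
                                                  side = p$side)
      }
    }
    if (!seen) stop_user("unknown compound id '%s'", compound_id)
  }
  if (length(targets) == 0) return(layout)

  d <- config$node_diameter
  pid <- layout$pathway_id
  new_uids <- character(); new_dirs <- list()
  for (tg in targets) {
    uid <- sprintf("%s::side::%s::%s", pid, tg$rid, tg$cid)
    if (!is.null(layout$glyphs[[uid]])) next  # idempotent
    info <- layout$reaction_info[[tg$rid]]
    a <- glyph_center(layout$glyphs[[info$in_uid]])
    b <- glyph_center(layout$glyphs[[info$out_uid]])
    v <- b - a
    nv <- sqrt(sum(v^2)); if (nv < 1e-9) v <- c(0, 1) else v <- v / nv
    perp <- c(-v[2], v[1])
    t0 <- if (tg$side == "substrate") 0.3 else 0.7
    ctr <- a + (b - a) * t0 + perp * config$side_offset
    layout$glyphs[[uid]] <- make_glyph(uid, "metabolite-node",
                                       ref_id = tg$cid,
                                       x = ctr[1] - d / 2, y = ctr[2] - d / 2,
                                       width = d, height = d,
                                       color = style$colors[["metabolite-node"]],
                                       label_text = tg$cid)
    new_uids <- c(new_uids, uid)
    new_dirs[[length(new_dirs) + 1L]] <- perp
    euid <- sprintf("%s::sideedge::%s::%s", pid, tg$rid, tg$cid)
    layout$edges[[euid]] <- make_edge(
      euid, "reaction-edge",
      source_uid = if (tg$side == "substrate") uid else info$in_uid,
      target_uid = if (tg$side == "substrate") info$out_uid else uid,
      ref_id = tg$rid, color = style$colors[["reaction-edge"]],
      thickness = style$edge_thickness * 0.7, arrow = "none",
      curved = TRUE, primary = FALSE)
  }
  if (length(new_uids)) {
    fixed <- lapply(layout$glyphs[setdiff(names(layout$glyphs), new_uids)],
                    glyph_rect)
    fixed <- fixed[vapply(setdiff(names(layout$glyphs), new_uids),
                          function(u) !(layout$glyphs[[u]]$kind %in%
                                          container_kinds), TRUE)]
    layout$glyphs <- resolve_overlaps(layout$glyphs, new_uids, new_dirs,
                                      fixed)
    layout$bbox <- layout_bbox(layout)
  }
  layout
}
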