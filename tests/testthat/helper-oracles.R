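# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately brute-force and share no code with the package
# internals they check.

# --- rectangle overlap oracle (all pairs, non-container glyphs) ------------

glyph_rects_oracle <- function(layout, offset = c(0, 0)) {
  gs <- Filter(function(g)
    !(g$kind %in% c("pathway-box", "omics-grid", "omics-box")),
    layout$glyphs)
  lapply(gs, function(g) c(g$x + offset[1], g$y + offset[2],
                           g$x + offset[1] + g$width,
                           g$y + offset[2] + g$height))
}

count_overlaps_oracle <- function(rects) {
  n <- length(rects)
  bad <- 0L
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- rects[[i]]; b <- rects[[j]]
    if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
      bad <- bad + 1L
  }
  bad
}

# minimum separation between two bboxes (negative if they overlap)
bbox_separation <- function(a, b) {
  max(b[1] - a[3], a[1] - b[3], b[2] - a[4], a[2] - b[4])
}

collage_layout_bboxes <- function(cg) {
  lapply(cg$layouts, function(pl) {
    b <- layout_bbox(pl$layout)
    c(b[1] + pl$offset[1], b[2] + pl$offset[2],
      b[3] + pl$offset[1], b[4] + pl$offset[2])
  })
}

# --- brute-force Euclidean MST oracle (edge-subset enumeration, k <= 6) ----

brute_mst_total <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  pairs <- t(utils::combn(n, 2))
  lens <- sqrt(rowSums((pts[pairs[, 1], , drop = FALSE] -
                          pts[pairs[, 2], , drop = FALSE])^2))
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # union-find connectivity check
    parent <- seq_len(n)
    root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in sel) {
      a <- root(pairs[k, 1]); b <- root(pairs[k, 2])
      parent[a] <- b
    }
    if (length(unique(vapply(seq_len(n), root, 1L))) == 1)
      best <- min(best, sum(lens[sel]))
  }
  best
}

# --- maximal simple directed path enumeration (backbone tie-break oracle) --

all_maximal_link_paths <- function(pw) {
  rids <- vapply(pw$reactions, function(r) r$id, "")
  succ <- setNames(lapply(rids, function(x) character()), rids)
  has_pred <- setNames(rep(FALSE, length(rids)), rids)
  for (lk in pw$links) {
    succ[[lk[1]]] <- c(succ[[lk[1]]], lk[2])
    has_pred[[lk[2]]] <- TRUE
  }
  out <- list()
  walk <- function(path) {
    nxt <- setdiff(succ[[path[length(path)]]], path)
    if (length(nxt) == 0) out[[length(out) + 1L]] <<- path
    else for (s in sort(nxt)) walk(c(path, s))
  }
  for (r in rids[!has_pred]) walk(r)
  if (length(out) == 0) out <- as.list(rids)
  out
}

# --- tiny hand-built fixtures ----------------------------------------------

mk_rxn <- function(id, sub, prod, sides = list(), dir = "forward",
                   enz = paste0("E", id), genes = paste0("g", id)) {
  parts <- c(list(reaction_participant(sub, "substrate"),
                  reaction_participant(prod, "product")), sides)
  reaction(id, parts, dir, enzyme_labels = enz, gene_ids = genes)
}

# linear chain pathway over the given compound sequence
chain_pw <- function(id = "P1", comps = c("A", "B", "C", "D"),
                     class_path = c("Biosynthesis")) {
  n <- length(comps) - 1
  rx <- lapply(seq_len(n), function(i)
    mk_rxn(paste0(id, "-r", i), comps[i], comps[i + 1]))
  links <- if (n >= 2) lapply(seq_len(n - 1), function(i)
    c(paste0(id, "-r", i), paste0(id, "-r", i + 1))) else list()
  pathway(id, rx, links, class_path = class_path)
}

cycle_pw <- function(id = "CY", comps = c("C1", "C2", "C3", "C4"),
                     class_path = c("Generation of Precursor Metabolites and Energy")) {
  n <- length(comps)
  rx <- lapply(seq_len(n), function(i)
    mk_rxn(paste0(id, "-r", i), comps[i], comps[i %% n + 1]))
  links <- lapply(seq_len(n), function(i)
    c(paste0(id, "-r", i), paste0(id, "-r", i %% n + 1)))
  pathway(id, rx, links, class_path = class_path)
}

collection_for <- function(pws) {
  cids <- sort(unique(unlist(lapply(pws, function(pw)
    lapply(pw$reactions, function(r)
      vapply(r$participants, function(p) p$compound_id, ""))))))
  pathway_collection(lapply(cids, compound), pws)
}

# assembled collage from hand-built pathways
collage_of <- function(pws, max_width = 2000, gap = 30) {
  lays <- lapply(pws, layout_pathway)
  assemble_collage(lays, pws, max_width = max_width, gap = gap)
}

# uids of metabolite nodes for a compound, in stable order
nodes_of <- function(cg, cid) {
  out <- character()
  for (pl in cg$layouts) for (g in pl$layout$glyphs)
    if (g$kind == "metabolite-node" && g$ref_id == cid)
      out <- c(out, g$uid)
  out
}

all_glyphs_flat <- function(cg) {
  out <- list()
  for (pl in cg$layouts) out <- c(out, pl$layout$glyphs)
  out
}

# edge lookup by uid across all layouts (placement order is not input order)
get_edge <- function(cg, uid) {
  for (pl in cg$layouts)
    if (!is.null(pl$layout$edges[[uid]])) return(pl$layout$edges[[uid]])
  cg$connections[[uid]]
}

all_edges_flat <- function(cg) {
  out <- list()
  for (pl in cg$layouts) out <- c(out, pl$layout$edges)
  c(out, cg$connections)
}

# standard diverging test scheme
test_scheme <- function() {
  color_scheme(c(-2, -1, 0, 1, 2),
               c("#2166ac", "#67a9cf", "#d1e5f0", "#fddbc7", "#ef8a62",
                 "#b2182b"))
}

# parse PNG IHDR dimensions straight from the file bytes
png_dims <- function(path) {
  b <- readBin(path, "raw", 32)
  c(sum(as.integer(b[17:20]) * 256^(3:0)),
    sum(as.integer(b[21:24]) * 256^(3:0)))
}
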