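test_that("category mapping follows the keyword table", {
  expect_identical(category_of(pathway("p", list(mk_rxn("r", "A", "B")),
                                       class_path = c("Biosynthesis",
                                                      "Amino Acids"))),
                   "biosynthesis")
  expect_identical(category_of(pathway("p", list(mk_rxn("r", "A", "B")),
                                       class_path = "Degradation/Utilization/Assimilation")),
                   "degradation")
  expect_identical(category_of(pathway("p", list(mk_rxn("r", "A", "B")),
                                       class_path = "Generation of Precursor Metabolites and Energy")),
                   "energy")
  expect_identical(category_of(pathway("p", list(mk_rxn("r", "A", "B")))),
                   "other")
})

test_that("single pathway gets margin offsets; bbox = layout bbox + margins", {
  pw <- chain_pw("P1")
  lay <- layout_pathway(pw)
  cg <- assemble_collage(list(lay), list(pw), max_width = 1200, gap = 30)
  bb <- collage_bbox(cg)
  lb <- layout_bbox(lay)
  expect_equal(bb[1], 30)
  expect_equal(bb[2], 30)
  expect_equal(bb[3] - bb[1], lb[3] - lb[1])
  expect_equal(bb[4] - bb[2], lb[4] - lb[2])
})

test_that("biosynthesis places strictly left of degradation", {
  bio <- chain_pw("BIO", c("A", "B", "C"), class_path = "Biosynthesis")
  deg <- chain_pw("DEG", c("X", "Y", "Z"),
                  class_path = "Degradation/Utilization/Assimilation")
  # order of the input list must not matter
  for (pws in list(list(bio, deg), list(deg, bio))) {
    cg <- collage_of(pws)
    bbs <- collage_layout_bboxes(cg)
    pids <- vapply(cg$layouts, function(pl) pl$layout$pathway_id, "")
    expect_lt(bbs[[which(pids == "BIO")]][3],
              bbs[[which(pids == "DEG")]][1])
  }
})

test_that("shelf packing wraps rows, keeps gaps, respects max_width", {
  pws <- lapply(1:5, function(i)
    chain_pw(sprintf("P%d", i), c(sprintf("a%d", i), sprintf("b%d", i),
                                  sprintf("c%d", i)),
             class_path = "Biosynthesis"))
  lays <- lapply(pws, layout_pathway)
  w <- max(vapply(lays, function(l) layout_bbox(l)[3] - layout_bbox(l)[1], 0))
  gap <- 20
  max_width <- ceiling(2 * w + 3 * gap + 10)  # forces > 1 row for 5 layouts
  cg <- assemble_collage(lays, pws, max_width = max_width, gap = gap)
  bbs <- collage_layout_bboxes(cg)
  ys <- vapply(bbs, function(b) b[2], 0)
  expect_gt(length(unique(round(ys, 6))), 1)  # wrapped to >= 2 rows
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(bbox_separation(bbs[[i]], bbs[[j]]), gap - 1e-9)
  expect_lte(max(vapply(bbs, function(b) b[3], 0)), max_width)
  # deterministic
  cg2 <- assemble_collage(lays, pws, max_width = max_width, gap = gap)
  expect_true(collage_equal(cg, cg2))
})

test_that("assembly rejects an impossible max_width", {
  pw <- chain_pw("P1")
  lay <- layout_pathway(pw)
  w <- layout_bbox(lay)[3] - layout_bbox(lay)[1]
  expect_error(assemble_collage(list(lay), list(pw), max_width = w, gap = 30),
               "max_width")
})

test_that("connect_metabolite stars out to every other occurrence, idempotently", {
  pws <- list(chain_pw("P1", c("A", "X", "B")),
              chain_pw("P2", c("C", "X", "D")),
              chain_pw("P3", c("X", "E", "F")))
  cg <- collage_of(pws)
  xs <- nodes_of(cg, "X")
  expect_identical(length(xs), 3L)
  cg2 <- connect_metabolite(cg, xs[1])
  expect_identical(length(cg2$connections), 2L)  # k - 1 star edges
  # repeat call adds nothing
  cg3 <- connect_metabolite(cg2, xs[1])
  expect_true(collage_equal(cg2, cg3))
  # unique compound: no edges
  cg4 <- connect_metabolite(cg, nodes_of(cg, "A"))
  expect_identical(length(cg4$connections), 0L)
  expect_error(connect_metabolite(cg, "nope"), "unknown glyph")
  enz <- grep("::enz::", names(all_glyphs_flat(cg)), value = TRUE)[1]
  expect_error(connect_metabolite(cg, enz), "not a metabolite")
})

test_that("connect_all builds per-compound Euclidean MSTs", {
  pws <- list(chain_pw("P1", c("A", "X", "B")),
              chain_pw("P2", c("C", "X", "D")),
              chain_pw("P3", c("X", "E", "F")))
  cg <- connect_all(collage_of(pws))
  xs <- nodes_of(cg, "X")
  conns <- cg$connections
  expect_identical(length(conns), 2L)  # k - 1 edges for k = 3
  # all edges stay within the compound
  for (e in conns) expect_identical(e$ref_id, "X")
  # total length equals the brute-force minimum spanning tree
  pts <- t(vapply(xs, function(u) pathcollage:::abs_center(cg, u), c(0, 0)))
  total <- sum(vapply(conns, function(e) {
    a <- pathcollage:::abs_center(cg, e$source_uid)
    b <- pathcollage:::abs_center(cg, e$target_uid)
    sqrt(sum((a - b)^2))
  }, 0))
  expect_equal(total, brute_mst_total(pts), tolerance = 1e-9)
  # no shared compounds: unchanged
  cg0 <- collage_of(list(chain_pw("Q1", c("a", "b")),
                         chain_pw("Q2", c("c", "d"))))
  expect_true(collage_equal(cg0, connect_all(cg0)))
  # exclusion list honored
  cg_ex <- connect_all(collage_of(pws), exclude = "X")
  expect_identical(length(cg_ex$connections), 0L)
})

test_that("collinear occurrence geometry picks the short-link MST", {
  # three occurrences on a line at distances 1 and 4: the MST must use the
  # two short links, never the long (0,0)-(5,0) edge
  pws <- list(chain_pw("P1", c("A", "X", "B")),
              chain_pw("P2", c("C", "X", "D")),
              chain_pw("P3", c("X", "E", "F")))
  cg <- collage_of(pws)
  xs <- sort(nodes_of(cg, "X"))
  # move the three occurrences to controlled absolute positions
  pos <- list(c(0, 0), c(1, 0), c(5, 0))
  for (i in seq_along(xs)) {
    cur <- pathcollage:::abs_center(cg, xs[i])
    cg <- move_node(cg, xs[i], pos[[i]][1] - cur[1], pos[[i]][2] - cur[2])
  }
  cg <- connect_all(cg)
  ends <- lapply(cg$connections, function(e) sort(c(e$source_uid,
                                                    e$target_uid)))
  expect_true(list(sort(c(xs[1], xs[2]))) %in% ends ||
                any(vapply(ends, identical, TRUE, sort(c(xs[1], xs[2])))))
  expect_true(any(vapply(ends, identical, TRUE, sort(c(xs[2], xs[3])))))
  expect_false(any(vapply(ends, identical, TRUE, sort(c(xs[1], xs[3])))))
})

test_that("pathways_for_metabolite scans all roles and both sides", {
  sides <- list(reaction_participant("ATP", "substrate", "side"))
  pws <- list(chain_pw("P1", c("A", "X", "B")),
              chain_pw("P2", c("C", "D")),
              pathway("P3", list(mk_rxn("P3-r1", "E", "F", sides = sides))))
  coll <- collection_for(pws)
  expect_identical(pathways_for_metabolite("X", coll), "P1")
  # side-only participation still counts
  expect_identical(pathways_for_metabolite("ATP", coll), "P3")
  # brute-force oracle over every reaction participant
  for (cid in c("A", "B", "C", "D", "E", "F", "X", "ATP")) {
    hits <- sort(unique(unlist(lapply(pws, function(pw) {
      found <- any(vapply(pw$reactions, function(r)
        any(vapply(r$participants, function(p) p$compound_id == cid, TRUE)),
        TRUE))
      if (found) pw$id else character()
    }))))
    expect_identical(pathways_for_metabolite(cid, coll), hits)
  }
  expect_error(pathways_for_metabolite("missing", coll), "unknown compound")
})

test_that("added pathways land below the collage, left-aligned", {
  p1 <- chain_pw("P1"); p2 <- chain_pw("P2", c("E", "F", "G"))
  cg <- collage_of(list(p1, p2))
  bb0 <- collage_bbox(cg)
  p3 <- chain_pw("P3", c("H", "I"))
  cg2 <- add_pathway_to_collage(cg, layout_pathway(p3), gap = 30)
  bbs <- collage_layout_bboxes(cg2)
  expect_equal(bbs[[3]][2], bb0[4] + 30)
  expect_equal(bbs[[3]][1], bb0[1])
  expect_true(all(vapply(bbs[1:2], function(b) b[4] < bbs[[3]][2], TRUE)))
  # sequential adds stack strictly downward
  p4 <- chain_pw("P4", c("J", "K"))
  cg3 <- add_pathway_to_collage(cg2, layout_pathway(p4), gap = 30)
  bbs3 <- collage_layout_bboxes(cg3)
  expect_gt(bbs3[[4]][2], bbs3[[3]][4])
  # empty collage: margin offset
  cg_empty <- pathcollage:::new_collage()
  cg_e <- add_pathway_to_collage(cg_empty, layout_pathway(p3), gap = 30)
  bb <- collage_bbox(cg_e)
  expect_equal(bb[1], 30); expect_equal(bb[2], 30)
  # duplicate pathway rejected
  expect_error(add_pathway_to_collage(cg2, layout_pathway(p3)), "already")
})
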