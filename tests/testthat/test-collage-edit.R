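shared_collage <- function() {
  collage_of(list(chain_pw("P1", c("A", "X", "B")),
                  chain_pw("P2", c("C", "X", "D"))))
}

test_that("move_node translates exactly one glyph (plus attached grids)", {
  cg <- shared_collage()
  uid <- nodes_of(cg, "A")
  expect_true(collage_equal(cg, move_node(cg, uid, 0, 0)))
  g0 <- pathcollage:::get_glyph(cg, uid)
  cg2 <- move_node(cg, uid, 10, -5)
  g1 <- pathcollage:::get_glyph(cg2, uid)
  expect_equal(c(g1$x - g0$x, g1$y - g0$y), c(10, -5))
  # nothing else moved
  others <- setdiff(names(all_glyphs_flat(cg)), uid)
  for (u in others) {
    a <- pathcollage:::get_glyph(cg, u); b <- pathcollage:::get_glyph(cg2, u)
    expect_identical(c(a$x, a$y), c(b$x, b$y))
  }
  expect_error(move_node(cg, "ghost", 1, 1), "unknown glyph")
})

test_that("moving a label moves its attached omics grid boxes identically", {
  cg <- shared_collage()
  ds <- omics_dataset("gene", c("t1", "t2", "t3"),
                      list(`gP1-r1` = c(1, 2, NA)))
  cg <- apply_timeseries_overlay(cg, ds, test_scheme())
  enz <- grep("P1::enz::P1-r1$", names(all_glyphs_flat(cg)), value = TRUE)
  kids <- grep("::grid::", names(all_glyphs_flat(cg)), value = TRUE)
  expect_gt(length(kids), 0)
  before <- lapply(kids, function(u) {
    g <- pathcollage:::get_glyph(cg, u); c(g$x, g$y)
  })
  cg2 <- move_node(cg, enz, 7, 3)
  after <- lapply(kids, function(u) {
    g <- pathcollage:::get_glyph(cg2, u); c(g$x, g$y)
  })
  for (i in seq_along(kids))
    expect_equal(after[[i]] - before[[i]], c(7, 3))
})

test_that("move_pathway shifts all glyphs as a unit and is invertible", {
  cg <- shared_collage()
  cg <- connect_metabolite(cg, nodes_of(cg, "X")[1])
  # exact inverse
  cg_back <- move_pathway(move_pathway(cg, "P1", 12.5, -8), "P1", -12.5, 8)
  expect_true(collage_equal(cg, cg_back))
  # every glyph center shifts by the same vector
  uids <- names(cg$layouts[[1]]$layout$glyphs)
  cg2 <- move_pathway(cg, "P1", 100, 50)
  for (u in uids) {
    a <- pathcollage:::abs_center(cg, u)
    b <- pathcollage:::abs_center(cg2, u)
    expect_equal(b - a, c(100, 50))
  }
  # connection edge geometry: moved endpoint follows, the other stays
  e <- cg$connections[[1]]
  in_p1 <- function(u) !is.na(match(u, uids))
  for (endp in c(e$source_uid, e$target_uid)) {
    d <- pathcollage:::abs_center(cg2, endp) -
      pathcollage:::abs_center(cg, endp)
    expect_equal(d, if (in_p1(endp)) c(100, 50) else c(0, 0))
  }
  expect_error(move_pathway(cg, "nope", 1, 1), "unknown pathway")
})

test_that("deletion removes incident edges but never orphans anything", {
  cg <- shared_collage()
  xs <- nodes_of(cg, "X")
  cg <- connect_metabolite(cg, xs[1])
  # X in P1 touches 2 reaction edges + 1 connection edge = degree 3
  n_edges0 <- length(all_edges_flat(cg))
  cg2 <- delete_element(cg, xs[1])
  expect_null(pathcollage:::get_glyph(cg2, xs[1]))
  expect_identical(n_edges0 - length(all_edges_flat(cg2)), 3L)
  # no orphans: every remaining edge endpoint resolves to a glyph
  for (e in all_edges_flat(cg2)) {
    expect_false(is.null(pathcollage:::get_glyph(cg2, e$source_uid)))
    expect_false(is.null(pathcollage:::get_glyph(cg2, e$target_uid)))
  }
  # pathway deletion: no glyph of that pathway survives, connections drop
  cg3 <- delete_element(cg, "P1")
  expect_identical(length(cg3$layouts), 1L)
  expect_identical(length(cg3$connections), 0L)
  expect_true(all(grepl("^P2", names(all_glyphs_flat(cg3)))))
  # connection deletion keeps both endpoint nodes
  conn_uid <- names(cg$connections)[1]
  cg4 <- delete_element(cg, conn_uid)
  expect_identical(length(cg4$connections), 0L)
  expect_false(is.null(pathcollage:::get_glyph(cg4, xs[1])))
  expect_false(is.null(pathcollage:::get_glyph(cg4, xs[2])))
  expect_error(delete_element(cg, "ghost"), "unknown element")
})

test_that("merging collapses duplicates into the first-listed survivor", {
  cg <- shared_collage()
  xs <- nodes_of(cg, "X")
  n0 <- length(all_glyphs_flat(cg))
  pos0 <- pathcollage:::abs_center(cg, xs[1])
  cg2 <- merge_nodes(cg, xs)
  expect_identical(n0 - length(all_glyphs_flat(cg2)), 1L)
  # survivor keeps its position; absorbed uid gone
  expect_equal(pathcollage:::abs_center(cg2, xs[1]), pos0)
  expect_null(pathcollage:::get_glyph(cg2, xs[2]))
  # all edges formerly incident to the absorbed node now hit the survivor
  for (e in all_edges_flat(cg2)) {
    expect_false(e$source_uid == xs[2] || e$target_uid == xs[2])
    expect_false(is.null(pathcollage:::get_glyph(cg2, e$source_uid)))
    expect_false(is.null(pathcollage:::get_glyph(cg2, e$target_uid)))
  }
  expect_identical(length(cg2$merges), 1L)
  expect_identical(cg2$merges[[1]]$survivor, xs[1])
  # merge record survives save/load
  f <- tempfile(fileext = ".json")
  save_collage(cg2, f)
  expect_true(collage_equal(cg2, load_collage(f)))
})

test_that("merging removes self-loop connections and parallel duplicates", {
  cg <- collage_of(list(chain_pw("P1", c("A", "X", "B")),
                        chain_pw("P2", c("C", "X", "D")),
                        chain_pw("P3", c("X", "E", "F"))))
  xs <- nodes_of(cg, "X")
  cg <- connect_metabolite(cg, xs[1])  # edges x1-x2, x1-x3
  census0 <- length(cg$connections)
  expect_identical(census0, 2L)
  cg2 <- merge_nodes(cg, xs)
  # both connections became self-loops on the survivor: removed
  expect_identical(length(cg2$connections), 0L)
  expect_identical(length(nodes_of(cg2, "X")), 1L)
  # error paths leave the collage untouched
  a_uid <- nodes_of(cg, "A")
  expect_error(merge_nodes(cg, c(xs[1], a_uid)), "different compounds")
  expect_error(merge_nodes(cg, xs[1]), "at least 2")
  expect_error(merge_nodes(cg, c(xs[1], "ghost")), "unknown glyph")
})

test_that("highlight and relabel touch only the named attribute", {
  cg <- shared_collage()
  uid <- nodes_of(cg, "A")
  cg2 <- highlight(cg, uid, "#ff0000")
  g2 <- pathcollage:::get_glyph(cg2, uid)
  expect_identical(g2$color, "#ff0000")
  g2$color <- pathcollage:::get_glyph(cg, uid)$color
  expect_true(collage_equal(list(g2),
                            list(pathcollage:::get_glyph(cg, uid))))
  # relabel is verbatim
  enz <- grep("::enz::", names(all_glyphs_flat(cg)), value = TRUE)[1]
  cg3 <- relabel(cg, enz, "pyruvate kinase  (PK)")
  expect_identical(pathcollage:::get_glyph(cg3, enz)$label_text,
                   "pyruvate kinase  (PK)")
  # edges can be highlighted too
  redge <- names(cg$layouts[[1]]$layout$edges)[1]
  cg4 <- highlight(cg, redge, "#123456")
  expect_identical(cg4$layouts[[1]]$layout$edges[[redge]]$color, "#123456")
})

test_that("set_style toggles are involutions and reject unknown fields", {
  cg <- shared_collage()
  cg_off <- set_style(cg, list(show_pathway_boxes = FALSE))
  boxes <- grep("::box$", names(all_glyphs_flat(cg_off)), value = TRUE)
  for (b in boxes)
    expect_false(pathcollage:::get_glyph(cg_off, b)$visible)
  cg_on <- set_style(cg_off, list(show_pathway_boxes = TRUE))
  expect_true(collage_equal(cg, cg_on))
  expect_error(set_style(cg, list(no_such_field = 1)), "unknown style")
})
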