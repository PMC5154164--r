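test_that("bin rule: half-open bins, below-range bin, missing color", {
  sch <- color_scheme(c(0, 10, 20), c("c0", "c1", "c2", "c3"),
                      missing_color = "miss")
  expect_identical(color_for(-5, sch), "c0")     # below lowest breakpoint
  expect_identical(color_for(0, sch), "c1")      # breakpoint -> its own bin
  expect_identical(color_for(9.999, sch), "c1")
  expect_identical(color_for(10, sch), "c2")
  expect_identical(color_for(20, sch), "c3")     # at/above last breakpoint
  expect_identical(color_for(1e9, sch), "c3")
  expect_identical(color_for(NA, sch), "miss")
  expect_identical(color_for(NULL, sch), "miss")
})

# one shared compound (X, 3 occurrences) + one gene shared by two reactions
overlay_fixture <- function() {
  rx1 <- list(mk_rxn("P1-r1", "A", "X", genes = "gShared"),
              mk_rxn("P1-r2", "X", "B", genes = "gShared"))
  p1 <- pathway("P1", rx1, links = list(c("P1-r1", "P1-r2")))
  p2 <- chain_pw("P2", c("C", "X", "D"))
  p3 <- chain_pw("P3", c("X", "E"))
  collage_of(list(p1, p2, p3))
}

test_that("entity matching targets the right uids per data type", {
  cg <- overlay_fixture()
  # metabolite rows match every occurrence
  m <- match_entities(cg, omics_dataset("metabolite", "t1",
                                        list(X = 1, Ghost = 2)))
  expect_setequal(m$matches$X, nodes_of(cg, "X"))
  expect_identical(length(m$matches$X), 3L)
  expect_identical(m$unmatched, "Ghost")
  # gene rows match enzyme label + reaction edge of each carrying reaction
  mg <- match_entities(cg, omics_dataset("gene", "t1", list(gShared = 1)))
  expect_setequal(mg$matches$gShared,
                  c("P1::enz::P1-r1", "P1::rxn::P1-r1",
                    "P1::enz::P1-r2", "P1::rxn::P1-r2"))
  # flux rows match primary reaction edges
  mf <- match_entities(cg, omics_dataset("flux", "t1", list(`P1-r1` = 1)))
  expect_identical(mf$matches$`P1-r1`, "P1::rxn::P1-r1")
})

test_that("single-value overlay colors targets per scheme, nothing else", {
  cg <- overlay_fixture()
  sch <- test_scheme()
  ds <- omics_dataset("flux", "cond1", list(`P1-r1` = -1.5, `P1-r2` = 2.5))
  cg2 <- apply_single_overlay(cg, ds, sch)
  e1 <- get_edge(cg2, "P1::rxn::P1-r1")
  e2 <- get_edge(cg2, "P1::rxn::P1-r2")
  expect_identical(e1$overlay_color, color_for(-1.5, sch))
  expect_identical(e2$overlay_color, color_for(2.5, sch))
  # node colors untouched by flux data
  for (u in nodes_of(cg2, "X"))
    expect_null(pathcollage:::get_glyph(cg2, u)$overlay_color)
  # wrong-mode error directs to the other entry point
  ds5 <- omics_dataset("flux", c("a", "b"),
                       list(`P1-r1` = c(1, 2)))
  expect_error(apply_single_overlay(cg, ds5, sch), "timeseries")
  expect_error(apply_timeseries_overlay(cg, ds, sch), "single")
})

test_that("re-applying an overlay clears every trace of the previous one", {
  cg <- overlay_fixture()
  sch <- test_scheme()
  cg1 <- apply_timeseries_overlay(cg, omics_dataset("gene", c("t1", "t2"),
                                                    list(gShared = c(1, 2))),
                                  sch)
  expect_gt(length(grep("::grid::", names(all_glyphs_flat(cg1)))), 0)
  cg2 <- apply_single_overlay(cg1, omics_dataset("metabolite", "t1",
                                                 list(X = 0.5)), sch)
  # grids gone, former gene targets uncolored
  expect_identical(length(grep("::grid::", names(all_glyphs_flat(cg2)))), 0L)
  expect_null(get_edge(cg2, "P1::rxn::P1-r1")$overlay_color)
  for (u in nodes_of(cg2, "X"))
    expect_identical(pathcollage:::get_glyph(cg2, u)$overlay_color,
                     color_for(0.5, sch))
  # overlay with nothing matched leaves geometry and colors untouched
  cg3 <- apply_single_overlay(cg, omics_dataset("metabolite", "t1",
                                                list(Nobody = 1)), sch)
  cg3["omics"] <- list(NULL)  # drop the attachment, keep the slot
  expect_true(collage_equal(cg, cg3))
})

test_that("time-series grids: one box per column, ordered, colored by rule", {
  cg <- overlay_fixture()
  sch <- test_scheme()
  vals <- c(-3, -1.2, 0.3, NA, 5)
  ds <- omics_dataset("gene", sprintf("t%d", 1:5), list(gShared = vals))
  cg2 <- apply_timeseries_overlay(cg, ds, sch)
  grids <- grep("::grid::", names(all_glyphs_flat(cg2)), value = TRUE)
  grids <- grids[!grepl("::box", grids)]
  expect_identical(length(grids), 2L)  # one per matched enzyme label
  for (guid in grids) {
    boxes <- paste0(guid, "::box", 1:5)
    gl <- lapply(boxes, function(u) pathcollage:::get_glyph(cg2, u))
    expect_false(any(vapply(gl, is.null, TRUE)))
    # left-to-right in column order
    expect_true(all(diff(vapply(gl, function(g) g$x, 0)) > 0))
    # each box color equals an independent recomputation of the bin rule
    for (k in 1:5)
      expect_identical(gl[[k]]$color, color_for(vals[k], sch))
    # single row
    expect_identical(length(unique(vapply(gl, function(g) g$y, 0))), 1L)
  }
  # gene grids sit at the enzyme label position and hide the label
  vis <- visible_elements(cg2, zoom = 2)
  expect_false("P1::enz::P1-r1" %in% vis)
  expect_true(any(grepl("::grid::", vis)))
  g <- pathcollage:::get_glyph(cg2, grids[1])
  anchor <- pathcollage:::get_glyph(cg2, g$parent_uid)
  expect_identical(anchor$kind, "enzyme-label")
  expect_equal(c(g$x, g$y), c(anchor$x, anchor$y))
})

test_that("metabolite grids hang below each node occurrence", {
  cg <- overlay_fixture()
  ds <- omics_dataset("metabolite", c("t1", "t2"), list(X = c(1, NA)))
  cg2 <- apply_timeseries_overlay(cg, ds, test_scheme())
  xs <- nodes_of(cg2, "X")
  for (u in xs) {
    guid <- sprintf("%s::grid::X", u)
    g <- pathcollage:::get_glyph(cg2, guid)
    expect_false(is.null(g))
    node <- pathcollage:::get_glyph(cg2, u)
    expect_gt(g$y, node$y + node$height - 1e-9)
    expect_identical(g$parent_uid, u)
  }
  # all-missing vector: every box in missing color
  ds2 <- omics_dataset("metabolite", c("t1", "t2"),
                       list(X = c(NA_real_, NA_real_)))
  cg3 <- apply_timeseries_overlay(cg, ds2, test_scheme())
  boxes <- grep("::grid::X::box", names(all_glyphs_flat(cg3)), value = TRUE)
  expect_identical(length(boxes), 6L)  # 3 occurrences x 2 columns
  for (b in boxes)
    expect_identical(pathcollage:::get_glyph(cg3, b)$color,
                     test_scheme()$missing_color)
})

test_that("flux condition series: leftmost box shows the first condition", {
  cg <- overlay_fixture()
  sch <- test_scheme()
  ds <- omics_dataset("flux", c("anaerobic", "aerobic"),
                      list(`P1-r1` = c(-1.5, 1.5)))
  cg2 <- apply_timeseries_overlay(cg, ds, sch)
  guid <- grep("::grid::P1-r1$", names(all_glyphs_flat(cg2)), value = TRUE)
  expect_identical(length(guid), 1L)
  b1 <- pathcollage:::get_glyph(cg2, paste0(guid, "::box1"))
  b2 <- pathcollage:::get_glyph(cg2, paste0(guid, "::box2"))
  expect_lt(b1$x, b2$x)
  expect_identical(b1$color, color_for(-1.5, sch))
  expect_identical(b2$color, color_for(1.5, sch))
})

test_that("show_omics toggle is an involution restoring enzyme labels", {
  cg <- overlay_fixture()
  ds <- omics_dataset("gene", c("t1", "t2"), list(gShared = c(0, 1)))
  cg2 <- apply_timeseries_overlay(cg, ds, test_scheme())
  vis_on <- visible_elements(cg2, zoom = 2)
  cg_off <- set_style(cg2, list(show_omics = FALSE))
  vis_off <- visible_elements(cg_off, zoom = 2)
  expect_false(any(grepl("::grid::", vis_off)))
  expect_true("P1::enz::P1-r1" %in% vis_off)
  cg_back <- set_style(cg_off, list(show_omics = TRUE))
  expect_true(collage_equal(cg2, cg_back))
  expect_setequal(visible_elements(cg_back, zoom = 2), vis_on)
})

test_that("overlay survives save/load bit-exactly", {
  cg <- overlay_fixture()
  sch <- test_scheme()
  cg2 <- apply_timeseries_overlay(cg, omics_dataset(
    "gene", sprintf("t%d", 1:5), list(gShared = c(-3, -1.2, 0.3, NA, 5))),
    sch)
  f <- tempfile(fileext = ".json")
  save_collage(cg2, f)
  cg3 <- load_collage(f)
  expect_true(collage_equal(cg2, cg3, tol = 1e-9))
  # colors compare exactly as strings
  for (u in grep("::box", names(all_glyphs_flat(cg2)), value = TRUE))
    expect_identical(pathcollage:::get_glyph(cg3, u)$color,
                     pathcollage:::get_glyph(cg2, u)$color)
})
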