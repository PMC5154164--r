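# pathcollage

Scriptable construction of **pathway collages** — personalized multi-pathway
metabolic diagrams. A single metabolic pathway is often too little context
and a whole-network "cellular overview" far too much; a collage depicts
exactly the medium-sized fragment of metabolism a scientist cares about:
a chosen set of pathways, each laid out with the field's standard
conventions, placed side by side, with explicit connection lines between
occurrences of the same metabolite in different pathways, and with omics
data (gene expression, metabolite abundance, reaction flux) painted on top.

The package is aimed at systems-biology workflows that need reproducible,
scriptable figures rather than a mouse-driven viewer: every interactive
refinement (move, delete, merge, connect, restyle) exists as a pure function
and as a JSON edit-script op, so a collage build is a deterministic pipeline
from data to image.

## The method in brief

* **Single-pathway layout.** The *backbone* of a pathway is the ordered
  alternating chain of main metabolites and reactions along its principal
  axis; side (currency) metabolites such as NADP are omitted by default and
  can be added back per reaction or everywhere at once. Geometry is
  topology-aware: linear pathways become vertical chains with backbone nodes
  equally spaced (spacing = 3 node diameters), cycles become circles of
  radius `r = spacing · n / 2π` anchored with the lexicographically smallest
  compound at 12 o'clock running clockwise, and branched pathways become
  layered top-down trees (backbone = longest reaction path, ties broken
  lexicographically). Enzyme and gene labels sit beside their reaction edge;
  a deterministic de-overlap pass guarantees that no two non-container glyph
  rectangles intersect.
* **Assembly.** Layouts are grouped by functional class (from the root of
  each pathway's ontology class path) and shelf-packed into contiguous
  category blocks ordered biosynthesis → energy → other → degradation left
  to right, so biosynthetic pathways end up left of degradative ones.
  Shared metabolites deliberately do not influence placement.
* **Connections and merges.** For each compound with k ≥ 2 node
  occurrences, `connect_all()` draws the Euclidean minimum-spanning-tree
  (k − 1 green edges); `connect_metabolite()` stars one node out to all its
  twins; `merge_nodes()` collapses occurrences into one.
* **Omics overlay.** A 1-column dataset colors matched nodes/edges through
  an ordered-breakpoint color scheme (half-open bins, below-range bin,
  missing-data color). A multi-column (time-series) dataset instead adds a
  row of colored boxes per matched element — below metabolite nodes, in
  place of enzyme names, or beside reaction arrows — leftmost box = first
  condition.
* **Semantic zoom + export.** Label classes appear only at zoom levels
  where they are readable (inclusive thresholds, monotone in zoom); output
  is deterministic SVG, rasterized PNG (`ceil(canvas × scale)`, clamped to
  `max_dim`), saved-collage JSON (round-trip identical), and a
  Cytoscape-style viewer JSON validated against a shipped schema.

## Worked example

```r
library(pathcollage)

# synthetic stand-in for a pathway/genome database extract
coll <- generate_collection(5, shared_compound_rate = 0.4, seed = 11)
coll
#> pathway collection (schema 1.0): 38 compounds, 5 pathways

layouts <- lapply(coll$pathways, layout_pathway)
collage <- assemble_collage(layouts, coll$pathways,
                            max_width = 1600, gap = 30)
collage
#> pathway collage: 5 pathways, 106 glyphs, 31 edges, 0 connections
round(collage_bbox(collage), 1)
#> [1]   30.0   30.0 1075.1  300.2

collage <- connect_all(collage)          # 4 green metabolite connections
length(collage$connections)
#> [1] 4

# 5-timepoint expression overlay: boxes replace enzyme names
expr   <- generate_omics(coll, "gene", n_columns = 5, coverage = 1, seed = 11)
scheme <- color_scheme(c(-2, -1, 0, 1, 2),
                       c("#2166ac", "#67a9cf", "#d1e5f0",
                         "#fddbc7", "#ef8a62", "#b2182b"))
collage <- apply_timeseries_overlay(collage, expr, scheme)
collage
#> pathway collage: 5 pathways, 292 glyphs, 31 edges, 4 connections
#>   [timeseries gene overlay]
length(collage$omics$coverage$matched)   # 31 matched, 0 unmatched
#> [1] 31

svg <- render_svg(collage, zoom = 1)
svg
#> <SVG document, 58404 bytes>
export_png(svg, "collage.png", scale = 2)   # 2131 x 581 px raster

save_collage(collage, "glycolysis-collage.json")
collage_equal(collage, load_collage("glycolysis-collage.json"))
#> [1] TRUE
```

The five generated pathways are `linear cyclic branched linear cyclic` in
topology and `biosynthesis degradation degradation degradation other` in
category, so the printed bbox shows the biosynthesis block packed at the
left edge (x = 30) with the degradation block to its right.

The same pipeline from a shell:

```sh
pathcollage fixtures --out-dir fx --n-pathways 5 --seed 11
pathcollage build   --collection fx/collection.json \
                    --pathways PWY001,PWY002,PWY003 --out collage.json
pathcollage edit    --in collage.json --script edits.json --out collage2.json
pathcollage overlay --in collage2.json --omics fx/expression.tsv \
                    --type gene --scheme fx/scheme.json --out collage3.json
pathcollage render  --in collage3.json --out collage.png --scale 2
pathcollage export  --in collage3.json --out viewer.json
```

`build --metabolites ade,gua ...` instead expands the metabolite list into
every pathway those compounds participate in (the pathways-for-metabolite
transform) before laying out.

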