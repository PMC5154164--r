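---
title: "Building pathway collages: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building pathway collages: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcollage)
```

## The problem

A biologist studying, say, a drug's effect on pathogen metabolism rarely
wants either a single pathway diagram (too little context) or the
organism's full metabolic map (information overload). What they want is a
*collage*: a hand-picked set of pathways, each drawn with the conventions
of classical pathway diagrams, arranged together, with the cross-pathway
identities of metabolites made explicit and experimental data painted on
top. This package implements that workflow as a deterministic library and
CLI: specify pathways (directly or via the metabolites/genes that
participate in them), lay each one out, assemble, refine by script,
overlay omics data, and export.

## The data model

A *collection* holds compounds and pathways; a pathway is a set of
reactions plus ordering links (predecessor → successor pairs over reaction
ids) and an ontology class path. Reaction participants carry a
`side` (substrate/product) and a `role` (`main`/`side`). Main participants
define the drawn structure; side participants are currency couples (ATP,
NAD(P)H, CoA, Pi…) that are omitted by default and can be re-added.

A *collage* is a list of placed pathway layouts (each an offset plus
positioned glyphs and edges), collage-level connection edges, merge
records, a style configuration and optionally an attached omics dataset
with its color scheme. All geometry uses screen coordinates — origin
top-left, y increasing downward, real-valued layout units — matching the
SVG/browser rendering target. Glyph positions are top-left corners.

One deliberate modeling decision: a compound occurring in several pathways
(or twice within one) is several distinct metabolite-node glyphs. Identity
is only asserted explicitly, by drawing connection edges or by merging —
mirroring how a scientist curates a figure rather than a normalized graph
database. Identifiers are case-sensitive throughout to avoid silent
aliasing.

## Single-pathway layout

The layout pipeline is: classify topology → extract backbone → place
occurrences → attach labels → de-overlap → box.

**Topology.** The reaction link graph decides: any directed cycle ⇒
*cyclic*; acyclic with in/out degree ≤ 1 everywhere ⇒ *linear*; otherwise
*branched*.

**Backbone.** The backbone is the alternating chain of main compounds and
reactions along the principal axis. Between consecutive chain reactions the
shared occurrence is a main product of the predecessor that is also a main
substrate of the successor (lexicographically smallest when ambiguous).
For cycles, the cycle is walked in link direction and rotated so the
lexicographically smallest compound id leads — an arbitrary but stable
anchor that makes layouts reproducible. For branched pathways the backbone
is the longest directed reaction path, ties broken by the lexicographically
smallest concatenation of reaction ids; all main participants of terminal
reactions act as backbone endpoints. Main participants beyond the chain
get their own auxiliary occurrence nodes with short stub edges.

**Geometry constants** (all in `layout_config()`): node diameter 12 units;
backbone spacing 3 diameters (36); cyclic radius `spacing·n/2π` so the arc
between adjacent nodes equals the linear spacing; branch arms offset by 6
diameters; label text width estimated as `0.6 · font size · nchar` —
deliberately font-metric-free so overlap tests hold on every platform.
Linear backbones are vertical and equally spaced; cyclic backbones sit on
an anchored circle, first node at 12 o'clock, clockwise; branched layouts
are layered top-down by longest-path depth with branch columns to the
right.

**Overlap freedom.** Backbone geometry cannot self-intersect by
construction (grid cells / chord lengths exceed the node diameter). Labels
and auxiliary nodes then pass through a greedy deterministic resolver: in
uid order, each glyph slides along its escape direction (horizontal for
chains/trees, radial for circles, perpendicular for side metabolites) in
2-unit steps until disjoint from everything already placed. Sequential
placement guarantees a globally overlap-free result; determinism follows
from the fixed ordering. The *pathway box* and omics grids are containers —
they enclose content by design and are exempt from the disjointness
invariant (the tests' brute-force oracle checks all non-container pairs).

**Reversibility** renders as a two-headed arrow; backbone traversal always
follows link order regardless of reversibility.

## Assembly

Pathways are grouped by a keyword table over the root of the class path
(`Biosynthesis…` / `Degradation…` / `…Energy` / other). Blocks are placed
left-to-right in the fixed order biosynthesis < energy < other <
degradation; only the two extremes are field conventions, the middle order
is this package's choice. Within a block, shelf packing: layouts sorted by
descending height (ties by pathway id) fill rows left-to-right, wrapping
when `max_width` would be exceeded; separation of at least `gap` holds
between all bounding boxes. Shelf packing was chosen over true 2-D bin
packing for determinism and simplicity — "as compact as possible" means
the shelf heuristic's output, not a global optimum. Shared metabolites
never influence placement. When several category blocks compete for a
narrow `max_width`, the left-to-right block rule wins and the width bound
can be exceeded; the precondition (`max_width ≥ widest + 2·gap`) only
guarantees the single-block case.

## Connections and merges

`connect_metabolite(uid)` adds edges from one node to every other
occurrence of its compound (k − 1 star edges). `connect_all()` uses, per
compound, the Euclidean minimum spanning tree over occurrence centers:
k − 1 edges bound visual clutter while keeping the occurrences connected,
which is what the green inter-pathway lines are for. An MST (own Prim
implementation, deterministic tie-breaks) rather than an all-pairs clique
is a design choice; the test suite verifies minimality against brute-force
edge-subset enumeration for k ≤ 6. Currency metabolites are *not* excluded
by default — the `exclude` argument (and the CLI config) carries an
exclusion list instead, keeping the library free of hidden policy.

Merging keeps the first-listed node at its position (the caller controls
geometry; no centroid repositioning), re-targets all incident edges to the
survivor, collapses resulting parallel duplicates, removes self-loop
connections, and records the merge. Grids attached to absorbed nodes are
deleted rather than re-parented, to avoid duplicate grids on the survivor.

## Omics overlays

The bin rule is the one place a color scheme needs a convention, and the
source diagrams only show a legend, so the convention is declared: bins are
half-open `[bᵢ, bᵢ₊₁)`, with a below-range bin in front and the last color
catching values ≥ the last breakpoint; missing values get `missing_color`.
A value exactly at a breakpoint belongs to the bin it opens.

Matching is exact and case-sensitive (no synonym resolution): gene rows
match reaction `gene_ids` and target the enzyme label plus reaction edge;
metabolite rows match compound ids and target *every* occurrence; flux rows
match reaction ids and target the primary reaction edge. Unmatched rows go
into a coverage summary rather than erroring.

Single-value mode paints an `overlay_color` slot kept separate from the
base color, so user highlights survive an overlay swap, and re-applying a
dataset always clears the previous overlay first. Time-series mode creates
one single-row grid of boxes per matched element — below metabolite nodes,
at the enzyme label's position (label hidden while `show_omics` is on),
beside reaction edge midpoints — leftmost box = first column. Grids never
wrap and layout is never recomputed to make room: beyond roughly 6
timepoints the boxes get cramped and the user moves them with
`move_node()`, exactly as the original workflow expects manual cleanup.
In time-series gene mode only the boxes are colored, not the reaction edge
(the single-value rule would double-encode the first timepoint).

## Semantic zoom and rendering

Zoom thresholds are declared, not derived — "readable" is perceptual:
pathway labels at 0.25, metabolite labels at 0.5, enzyme/gene labels at
0.75, all inclusive (`zoom ≥ threshold`) and configurable. Nodes, edges and
pathway boxes are always visible subject to style toggles, so inclusion is
monotone non-decreasing in zoom — a property the tests check over a 20-point
zoom grid. SVG output uses fixed `%.3f` number formatting and a fixed
element order (boxes, edges, connections, nodes/grids, labels), making the
byte stream a pure function of the input. PNG rasterization draws the SVG
primitives on a cairo bitmap device; dimensions are `ceil(canvas · scale)`,
uniformly downscaled to `max_dim` (default 8192 px) preserving aspect
ratio. A single estimated sans-serif metric is used everywhere rather than
measured fonts, trading typographic fidelity for platform-independent
determinism.

## Persistence and interchange

Saved collages are versioned JSON ("1.0"); unknown versions are rejected,
not guessed. Numbers are written with 17 significant digits so doubles
round-trip exactly; deep-equality comparison (`collage_equal()`) is exact
on strings and tolerant to 1e-9 on numbers. The viewer export is a
Cytoscape-style elements list — the closest public convention to the
original tool's undocumented graph dialect — with node positions at glyph
centers; it validates against a schema shipped in `inst/schema/` using a
small built-in validator (no JSON-schema package exists in the supported
dependency set; the validator covers the subset the schema uses).

## Synthetic fixtures: what they do and do not establish

`generate_collection()` emulates a pathway/genome-database extract: mixed
topologies, 1–8 reactions per pathway by default, at least one biosynthetic
and one degradative pathway from n = 2 on, a 10-compound shared pool
feeding backbone duplicates at the requested rate, and an 8-compound
currency pool (ATP, ADP, NAD, NADH, NADP, NADPH, CoA, Pi) for side
participants — the NADP/adenine-style sharing the connect/merge features
exist for. Omics fixtures draw standard-normal values with ~5% missing
cells. All randomness flows through one locally seeded generator that
restores the global RNG state.

The generator makes no attempt at biological realism: no mass balance, no
realistic stoichiometry, no compartments, transport or regulation (the
diagrams this package draws carry none of these either). A green test
therefore establishes geometric and structural correctness — overlap
freedom, packing invariants, MST minimality, round-trip identity — not
biological plausibility of any particular collage.

## Known limitations

* Edge routing is straight-line (curved stubs for side metabolites); edges
  may cross nodes in dense branched layouts.
* Shelf packing is deterministic but not optimal; very heterogeneous
  layout sizes waste row space.
* Gene and enzyme labels share one visibility toggle
  (`show_enzyme_labels`); the data model keeps them as separate glyphs, so
  splitting the toggle later is cheap.
* Text widths are estimates; exotic label lengths are safe against overlap
  but may look loose or tight when rendered with a real font.
* No undo stack: edits are pure functions, so scripts keep history by
  keeping values.
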