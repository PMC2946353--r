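---
title: "Methods: radial ontology layouts, statistic mappings and tiered pathway scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial ontology layouts, statistic mappings and tiered pathway scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ersfviz)
```

## The problem

Biological ontologies — pathway ontologies that group metabolic pathways
into functional categories, or the Gene Ontology — are directed acyclic
graphs, not trees: one pathway routinely belongs to several categories.
Indented lists and node-link drawings either hide this multiple inheritance
or bury it in edge clutter, and neither scales to the few hundred terms a
whole-organism pathway ontology contains.  `ersfviz` draws the ontology as
an enhanced radial space-filling (ERSF) layout — a sunburst over a spanning
tree, with the non-tree edges shown explicitly as satellite orbits — and
maps per-term summaries of gene expression experiments onto the geometry.

## The spanning tree and the major-parent rule

The sunburst can only nest a region under one parent, so every multi-parent
term keeps a single *major* parent and the remaining in-edges become
*non-tree* edges from *minor* parents.  The major parent is the parent of
the term's **first-listed** incoming edge in the input file.  The rule has
to be stated somewhere, and input order has two virtues: it is
deterministic (identical files give byte-identical layouts), and it lets
curators control the nesting simply by edge order.  Plausible alternatives
(smallest-depth parent, lexicographic parent) disagree with the intended
major/minor assignment on the packaged toy DAG `make_g2()`, where category
`C` must come out as the *minor* parent of pathways `AA1` and `AA2`.

Graphs with several roots (the Gene Ontology has three namespace roots) are
normalized by inserting a virtual root `__ROOT__` rather than rejected.
Depths are computed over tree edges only, so `depth(child) =
depth(major_parent) + 1` and each depth forms one ring ("layer") of the
drawing.

## Region geometry

Each term owns an annular region with five variables:

* **Sweep angle.**  A spanning-tree leaf sweeps `360 * w / sum(w)` degrees
  (default weight 1, so every pathway spans the same angle); a category
  sweeps exactly the sum of its children.  Siblings are laid out
  contiguously in lexicographic id order — the order is arbitrary but must
  be fixed for reproducibility.  Conservation is exact: the suite checks
  closure to `1e-9` degrees.
* **Radius.**  Layer `k` occupies the annulus `[k*w, (k+1)*w]` with a
  constant ring width `w` (default 10 layout units); the root is the
  central disc.  A `hide_root` flag drops the root disc for users who find
  it redundant.
* **Color.**  Structure-based: a rim node takes its hue from its angular
  midpoint on the HSV wheel (full saturation/value); a category is the
  sweep-weighted mean of its children's colors, computed bottom-up.  The
  averaging is done in linear RGB; the choice of averaging space is
  cosmetic, and RGB keeps the recursion exactly testable against an
  independent recomputation.
* **Height.**  `H0 * (1 + subtree height)`, so a leaf extrudes to `H0`
  rather than zero — strictly proportional height would make every pathway
  invisible in the 3D view — and the root is tallest.
* **Transparency** is reserved for the data mappings below.

## Orbits, downlinks, access points

Every term with two or more parents gets one *orbit*: a circle on its own
layer.  Orbits are confined to the middle band of the ring — fractions 0.3
to 0.7 of the ring width, exposed as `orbit_band` — so a gap always
separates orbits of adjacent layers.  Within a layer, orbits sorted by
(downlink count, child id) receive evenly spaced radii across the band and
evenly spaced altitudes, largest count outermost and highest, making "does
this pathway belong to many categories?" readable at a glance.  Orbit
altitudes start one `H0` above the tallest region of the layer; the
alternative (a fixed altitude band) can collide with tall data-mapped
regions, and nothing rules between the two readings, so the collision-free
one was taken.

Each minor parent gets exactly **one** radial ray from its region's angular
midpoint and radial center, spanning from its nearest linked orbit to its
farthest (through the anchor); where the ray's angle crosses a linked
child's orbit lies that child's *access point*.  Sharing one ray per parent
keeps total ink proportional to the farthest link, not to the number of
links.

## Mapping experimental values

Gene-level values arrive as a genes-by-conditions matrix plus a term-to-gene
annotation.  A term's gene set is its direct annotations unioned with its
tree children's sets — a union, not a multiset, so a gene shared by two
child pathways is counted once in their parent.

* **Ensemble statistics** per term and condition: mean and median over the
  observed genes, and the mean per-gene coefficient of variation across
  conditions, `CoV = sigma/mu` with the *population* standard deviation
  (divisor `N`).  CoV is undefined at `mu = 0`; the value is flagged
  missing and rendered grey/flat rather than patched with absolute values.
  Missing expression values are dropped pairwise.
* **Differential expression**: a gene changes if
  `|treatment - control| > threshold`, strictly; direction follows the
  sign.  The default threshold is 0.7 on the scale the user supplies —
  log-scale input makes the difference read as a fold change; a `ratio`
  metric is available for linear-scale data.
* **Overrepresentation**: the one-sided Fisher/hypergeometric upper tail
  `P(X >= k)` for the overlap between a selected gene list and a term's
  set, computed with `stats::phyper`; the suite cross-checks every table
  with universe up to 20 against an exhaustive enumeration oracle at
  `1e-12`.  No multiple-testing correction is applied by default (raw
  p-values are reported); `p.adjust` is left to the user.

Two style encodings turn statistics into geometry.  `style_by_value()` maps
a statistic linearly onto a green-yellow-red ramp and/or onto `[0, Hmax]`;
the range defaults to the data but can be fixed so that the same value gets
the same color in every animation frame.  `style_differential_view()` sets
height to `H0 * log2(n_de + 1)` — the logarithm tames the cumulative counts
of top categories — and color to `log2((n_up+1)/(n_down+1))` clipped to
`[-3, 3]` on a green-white-red diverging ramp; terms with fewer than
`min_de` (default 5) differentially expressed genes are left fully
transparent so the interesting regions stand out.  A matrix with `k`
conditions becomes `k` animation frames in column order, reorderable and
subsettable.

## The aligned tiered pathway layout

An individual pathway mixes entity types; the tiered layout gives each type
one z-plane (default order metabolite, polypeptide, RNA, DNA, other, spaced
`dz = 20` units).  The user-selected *major* plane is laid out first with a
deterministic Fruchterman–Reingold embedding (500 iterations, unit ideal
edge length, seed default 42); pairs of major nodes joined through a single
non-major intermediary — e.g. metabolite–reaction–metabolite — are
connected for layout purposes, so reaction nodes do not tear the backbone
apart.  Remaining planes cascade downward: each node takes the centroid of
its already-placed neighbors, so a protein lands midway between its two
substrates and an RNA with a single protein neighbor sits exactly under it
(the "aligned" property, asserted bit-exactly in the suite).  Nodes still
unplaced when the passes stall are parked on a margin grid.  Nodes of one
plane closer than `r_min = 0.5` units are fanned out on a deterministic
circle of radius `r_min` around their common centroid, in id order.
Major-plane coordinates are never touched by any later pass.

## Renderers

SVG gives the top-down 2D projection (annular-sector paths, dashed orbit
circles, ray segments, access-point dots), which is how users view the
layout most of the time.  KML 2.2 gives the 3D scene: extruded polygons at
the region height (arcs tessellated at 4° steps), orbit rings at altitude,
rays as 3D polylines, with layout units mapped to lon/lat by a local
equirectangular projection about a configurable anchor (rejected within 5°
of the poles, where the projection degenerates).  Multi-frame styles become
one `Folder` per frame carrying a `TimeSpan` on a synthetic daily timeline,
which Earth viewers play as an animation.  All XML is emitted through
`xml2` in sorted node order, so outputs are well-formed and byte-stable;
the suite parses every emitted file and censuses its elements.  True XSD
validation against the OGC KML 2.2 schema is not performed; well-formedness
plus namespace and element-census checks stand in for it.

## The synthetic data generator

`synth_expression()` emulates the matrices the tool is pointed at: genes
assigned uniformly at random to the eight leaf pathways of the toy DAG,
baseline intensities i.i.d. Normal(`mu0 = 8`, `sigma0 = 0.5`) — a
realistic log2 microarray intensity scale — and additive condition-specific
shifts on designated terms.  The default seven conditions mirror a
seven-point time series.  What it does **not** emulate: correlated genes,
replicate structure (replicates are assumed averaged upstream),
heteroskedastic or heavy-tailed noise, and annotation bias toward large
pathways.  Passing tests therefore show that the mappings recover clean
additive signal at realistic noise, not that they are robust to everything
real microarrays do.

One consequence worth stating: with independent per-condition noise, a
null gene is "differentially expressed" with probability
`P(|N(0, sigma0*sqrt(2))| > 0.7) ≈ 0.32`, so an unshifted pathway with
~100 genes carries ~32 noise DE genes and will clear any small `min_de`.
The transparency cutoff separates signal from noise *per pathway* only when
pathways are small relative to `1/0.32 * min_de`; the suite demonstrates
shift recovery on an 800-gene cohort (where a +2.0 shift marks ≥95% of the
target pathway's genes "up") and the transparency behavior on a sparse
48-gene cohort (~6 genes per pathway, expected noise DE ≈ 2 < `min_de`).
Ancestor categories accumulate their descendants' DE counts by
construction — that is precisely why the differential view log-scales
height — and are not expected to go transparent.

`synth_pathway()` builds the two pathway shapes the tiered layout is
designed around: a metabolic cycle (`n` metabolites in a ring,
`ceiling(n/2)` catalyzing proteins each with one RNA and one DNA beneath)
and a signaling hub (one metabolite regulating `n` proteins).

## Problem sizes and numerical choices

The test suite runs entirely on generated data: 200 random trees and 200
random DAGs of up to 50 nodes for the geometry and counting properties,
every hypergeometric table with universe ≤ 20, 1000 random vectors for CoV,
and the 800/48-gene cohorts above.  Angle closure is asserted to 1e-9
degrees; Fisher agreement to 1e-12; alignment and determinism claims are
asserted bit-exactly (`identical`), not to a tolerance.  Ties are broken
lexicographically by id everywhere a sort order is needed; all randomness
flows through explicit seeds, and the spring embedding restores the
caller's RNG state afterwards.

## Limitations

Label placement, level-of-detail culling and interactive navigation are
delegated to the viewer consuming the SVG/KML.  OBO support is limited to
`is_a` (other relationship types are counted and ignored with a warning).
Sibling order and leaf hues are structural, not semantic: adjacent regions
are not necessarily biologically similar, a known perceptual trap of
structure-based coloring.  The equirectangular projection distorts at high
anchor latitudes; keep the anchor near the equator for metrically faithful
scenes.
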