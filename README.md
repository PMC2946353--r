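# ersfviz

Enhanced Radial Space-Filling (ERSF) layouts for biological ontologies, with
experiment statistics mapped onto the geometry, plus an aligned 3D tiered
layout for individual pathways.  Output goes to SVG (2D sunburst) and KML 2.2
(extruded 3D scene with optional time animation) for any Earth-style viewer.

## Who it is for

Systems biologists who want a *global* view of a pathway or gene ontology —
hundreds of terms, including the multiple-inheritance ("non-tree") edges
that indented lists and node-link drawings hide — and who want per-term
summaries of an expression experiment (means, coefficient of variation,
differential-expression counts, Fisher overrepresentation) drawn directly on
that view.

## The model in brief

An ontology is a DAG of terms.  Each multi-parent term keeps one **major
parent** (the parent of its first-listed incoming edge); the induced
spanning tree is drawn as a sunburst:

* sweep angle: leaf `i` sweeps `360·wᵢ/Σw` (equal weights by default);
  a category sweeps the exact sum of its children — conservation is exact;
* radius: tree depth `k` occupies the annulus `[k·w, (k+1)·w]`;
* color: leaf hue from the angular midpoint on the HSV wheel, categories
  the sweep-weighted mean of their children (bottom-up);
* height: `H0·(1 + subtree height)`.

Every remaining (non-tree) edge is drawn in the third dimension: the child
gets a satellite **orbit** circle on its layer (most-linked orbit outermost
and highest), each minor parent sends a single radial **downlink** ray, and
ray–orbit intersections are the **access points**.  Statistics map onto the
regions: e.g. the differential view sets height to `H0·log2(n_de + 1)` and
color to `log2((n_up+1)/(n_down+1))` on a green–white–red ramp, leaving
terms with fewer than `min_de` DE genes transparent.  Genes change state
when `|treatment − control| > 0.7` (strict, on the scale supplied; the
threshold and metric are configurable).  Overrepresentation of a gene list
in a term is the one-sided hypergeometric tail `P(X ≥ k)`.

For a single pathway, the **tiered layout** puts each entity type on its own
z-plane (metabolite, polypeptide, RNA, DNA, …), lays out the user-chosen
major plane with a seeded spring embedding, and places every other node at
the centroid of its already-placed neighbors — so proteins sit between
their substrates and RNAs/DNAs directly beneath their proteins.

## Worked example

```r
library(ersfviz)

g2  <- make_g2()                      # toy DAG: 13 terms, 4 non-tree edges
lay <- ersf_layout(g2)
glance(lay)
#> # A tibble: 1 × 6
#>   n_regions n_layers n_orbits n_rays n_access_points n_non_tree_edges
#>       <int>    <int>    <int>  <int>           <int>            <int>
#> 1        13        4        4      3               4                4
```

Thirteen annular regions over four rings; the four multi-parent pathways
each get an orbit, served by three downlink rays (category `C` links two
children through one ray, hence 4 access points on 3 rays).

```r
sim  <- synth_expression(800, conditions = c("ctrl", "trt"),
                         effects = data.frame(node = "C1",
                                              condition = "trt", shift = 2),
                         seed = 1)
sets <- aggregate_gene_sets(sim$annotation, lay$tree)
st   <- node_stats(sim$expr, sets, control = "ctrl", treatment = "trt")
dplyr::distinct(st[st$node %in% c("C1", "C2"),
                   c("node", "n_genes", "n_up", "n_down", "n_de")])
#> # A tibble: 2 × 5
#>   node  n_genes  n_up n_down  n_de
#>   <chr>   <int> <int>  <int> <int>
#> 1 C1         96    94      0    94
#> 2 C2         94    19     16    35
```

The +2 shift marks 94 of pathway `C1`'s 96 genes up-regulated (none down);
its unshifted sibling `C2` shows only the symmetric noise floor.  Render it:

```r
style <- style_differential_view(st, min_de = 5, H0 = 5)
ersf_to_svg(lay, "g2_de.svg", style = style)   # 2D sunburst
ersf_to_kml(lay, "g2_de.kml", style = style)   # extruded 3D scene
autoplot(lay, style = style)                   # quick ggplot preview

tp <- tiered_layout(synth_pathway("cycle", 6), seed = 42)
tiered_to_kml(tp, synth_pathway("cycle", 6), "cycle.kml")
```

A command-line wrapper covers the same ground
(`inst/cli/ersfviz ersf --ontology g2.tsv --out g2.svg`, plus `tiered` and
`fixtures` subcommands).

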