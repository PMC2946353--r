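# ERSF geometry: angles, radii, colors, heights, orbits, downlinks.

g1_tree <- extract_spanning_tree(make_g1())
g2_tree <- extract_spanning_tree(make_g2())

test_that("equal-weight G1 angles: 45-degree leaves and conserved sweeps", {
  ang <- assign_angles(g1_tree)
  sw <- stats::setNames(ang$sweep_angle, ang$node)
  leaves <- g1_tree$nodes$node[g1_tree$nodes$is_leaf]
  expect_equal(unname(sw[leaves]), rep(45, 8))
  expect_equal(unname(sw["A"]), 180)  # children A1, A2, AA
  expect_equal(unname(sw["B"]), 90)
  expect_equal(unname(sw["C"]), 90)
  expect_equal(unname(sw["R"]), 360)
})

test_that("leaf weights give proportional sweeps", {
  ang <- assign_angles(g1_tree, leaf_weights = c(AA1 = 2))
  sw <- stats::setNames(ang$sweep_angle, ang$node)
  # oracle: 360 * w / sum(w), sum(w) = 9
  expect_equal(unname(sw["AA1"]), 360 * 2 / 9)
  expect_equal(unname(sw["B1"]), 360 / 9)
  expect_error(assign_angles(g1_tree, leaf_weights = c(AA1 = -1)), "> 0")
  single <- extract_spanning_tree(
    ontology_graph(data.frame(parent = "A", child = "B")))
  expect_equal(assign_angles(single)$sweep_angle, c(360, 360))
})

test_that("angle conservation and gap-free siblings hold on random trees", {
  for (seed in 1:30) {
    n <- sample(2:50, 1)
    tr <- extract_spanning_tree(ontology_graph(random_tree_edges(n, seed)))
    w <- stats::setNames(stats::runif(sum(tr$nodes$is_leaf), 0.2, 3),
                         tr$nodes$node[tr$nodes$is_leaf])
    ang <- assign_angles(tr, w)
    sw <- stats::setNames(ang$sweep_angle, ang$node)
    st <- stats::setNames(ang$start_angle, ang$node)
    expect_equal(unname(sw[tr$root]), 360, tolerance = 1e-12)
    for (p in tr$nodes$node[!tr$nodes$is_leaf]) {
      kids <- sort(tr$nodes$node[!is.na(tr$nodes$major_parent) &
                                   tr$nodes$major_parent == p])
      expect_lt(abs(sw[p] - sum(sw[kids])), 1e-9)
      # contiguity: each next sibling starts where the previous one ends
      ends <- (st[kids] + sw[kids])
      if (length(kids) > 1) {
        expect_equal(unname(st[kids][-1]) %% 360,
                     unname(ends[-length(kids)]) %% 360, tolerance = 1e-9)
      }
      # containment within the parent interval
      expect_true(all(st[kids] - st[p] >= -1e-9 | sw[p] == 360))
    }
  }
})

test_that("radii stack in constant-width rings by depth", {
  rad <- assign_radii(g1_tree, ring_width = 10)
  r <- rad[rad$node == "AA1", ]
  expect_equal(c(r$inner_radius, r$outer_radius), c(30, 40))
  expect_equal(unlist(rad[rad$node == "R", c("inner_radius", "outer_radius")]),
               c(inner_radius = 0, outer_radius = 10))
  expect_equal(max(rad$outer_radius), (max(g1_tree$nodes$depth) + 1) * 10)
  expect_error(assign_radii(g1_tree, ring_width = 0))
})

test_that("structure colors: leaf hues from midpoints, parents are sweep-weighted blends", {
  ang <- assign_angles(g1_tree)
  col <- structure_colors(g1_tree, ang)
  # independent bottom-up recomputation
  mid <- stats::setNames((ang$start_angle + ang$sweep_angle / 2) %% 360,
                         ang$node)
  sw <- stats::setNames(ang$sweep_angle, ang$node)
  ref <- function(node) {
    kids <- sort(g1_tree$nodes$node[!is.na(g1_tree$nodes$major_parent) &
                                      g1_tree$nodes$major_parent == node])
    if (length(kids) == 0) {
      return(as.numeric(grDevices::col2rgb(
        grDevices::hsv(mid[[node]] / 360, 1, 1))) / 255)
    }
    m <- vapply(kids, ref, numeric(3))
    as.numeric(m %*% (sw[kids] / sum(sw[kids])))
  }
  for (node in col$node) {
    expect_equal(unlist(col[col$node == node, c("r", "g", "b")]),
                 ref(node), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # single-child parent inherits the child color exactly
  chain <- extract_spanning_tree(
    ontology_graph(data.frame(parent = c("A", "B"), child = c("B", "C"))))
  cc <- structure_colors(chain, assign_angles(chain))
  expect_equal(unlist(cc[cc$node == "A", c("r", "g", "b")]),
               unlist(cc[cc$node == "C", c("r", "g", "b")]),
               ignore_attr = TRUE)
})

test_that("two equal children at opposite hues blend to their mean", {
  # force children colored (1,0,0) and (0,0,1): hues 0 and 240 at equal sweep
  tr <- extract_spanning_tree(
    ontology_graph(data.frame(parent = c("P", "P", "P"),
                              child = c("u", "v", "w"))))
  ang <- assign_angles(tr)
  col <- structure_colors(tr, ang)
  mid <- (ang$start_angle + ang$sweep_angle / 2)[match(c("u", "v", "w"),
                                                       ang$node)]
  leafcol <- t(grDevices::col2rgb(grDevices::hsv(mid / 360, 1, 1))) / 255
  expect_equal(unlist(col[col$node == "P", c("r", "g", "b")]),
               colMeans(leafcol), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("subtree heights follow H0 * (1 + longest downward path)", {
  h <- subtree_heights(g1_tree, H0 = 5)
  hv <- stats::setNames(h$height, h$node)
  for (node in names(hv)) {
    expect_equal(unname(hv[node]),
                 5 * (1 + brute_subtree_height(node, g1_tree)))
  }
  expect_equal(unname(hv[c("AA1", "AA", "A", "R")]), c(5, 10, 15, 20))
  chain <- extract_spanning_tree(ontology_graph(
    data.frame(parent = c("a", "b", "c"), child = c("b", "c", "d"))))
  ch <- subtree_heights(chain, H0 = 2)
  expect_equal(stats::setNames(ch$height, ch$node)[c("a", "b", "c", "d")],
               2 * c(4, 3, 2, 1), ignore_attr = TRUE)
})

test_that("G1 has no orbits; G2 has one orbit per multi-parent child", {
  expect_equal(nrow(ersf_layout(make_g1())$orbits), 0)
  lay <- ersf_layout(make_g2())
  expect_equal(nrow(lay$orbits), 4)
  expect_setequal(lay$orbits$child, c("AA1", "AA2", "B1", "C1"))
  # orbits sit on the child's layer within the 0.3-0.7 band
  reg <- lay$regions
  for (i in seq_len(nrow(lay$orbits))) {
    o <- lay$orbits[i, ]
    rr <- reg[reg$node == o$child, ]
    expect_equal(o$layer, rr$layer)
    w <- rr$outer_radius - rr$inner_radius
    expect_gte(o$radius, rr$inner_radius + 0.3 * w - 1e-12)
    expect_lte(o$radius, rr$inner_radius + 0.7 * w + 1e-12)
  }
  # within a layer: distinct radii/altitudes, both ascending together
  for (l in unique(lay$orbits$layer)) {
    ol <- lay$orbits[lay$orbits$layer == l, ]
    expect_false(any(duplicated(ol$radius)))
    expect_false(any(duplicated(ol$altitude)))
    expect_equal(order(ol$radius), order(ol$altitude))
    expect_equal(order(ol$radius), order(ol$downlink_count, ol$child))
  }
  # orbit altitude clears the tallest region of its layer
  top <- tapply(reg$height, reg$layer, max)
  expect_true(all(lay$orbits$altitude >
                    top[as.character(lay$orbits$layer)]))
})

test_that("most-linked orbit is outermost and highest; count-ties break by id", {
  # layer-2 children x,y,z: z has two minor parents, x and y one each
  edges <- data.frame(
    parent = c("R", "R", "R", "R", "A", "A", "A", "B", "B", "C", "D"),
    child = c("A", "B", "C", "D", "x", "y", "z", "z", "x", "z", "y"))
  tr <- extract_spanning_tree(ontology_graph(edges))
  lay <- ersf_layout(ontology_graph(edges))
  ol <- lay$orbits[order(lay$orbits$radius), ]
  expect_equal(ol$child, c("x", "y", "z"))  # counts 1,1,2; ties x<y
  expect_equal(ol$downlink_count, c(1L, 1L, 2L))
  expect_equal(order(ol$altitude), 1:3)
})

test_that("downlink rays: one per minor parent, access points on orbit circles", {
  lay <- ersf_layout(make_g2())
  expect_equal(sort(lay$rays$parent), c("A", "B", "C"))
  expect_equal(nrow(lay$access_points), 4)
  cr <- lay$rays[lay$rays$parent == "C", ]
  caps <- lay$access_points[lay$access_points$parent == "C", ]
  expect_equal(sort(caps$child), c("AA1", "AA2"))
  # inner access point belongs to the smaller orbit radius
  orad <- stats::setNames(lay$orbits$radius, lay$orbits$child)
  expect_equal(caps$radius, unname(orad[caps$child]))
  near <- caps$child[which.min(caps$radius)]
  oc <- lay$orbits[lay$orbits$child %in% c("AA1", "AA2"), ]
  expect_equal(near, oc$child[which.min(oc$radius)])
  # both segments share the anchor angle; ray spans anchor to farthest orbit
  expect_true(all(caps$angle == cr$angle))
  expect_equal(cr$r_to, max(cr$r_anchor, max(caps$radius)))
  expect_equal(cr$r_from, min(cr$r_anchor, min(caps$radius)))
  # access points lie on their orbit circle
  expect_equal(sqrt(caps$x^2 + caps$y^2), caps$radius, tolerance = 1e-9)
})

test_that("orbit count matches brute-force multi-parent census on random DAGs", {
  for (seed in 1:30) {
    n <- sample(5:50, 1)
    g <- normalize_root(random_dag(n, extra = sample(0:8, 1), seed = seed + 100))
    lay <- ersf_layout(g)
    expect_equal(nrow(lay$orbits), brute_multi_parent_count(g))
    expect_equal(nrow(lay$rays),
                 length(unique(lay$tree$non_tree_edges$parent)))
    expect_equal(nrow(lay$access_points), nrow(lay$tree$non_tree_edges))
  }
})

test_that("identical input yields byte-identical serialized layout", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_layout_json(ersf_layout(make_g2()), f1)
  write_layout_json(ersf_layout(make_g2()), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hide_root drops only the root disc", {
  lay <- ersf_layout(make_g1(), hide_root = TRUE)
  expect_false("R" %in% lay$regions$node)
  expect_equal(nrow(lay$regions), 12)
})
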