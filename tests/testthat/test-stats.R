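# Gene-set aggregation, CoV, DE classification, Fisher test, style maps.

test_that("gene sets union up the tree without double counting", {
  tr <- extract_spanning_tree(make_g1())
  ann <- tibble::tibble(node = c("A1", "A1", "A2", "A2"),
                        gene = c("g1", "g2", "g2", "g3"))
  sets <- aggregate_gene_sets(ann, tr)
  expect_equal(sets[["A1"]], c("g1", "g2"))
  expect_equal(sets[["A"]], c("g1", "g2", "g3"))
  expect_equal(sets[["B"]], character(0))
  expect_error(aggregate_gene_sets(tibble::tibble(node = "ZZ", gene = "g"), tr),
               "ZZ")
})

test_that("aggregation equals brute-force descendant union on random annotations", {
  tr <- extract_spanning_tree(make_g2())
  set.seed(11)
  leaves <- tr$nodes$node[tr$nodes$is_leaf]
  ann <- tibble::tibble(node = sample(leaves, 60, replace = TRUE),
                        gene = sample(sprintf("g%02d", 1:25), 60,
                                      replace = TRUE))
  ann <- dplyr::distinct(ann)
  sets <- aggregate_gene_sets(ann, tr)
  for (node in tr$nodes$node) {
    expect_equal(sets[[node]], brute_descendant_union(node, tr, ann))
  }
  # idempotence
  expect_identical(sets, aggregate_gene_sets(ann, tr))
})

test_that("CoV is the population sigma/mu and scale-invariant", {
  expect_equal(compute_cov(c(2, 4, 6)), sqrt(8 / 3) / 4, tolerance = 1e-12)
  expect_equal(compute_cov(c(5, 5, 5)), 0)
  expect_warning(expect_true(is.na(compute_cov(c(-1, 1)))), "zero mean")
  expect_equal(compute_cov(c(2, NA, 4, 6, NA)), compute_cov(c(2, 4, 6)))
  set.seed(42)
  for (i in 1:1000) {
    x <- stats::runif(sample(2:12, 1), 0.1, 10)
    c0 <- compute_cov(x)
    # direct formula
    expect_equal(c0, sqrt(mean((x - mean(x))^2)) / mean(x), tolerance = 1e-12)
    # scale invariance
    expect_equal(compute_cov(stats::runif(1, 0.5, 20) * x), c0,
                 tolerance = 1e-9)
  }
})

test_that("DE classification uses a strict threshold with sign direction", {
  expect_equal(as.character(classify_differential(1.0, 2.0)), "up")
  expect_equal(as.character(classify_differential(2.0, 1.3)), "unchanged")
  expect_equal(as.character(classify_differential(2.0, 1.2)), "down")
  expect_equal(as.character(classify_differential(NA, 5)), "unchanged")
  expect_equal(as.character(classify_differential(1, 3, threshold = 1,
                                                  metric = "ratio")), "up")
  cls <- classify_differential(c(0, 0, 0), c(1, -1, 0.5))
  expect_equal(as.character(cls), c("up", "down", "unchanged"))
})

test_that("Fisher p-value matches the worked 2x2 example and degenerate cases", {
  u <- sprintf("g%02d", 1:10)
  p <- fisher_overrepresentation(u[1:5], u[c(1:4, 6)], u)
  expect_equal(p, 26 / 252, tolerance = 1e-12)
  expect_equal(fisher_overrepresentation(u[6:10], u[1:5], u), 1)  # k = 0
  expect_equal(fisher_overrepresentation(u[1:3], u, u), 1)  # node = universe
  expect_error(fisher_overrepresentation("a", "a", character(0)), "empty")
  expect_error(fisher_overrepresentation("zz", u[1:2], u), "subset")
})

test_that("Fisher matches exhaustive enumeration for every table, universe <= 20", {
  for (N in c(1:10, 15, 20)) {
    u <- sprintf("u%02d", 1:N)
    for (m in 0:N) for (s in 0:N) {
      node <- utils::head(u, m)
      others <- setdiff(u, node)
      for (k in max(0, m + s - N):min(m, s)) {
        sel <- c(utils::head(node, k), utils::head(others, s - k))
        expect_equal(fisher_overrepresentation(sel, node, u),
                     brute_hyper_upper(k, m, s, N), tolerance = 1e-12)
      }
    }
  }
})

test_that("one-sided p-value is monotone decreasing in the overlap", {
  # fixed margins m = 6, s = 5, N = 15; grow k by swapping genes
  u <- sprintf("u%02d", 1:15)
  node <- u[1:6]
  ps <- vapply(0:5, function(k) {
    sel <- c(utils::head(node, k), utils::head(setdiff(u, node), 5 - k))
    fisher_overrepresentation(sel, node, u)
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("node_stats aggregates means, CoV and conserves DE counts", {
  tr <- extract_spanning_tree(make_g1())
  expr <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         ctrl = c(1, 2, 3), trt = c(2.5, 1.0, 3.2))
  ann <- tibble::tibble(node = c("A1", "A1", "A2"), gene = c("g1", "g2", "g3"))
  sets <- aggregate_gene_sets(ann, tr)
  st <- node_stats(expr, sets, control = "ctrl", treatment = "trt")
  a <- st[st$node == "A" & st$condition == "ctrl", ]
  expect_equal(a$n_genes, 3)
  expect_equal(a$mean, 2)
  expect_equal(a$median, 2)
  # per-gene classes: up (1.5), down (-1.0), unchanged (0.2)
  expect_equal(a$n_up, 1); expect_equal(a$n_down, 1); expect_equal(a$n_de, 2)
  expect_true(all(st$n_de == st$n_up + st$n_down, na.rm = TRUE))
  # unannotated subtree gets NA stats and zero counts
  b <- st[st$node == "B" & st$condition == "ctrl", ]
  expect_true(is.na(b$mean)); expect_equal(b$n_de, 0)
  expect_error(node_stats(expr, sets, control = "ctrl", treatment = "oops"),
               "unknown condition")
})

test_that("value styling maps range endpoints to ramp endpoints", {
  stats_tbl <- tibble::tibble(node = c("a", "b", "c", "d"),
                              mean = c(0, 5, 10, NA))
  st <- style_by_value(stats_tbl, "mean", encoding = "both", Hmax = 30)
  expect_equal(unlist(st[st$node == "a", c("r", "g", "b")]),
               c(r = 0, g = 1, b = 0))  # pure green at min
  expect_equal(unlist(st[st$node == "c", c("r", "g", "b")]),
               c(r = 1, g = 0, b = 0))  # pure red at max
  expect_equal(unlist(st[st$node == "b", c("r", "g", "b")]),
               c(r = 1, g = 1, b = 0))  # yellow mid
  expect_equal(st$height[st$node == "c"], 30)
  # missing -> grey, flat
  expect_equal(unlist(st[st$node == "d", c("r", "g", "b", "height")]),
               c(r = 0.6, g = 0.6, b = 0.6, height = 0))
  expect_warning(style_by_value(tibble::tibble(node = "a", mean = 1), "mean"),
                 "degenerate")
  # a fixed shared range makes equal stats render identically across frames
  s1 <- style_by_value(tibble::tibble(node = "a", mean = 3), "mean",
                       range = c(0, 10))
  s2 <- style_by_value(tibble::tibble(node = "a", mean = 3), "mean",
                       range = c(0, 10))
  expect_identical(s1[, c("r", "g", "b", "height")],
                   s2[, c("r", "g", "b", "height")])
})

test_that("differential view: log2 height, ratio color, transparency cutoff", {
  d <- tibble::tibble(node = c("bal", "none", "up7"),
                      n_up = c(3L, 0L, 7L), n_down = c(3L, 0L, 1L),
                      n_de = c(6L, 0L, 8L))
  st <- style_differential_view(d, min_de = 5, H0 = 5)
  bal <- st[st$node == "bal", ]
  expect_equal(unlist(bal[, c("r", "g", "b")]), c(r = 1, g = 1, b = 1))  # white
  none <- st[st$node == "none", ]
  expect_equal(none$height, 0)
  expect_false(none$visible)
  up7 <- st[st$node == "up7", ]  # s = log2(8/2) = 2 of 3 -> strong red
  expect_equal(up7$height, 5 * log2(9))
  expect_gt(up7$r, up7$g)
  expect_equal(unname(unlist(up7[, c("g", "b")])), rep(1 - 2 / 3, 2),
               tolerance = 1e-12)
  expect_true(up7$visible)
  expect_true(bal$visible)  # 6 >= min_de
})

test_that("animation frames follow matrix column order and honor reordering", {
  sim <- synth_expression(30, conditions = paste0("c", 1:7), seed = 3)
  tr <- extract_spanning_tree(sim$graph)
  sets <- aggregate_gene_sets(sim$annotation, tr)
  fr <- build_animation_frames(sim$expr, sets)
  expect_equal(names(fr), paste0("c", 1:7))
  expect_equal(length(fr), 7)
  fr2 <- build_animation_frames(sim$expr, sets, conditions = c("c3", "c1"))
  expect_equal(names(fr2), c("c3", "c1"))
  expect_error(build_animation_frames(sim$expr, sets, conditions = "c99"),
               "unknown condition")
  one <- build_animation_frames(sim$expr[, c("gene", "c1")], sets)
  expect_equal(length(one), 1)
})

test_that("selected-region gene dump writes the genes-by-conditions slice", {
  sim <- synth_expression(25, conditions = c("a", "b"), seed = 5)
  tr <- extract_spanning_tree(sim$graph)
  sets <- aggregate_gene_sets(sim$annotation, tr)
  out <- tempfile(fileext = ".csv")
  slice <- write_node_genes_csv(sim$expr, sets, "A", out)
  back <- utils::read.csv(out)
  expect_equal(nrow(back), length(intersect(sets[["A"]], sim$expr$gene)))
  expect_equal(names(back), c("gene", "a", "b"))
  expect_error(write_node_genes_csv(sim$expr, sets, "nope", out), "unknown")
})
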