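# Shared generators and independent oracles used across the suite.

# random rooted tree on n nodes: node i > 1 attaches to a uniform earlier node
random_tree_edges <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  if (n == 1) return(tibble::tibble(parent = character(0), child = character(0)))
  parent_idx <- vapply(2:n, function(i) sample.int(i - 1, 1), 0L)
  tibble::tibble(parent = ids[parent_idx], child = ids[2:n])
}

# random single-rooted DAG: a random tree plus extra forward edges
random_dag <- function(n, extra = 3, seed = 1) {
  set.seed(seed)
  edges <- random_tree_edges(n, seed)
  ids <- sprintf("n%03d", seq_len(n))
  have <- paste(edges$parent, edges$child)
  tries <- 0
  while (extra > 0 && tries < 200) {
    ij <- sort(sample.int(n, 2))
    e <- paste(ids[ij[1]], ids[ij[2]])
    tries <- tries + 1
    if (ij[2] > 1 && !e %in% have) {
      edges <- rbind(edges, tibble::tibble(parent = ids[ij[1]],
                                           child = ids[ij[2]]))
      have <- c(have, e)
      extra <- extra - 1
    }
  }
  ontology_graph(edges)
}

# brute-force count of nodes with >= 2 parents
brute_multi_parent_count <- function(g) {
  sum(table(g$edges$child) >= 2)
}

# exhaustive upper-tail hypergeometric: P(overlap >= k) by direct summation
brute_hyper_upper <- function(k, n_node, n_sel, n_universe) {
  jmax <- min(n_node, n_sel)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    choose(n_node, j) * choose(n_universe - n_node, n_sel - j)
  }, 0)) / choose(n_universe, n_sel)
}

# brute-force union of gene annotations over all tree descendants of a node
brute_descendant_union <- function(node, tree, annotation) {
  kids <- tree$nodes$node[!is.na(tree$nodes$major_parent) &
                            tree$nodes$major_parent == node]
  own <- annotation$gene[annotation$node == node]
  sort(unique(c(own, unlist(lapply(kids, brute_descendant_union, tree = tree,
                                   annotation = annotation)))))
}

# longest downward tree path from a node (edge count), by recursion
brute_subtree_height <- function(node, tree) {
  kids <- tree$nodes$node[!is.na(tree$nodes$major_parent) &
                            tree$nodes$major_parent == node]
  if (length(kids) == 0) return(0L)
  1L + max(vapply(kids, brute_subtree_height, 0L, tree = tree))
}

expect_wellformed_xml <- function(path) {
  expect_silent(x <- xml2::read_xml(path))
  invisible(x)
}

kml_find <- function(doc, what) {
  xml2::xml_find_all(doc, paste0("//d1:", what),
                     ns = xml2::xml_ns(doc))
}
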