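# Ontology DAG model: parsing, validation, virtual-root normalization and
# extraction of the major-parent spanning tree the ERSF layout is drawn on.

new_ontology_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "ontology_graph")
}

#' Construct an ontology graph from node and edge tables
#'
#' An ontology is modelled as a directed acyclic graph (DAG) of terms with
#' parent-to-child edges.  Edge insertion order is preserved: it is the
#' deterministic tie-break used when a multi-parent term's major parent is
#' chosen (see [extract_spanning_tree()]).
#'
#' @param edges A data frame with character columns `parent` and `child`,
#'   one row per directed parent-to-child edge, in input order.
#' @param nodes Optional data frame with columns `id` and `name`.  Nodes are
#'   otherwise inferred from edge endpoints, with `name = id`.
#' @return An `ontology_graph`: a list with tibbles `nodes` (`id`, `name`)
#'   and `edges` (`parent`, `child`).
#' @examples
#' g <- ontology_graph(data.frame(parent = "A", child = "B"))
#' ontology_roots(g)
#' @export
ontology_graph <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)[, c("parent", "child")]
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  ids <- unique(c(edges$parent, edges$child))
  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = ids, name = ids)
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!"name" %in% names(nodes)) nodes$name <- nodes$id
    nodes <- nodes[, c("id", "name")]
    nodes$id <- as.character(nodes$id)
    nodes$name <- as.character(nodes$name)
    extra <- setdiff(ids, nodes$id)
    if (length(extra) > 0) {
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(id = extra, name = extra))
    }
  }
  g <- new_ontology_graph(nodes, edges)
  validate_ontology(g)
  g
}

# Shared structural validation: endpoints, duplicates, self-loops, acyclicity.
validate_ontology <- function(g) {
  edges <- g$edges
  if (nrow(g$nodes) == 0) stop("ontology graph is empty", call. = FALSE)
  loops <- edges$parent == edges$child
  if (any(loops)) {
    stop("self-loop edge: ", edges$parent[which(loops)[1]], call. = FALSE)
  }
  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), ]
    stop("duplicate edge: ", d$parent[1], " -> ", d$child[1], call. = FALSE)
  }
  missing <- setdiff(unique(c(edges$parent, edges$child)), g$nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint not in node set: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(edges) > 0) {
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(ig)) {
      # name one member of a cycle for the error message
      member <- cycle_member(edges)
      stop("ontology graph is cyclic (cycle includes node '", member, "')",
           call. = FALSE)
    }
  }
  invisible(g)
}

# Find one node on a directed cycle by peeling nodes of in-degree zero.
cycle_member <- function(edges) {
  nodes <- unique(c(edges$parent, edges$child))
  repeat {
    indeg <- table(factor(edges$child, levels = nodes))
    src <- nodes[indeg == 0]
    if (length(src) == 0) return(sort(nodes)[1])
    nodes <- setdiff(nodes, src)
    edges <- edges[!(edges$parent %in% src), , drop = FALSE]
    if (length(nodes) == 0) return(NA_character_)
  }
}

#' Root ids of an ontology graph
#'
#' @param g An `ontology_graph`.
#' @return Character vector of node ids with no incoming edge, in node order.
#' @export
ontology_roots <- function(g) {
  setdiff(g$nodes$id, unique(g$edges$child))
}

#' @export
print.ontology_graph <- function(x, ...) {
  roots <- ontology_roots(x)
  cat("<ontology_graph> ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " edges, root", if (length(roots) != 1) "s", ": ",
      paste(utils::head(roots, 5), collapse = ", "),
      if (length(roots) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' Parse a parent/child edge-list TSV into an ontology graph
#'
#' The format is two tab-separated columns `parent<TAB>child`, UTF-8, with
#' `#` comment lines and an optional `parent\tchild` header.  Row order is
#' preserved and meaningful (first-listed parent wins major-parent ties).
#'
#' @param path Path to the TSV file.
#' @return An `ontology_graph`.
#' @seealso [parse_obo()], [write_edge_list()]
#' @export
parse_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no edges in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != 2L |
                 vapply(fields, function(f) any(!nzchar(trimws(f[1:2]))), TRUE))
  if (length(bad) > 0) {
    stop("malformed edge row at line ", keep[bad[1]], ": '",
         lines[keep[bad[1]]], "'", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  edges <- tibble::tibble(parent = trimws(m[, 1]), child = trimws(m[, 2]))
  if (edges$parent[1] == "parent" && edges$child[1] == "child") {
    edges <- edges[-1, , drop = FALSE]
  }
  if (nrow(edges) == 0) stop("no edges in ", path, call. = FALSE)
  ontology_graph(edges)
}

#' Write an ontology graph as an edge-list TSV
#'
#' @param g An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(as.data.frame(g$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse a minimal OBO 1.2 subset into an ontology graph
#'
#' Reads `[Term]` stanzas with `id:`, `name:`, `is_a:` and `is_obsolete:`
#' tags.  Each `child is_a parent` assertion becomes a parent-to-child edge.
#' Obsolete terms are skipped; relationship types other than `is_a`
#' (`relationship: part_of ...` etc.) are ignored with a warning giving the
#' count, since only one hierarchy relation is drawn.
#'
#' @param path Path to the OBO file.
#' @return An `ontology_graph`.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)
  if (length(term_starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0)
  edge_parent <- character(0); edge_child <- character(0)
  n_ignored <- 0L
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[(s + 1L):end]
    tagval <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), body, value = TRUE)
      trimws(sub(paste0("^", tag, ":\\s*"), "", hits))
    }
    if (any(grepl("^is_obsolete:\\s*true", body))) next
    id <- tagval("id")
    if (length(id) == 0) {
      stop("[Term] stanza without id: near line ", s, call. = FALSE)
    }
    id <- id[1]
    nm <- tagval("name")
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm) > 0) nm[1] else id)
    isa <- tagval("is_a")
    # strip trailing "! name" comments
    isa <- trimws(sub("!.*$", "", isa))
    edge_parent <- c(edge_parent, isa)
    edge_child <- c(edge_child, rep(id, length(isa)))
    n_ignored <- n_ignored + sum(grepl("^relationship:", body))
  }
  if (n_ignored > 0) {
    warning(n_ignored, " non-is_a relationship tag(s) ignored", call. = FALSE)
  }
  dangling <- setdiff(edge_parent, ids)
  if (length(dangling) > 0) {
    stop("is_a target(s) not defined as terms: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  ontology_graph(
    edges = tibble::tibble(parent = edge_parent, child = edge_child),
    nodes = tibble::tibble(id = ids, name = names_)
  )
}

#' Collapse multiple roots under a single virtual root
#'
#' Ontologies like the Gene Ontology have several namespace roots; the radial
#' layout needs exactly one.  When the graph has more than one root a virtual
#' root `__ROOT__` is inserted with an edge to each former root; a
#' single-rooted graph is returned unchanged.
#'
#' @param g An `ontology_graph`.
#' @param root_id Id for the inserted virtual root.
#' @return An `ontology_graph` with exactly one root.
#' @export
normalize_root <- function(g, root_id = "__ROOT__") {
  stopifnot(inherits(g, "ontology_graph"))
  if (nrow(g$nodes) == 0) stop("ontology graph is empty", call. = FALSE)
  roots <- ontology_roots(g)
  if (length(roots) == 0) stop("graph has no root", call. = FALSE)
  if (length(roots) == 1) return(g)
  if (root_id %in% g$nodes$id) {
    stop("virtual root id '", root_id, "' already used", call. = FALSE)
  }
  ontology_graph(
    edges = dplyr::bind_rows(
      tibble::tibble(parent = root_id, child = roots),
      g$edges
    ),
    nodes = dplyr::bind_rows(
      tibble::tibble(id = root_id, name = root_id), g$nodes
    )
  )
}

#' Extract the major-parent spanning tree of an ontology DAG
#'
#' Each multi-parent term keeps exactly one *major* parent — the parent of
#' its first-listed incoming edge — under which its annular region is drawn;
#' every other in-edge becomes a *non-tree* edge from a *minor* parent and is
#' later rendered as an orbit/downlink.  Depths are computed over tree edges
#' only, so `depth(child) = depth(major parent) + 1` and the root has depth 0.
#'
#' @param g A single-rooted `ontology_graph` (see [normalize_root()]).
#' @return A `spanning_tree`: list with `nodes` (tibble `node`, `depth`,
#'   `major_parent` (`NA` for the root), `is_leaf`), `non_tree_edges`
#'   (tibble `parent`, `child`, in input order) and `root`.
#' @examples
#' g2 <- make_g2()
#' tr <- extract_spanning_tree(g2)
#' tr$non_tree_edges
#' @export
extract_spanning_tree <- function(g) {
  stopifnot(inherits(g, "ontology_graph"))
  validate_ontology(g)
  roots <- ontology_roots(g)
  if (length(roots) != 1) {
    stop("graph must have exactly one root (got ", length(roots),
         "); call normalize_root() first", call. = FALSE)
  }
  root <- roots
  edges <- g$edges
  first <- !duplicated(edges$child)
  major <- stats::setNames(edges$parent[first], edges$child[first])
  non_tree <- edges[!first, , drop = FALSE]

  depth <- stats::setNames(rep(NA_integer_, nrow(g$nodes)), g$nodes$id)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier) > 0) {
    kids <- names(major)[major %in% frontier]
    depth[kids] <- depth[major[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(depth)) {
    stop("node(s) unreachable from root over tree edges: ",
         paste(names(depth)[is.na(depth)], collapse = ", "), call. = FALSE)
  }
  ids <- g$nodes$id
  structure(list(
    nodes = tibble::tibble(
      node = ids,
      depth = unname(depth[ids]),
      major_parent = unname(major[ids]),
      is_leaf = !(ids %in% edges$parent)
    ),
    non_tree_edges = tibble::as_tibble(non_tree),
    root = root
  ), class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("<spanning_tree> root '", x$root, "', ", nrow(x$nodes), " nodes, depth ",
      max(x$nodes$depth), ", ", nrow(x$non_tree_edges), " non-tree edge(s)\n",
      sep = "")
  invisible(x)
}

#' @rdname extract_spanning_tree
#' @param x A `spanning_tree`.
#' @param ... Unused.
#' @method tidy spanning_tree
#' @export
tidy.spanning_tree <- function(x, ...) x$nodes

# children of each node in the spanning tree, lexicographic id order
tree_children <- function(tree) {
  nd <- tree$nodes[!is.na(tree$nodes$major_parent), ]
  split(nd$node, factor(nd$major_parent, levels = unique(tree$nodes$node))) |>
    lapply(sort)
}

#' Serialize a spanning tree as a debug TSV
#'
#' Columns `node<TAB>depth<TAB>major_parent`, nodes sorted by id for
#' byte-stable output; the root's major parent is the empty string.
#'
#' @param tree A `spanning_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spanning_tree <- function(tree, path) {
  nd <- dplyr::arrange(tree$nodes, .data$node)
  nd$major_parent[is.na(nd$major_parent)] <- ""
  utils::write.table(as.data.frame(nd[, c("node", "depth", "major_parent")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
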