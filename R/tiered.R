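# 3D aligned tiered layout for a typed pathway graph: one z-plane per entity
# type (metabolite, polypeptide, RNA, DNA, ...), a force-directed embedding
# of the user-selected major plane first, then the remaining planes cascaded
# downward so each node sits at the centroid of its already-placed neighbors
# — RNAs and DNAs end up directly under their respective polypeptides.

PLANE_ORDER_DEFAULT <- c("metabolite", "polypeptide", "RNA", "DNA", "other")

#' Construct a typed pathway graph
#'
#' @param nodes Data frame with columns `id`, `type` and optionally `label`.
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `interaction`.
#' @return A `pathway_graph`: list of tibbles `nodes`, `edges`.
#' @export
pathway_graph <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "label", "type")]
  nodes$id <- as.character(nodes$id)
  edges <- tibble::as_tibble(edges)
  if (!"interaction" %in% names(edges)) edges$interaction <- "interacts"
  edges <- edges[, c("source", "target", "interaction")]
  if (anyDuplicated(nodes$id)) stop("duplicate node id", call. = FALSE)
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not in node table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' Parse a typed interaction network TSV
#'
#' Five tab-separated columns
#' `source<TAB>target<TAB>source_type<TAB>target_type<TAB>interaction`, `#`
#' comments and an optional header allowed.
#'
#' @param path TSV path.
#' @return A `pathway_graph`.
#' @export
parse_network_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("source", "target", "source_type",
                                        "target_type", "interaction"))
  if (identical(df[1, 1], "source")) df <- df[-1, , drop = FALSE]
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(id = df$source, type = df$source_type),
    tibble::tibble(id = df$target, type = df$target_type)))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    stop("conflicting types for node(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  pathway_graph(nodes, df[, c("source", "target", "interaction")])
}

#' Assign a z-plane to every node by entity type
#'
#' Planes are stacked top-down in `order`: `z = -dz * rank(type)`, the first
#' listed type at `z = 0`.
#'
#' @param g A `pathway_graph`.
#' @param order Character vector of entity types, top plane first.
#' @param dz Vertical spacing between planes (layout units).
#' @param aliases Optional named character vector mapping input types to
#'   types in `order` (e.g. `c(complex = "polypeptide")`).
#' @return Tibble `id`, `type`, `plane`, `z`.
#' @export
assign_planes <- function(g, order = PLANE_ORDER_DEFAULT, dz = 20,
                          aliases = NULL) {
  type <- g$nodes$type
  if (!is.null(aliases)) {
    hit <- type %in% names(aliases)
    type[hit] <- unname(aliases[type[hit]])
  }
  unknown <- setdiff(unique(type), order)
  if (length(unknown) > 0) {
    stop("entity type(s) not in plane order (alias them or extend `order`): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rank <- match(type, order) - 1L
  tibble::tibble(id = g$nodes$id, type = g$nodes$type, plane = type,
                 z = -dz * rank)
}

#' Force-directed layout of the major plane
#'
#' Embeds the subgraph induced on the major-type nodes with a deterministic
#' spring (Fruchterman-Reingold) layout: fixed seed, 500 iterations, unit
#' ideal edge length.  Edges between two major nodes are kept, and a pair of
#' major nodes connected through a single non-major intermediary (e.g.
#' metabolite-reaction-metabolite) is joined directly for layout purposes.
#'
#' @param g A `pathway_graph`.
#' @param major Entity type of the major plane.
#' @param seed Integer random seed (default 42).
#' @param planes Optional output of [assign_planes()] (used to resolve type
#'   aliases); defaults to the raw node types.
#' @return Tibble `id`, `x`, `y` for major-plane nodes.
#' @export
layout_major_plane <- function(g, major = "metabolite", seed = 42,
                               planes = NULL) {
  type <- if (is.null(planes)) {
    stats::setNames(g$nodes$type, g$nodes$id)
  } else {
    stats::setNames(planes$plane, planes$id)
  }
  major_ids <- sort(names(type)[type == major])
  if (length(major_ids) == 0) {
    stop("no nodes of major type '", major, "'; available types: ",
         paste(sort(unique(type)), collapse = ", "), call. = FALSE)
  }
  if (length(major_ids) == 1) {
    return(tibble::tibble(id = major_ids, x = 0, y = 0))
  }
  ed <- g$edges
  direct <- ed[type[ed$source] == major & type[ed$target] == major,
               c("source", "target")]
  # collapse major-X-major paths through one non-major intermediary
  bridged <- purrr::map_dfr(names(type)[type != major], function(mid) {
    nb <- unique(c(ed$target[ed$source == mid], ed$source[ed$target == mid]))
    nb <- sort(nb[type[nb] == major])
    if (length(nb) < 2) return(NULL)
    pairs <- utils::combn(nb, 2)
    tibble::tibble(source = pairs[1, ], target = pairs[2, ])
  })
  lay_edges <- dplyr::distinct(dplyr::bind_rows(direct, bridged))
  ig <- igraph::graph_from_data_frame(lay_edges, directed = FALSE,
                                      vertices = major_ids)
  ig <- igraph::simplify(ig)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(ig, niter = 500, dim = 2)
  xy <- sweep(xy, 2, colMeans(xy))  # center at origin
  tibble::tibble(id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]) |>
    dplyr::arrange(.data$id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cascade non-major planes under the major plane
#'
#' Planes are processed top-down; each unplaced node takes the centroid of
#' its already-placed neighbors' `(x, y)` (so a node with a single placed
#' neighbor projects exactly onto it — the "aligned" property).  Nodes with
#' no placed neighbor wait for the next pass; after placement stalls, the
#' orphans are laid on a grid at the plane margin.  Finally, nodes of one
#' plane closer than `r_min` are fanned out on a deterministic circle of
#' radius `r_min` around their common centroid, in id order.  Major-plane
#' coordinates are never moved.
#'
#' @param g A `pathway_graph`.
#' @param major_xy Output of [layout_major_plane()].
#' @param planes Output of [assign_planes()].
#' @param r_min Collision radius (layout units).
#' @param resolve_collisions Set `FALSE` to keep raw centroid positions.
#' @return A `tiered_positions`: tibble `id`, `label`, `type`, `plane`, `x`,
#'   `y`, `z` wrapped with the plane order and spacing.
#' @export
cascade_align <- function(g, major_xy, planes, r_min = 0.5,
                          resolve_collisions = TRUE) {
  pos <- stats::setNames(vector("list", nrow(g$nodes)), g$nodes$id)
  for (i in seq_len(nrow(major_xy))) {
    pos[[major_xy$id[i]]] <- c(major_xy$x[i], major_xy$y[i])
  }
  plane_of <- stats::setNames(planes$plane, planes$id)
  plane_seq <- unique(planes$plane[order(-planes$z)])
  ed <- g$edges
  neighbors <- function(id) {
    unique(c(ed$target[ed$source == id], ed$source[ed$target == id]))
  }
  unplaced <- function() names(pos)[vapply(pos, is.null, TRUE)]
  # centroid passes: plane order, then id order within a pass; positions from
  # the previous pass are frozen during a pass for determinism
  repeat {
    todo <- unplaced()
    if (length(todo) == 0) break
    snapshot <- pos
    progress <- FALSE
    for (pl in plane_seq) {
      for (id in sort(todo[plane_of[todo] == pl])) {
        nb <- neighbors(id)
        placed_nb <- nb[!vapply(snapshot[nb], is.null, TRUE)]
        if (length(placed_nb) > 0) {
          m <- do.call(rbind, snapshot[placed_nb])
          pos[[id]] <- colMeans(m)
          progress <- TRUE
        }
      }
    }
    if (!progress) break
  }
  orphans <- unplaced()
  if (length(orphans) > 0) {
    placed_m <- do.call(rbind, pos[!vapply(pos, is.null, TRUE)])
    x0 <- if (is.null(placed_m)) 0 else max(placed_m[, 1]) + 4 * r_min
    y0 <- if (is.null(placed_m)) 0 else min(placed_m[, 2])
    side <- ceiling(sqrt(length(orphans)))
    for (i in seq_along(sort(orphans))) {
      id <- sort(orphans)[i]
      pos[[id]] <- c(x0 + ((i - 1) %% side) * 4 * r_min,
                     y0 + ((i - 1) %/% side) * 4 * r_min)
    }
  }
  out <- tibble::tibble(
    id = g$nodes$id, label = g$nodes$label, type = g$nodes$type,
    plane = unname(plane_of[g$nodes$id]),
    x = unname(vapply(pos[g$nodes$id], `[`, 0, 1)),
    y = unname(vapply(pos[g$nodes$id], `[`, 0, 2)),
    z = planes$z[match(g$nodes$id, planes$id)])
  if (resolve_collisions) {
    major_ids <- major_xy$id
    for (pl in unique(out$plane)) {
      idx <- which(out$plane == pl & !(out$id %in% major_ids))
      if (length(idx) < 2) next
      clusters <- proximity_clusters(out$x[idx], out$y[idx], r_min)
      for (cl in clusters) {
        if (length(cl) < 2) next
        members <- idx[cl][order(out$id[idx[cl]])]
        cx <- mean(out$x[members]); cy <- mean(out$y[members])
        ang <- 2 * pi * (seq_along(members) - 1) / length(members)
        out$x[members] <- cx + r_min * cos(ang)
        out$y[members] <- cy + r_min * sin(ang)
      }
    }
  }
  structure(list(positions = out,
                 plane_order = plane_seq,
                 params = list(r_min = r_min)),
            class = "tiered_positions")
}

# single-linkage clusters of points closer than r_min (union-find)
proximity_clusters <- function(x, y, r_min) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < r_min) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

#' Compute the full aligned tiered layout
#'
#' Pipeline: [assign_planes()], [layout_major_plane()] on the user-selected
#' major plane, then [cascade_align()].
#'
#' @param g A `pathway_graph`.
#' @param major Major-plane entity type (default `"metabolite"`).
#' @param order Plane order, top first.
#' @param dz Plane spacing.
#' @param seed Spring-layout seed.
#' @param aliases,r_min See [assign_planes()] and [cascade_align()].
#' @return A `tiered_positions` object.
#' @examples
#' tp <- tiered_layout(synth_pathway("cycle", 6))
#' tidy(tp)
#' @export
tiered_layout <- function(g, major = "metabolite", order = PLANE_ORDER_DEFAULT,
                          dz = 20, seed = 42, aliases = NULL, r_min = 0.5) {
  planes <- assign_planes(g, order = order, dz = dz, aliases = aliases)
  major_xy <- layout_major_plane(g, major = major, seed = seed, planes = planes)
  cascade_align(g, major_xy, planes, r_min = r_min)
}

#' @export
print.tiered_positions <- function(x, ...) {
  cat("<tiered_positions> ", nrow(x$positions), " nodes on ",
      length(unique(x$positions$z)), " plane(s): ",
      paste(x$plane_order, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' @rdname tiered_layout
#' @param x A `tiered_positions`.
#' @param ... Unused.
#' @method tidy tiered_positions
#' @export
tidy.tiered_positions <- function(x, ...) x$positions

#' @rdname tiered_layout
#' @method glance tiered_positions
#' @export
glance.tiered_positions <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$positions),
                 n_planes = length(unique(x$positions$z)),
                 plane_order = paste(x$plane_order, collapse = ","))
}

#' Plot a tiered layout (top-down projection, one color per plane)
#'
#' @param object A `tiered_positions`.
#' @param graph Optional `pathway_graph` to draw edges.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tiered_positions
#' @export
autoplot.tiered_positions <- function(object, graph = NULL, ...) {
  pos <- object$positions
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y))
  if (!is.null(graph)) {
    seg <- graph$edges |>
      dplyr::inner_join(pos[, c("id", "x", "y")], by = c(source = "id")) |>
      dplyr::inner_join(pos[, c("id", "x", "y")], by = c(target = "id"),
                        suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend),
      color = "grey60", linewidth = 0.3)
  }
  p + ggplot2::geom_point(ggplot2::aes(color = .data$plane), size = 2) +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}
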