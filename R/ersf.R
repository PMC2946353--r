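# Enhanced Radial Space-Filling (ERSF) geometry.
#
# The spanning tree is drawn as a sunburst: one annular region per term, leaf
# regions on the rim, the root at the center, one ring ("layer") per tree
# depth.  Every region carries five visual variables: sweep angle, layer,
# radius, extrusion height and color.  Non-tree edges are drawn in a third
# dimension as satellite orbits (one circle per multi-parent term, on that
# term's layer) linked to each minor parent by a single radial downlink ray;
# ray/orbit intersections are the access points.

#' Assign angular extents to spanning-tree regions
#'
#' A leaf's sweep is proportional to its weight (`360 * w / sum(w)`; equal
#' weights by default, so every pathway spans the same angle) and a non-leaf's
#' sweep is exactly the sum of its children's sweeps.  Siblings are laid out
#' contiguously in lexicographic id order starting at the parent's start
#' angle; the root spans `[0, 360)`.
#'
#' @param tree A `spanning_tree`.
#' @param leaf_weights Optional named numeric vector of positive weights,
#'   one per leaf id; unnamed leaves default to 1.
#' @return Tibble with `node`, `start_angle`, `sweep_angle` (degrees).
#' @export
assign_angles <- function(tree, leaf_weights = NULL) {
  nd <- tree$nodes
  # rim nodes are the spanning-tree leaves: nodes with no tree children
  # (a minor-parent-only category keeps a visible region of its own)
  tree_leaf <- !(nd$node %in% nd$major_parent)
  w <- stats::setNames(rep(1, sum(tree_leaf)), nd$node[tree_leaf])
  if (!is.null(leaf_weights)) {
    if (is.null(names(leaf_weights))) {
      stop("leaf_weights must be a named vector", call. = FALSE)
    }
    unknown <- setdiff(names(leaf_weights), names(w))
    if (length(unknown) > 0) {
      stop("weights given for non-leaf id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(leaf_weights <= 0)) stop("leaf weights must be > 0", call. = FALSE)
    w[names(leaf_weights)] <- leaf_weights
  }
  children <- tree_children(tree)
  sweep <- stats::setNames(rep(NA_real_, nrow(nd)), nd$node)
  sweep[names(w)] <- 360 * w / sum(w)
  # bottom-up: process nodes by decreasing depth
  for (id in nd$node[order(-nd$depth)]) {
    kids <- children[[id]]
    if (length(kids) > 0) sweep[id] <- sum(sweep[kids])
  }
  start <- stats::setNames(rep(NA_real_, nrow(nd)), nd$node)
  start[tree$root] <- 0
  for (id in nd$node[order(nd$depth)]) {
    kids <- children[[id]]
    if (length(kids) > 0) {
      start[kids] <- start[id] + cumsum(c(0, sweep[kids][-length(kids)]))
    }
  }
  tibble::tibble(node = nd$node,
                 start_angle = unname(start[nd$node]) %% 360,
                 sweep_angle = unname(sweep[nd$node]))
}

#' Assign ring radii by layer
#'
#' Layer `k` (tree depth `k`) occupies the annulus `[k * w, (k + 1) * w]`
#' with constant ring width `w`; the root occupies the central disc.
#'
#' @param tree A `spanning_tree`.
#' @param ring_width Ring width in layout units (> 0).
#' @return Tibble with `node`, `layer`, `inner_radius`, `outer_radius`.
#' @export
assign_radii <- function(tree, ring_width = 10) {
  stopifnot(ring_width > 0)
  tibble::tibble(node = tree$nodes$node,
                 layer = tree$nodes$depth,
                 inner_radius = tree$nodes$depth * ring_width,
                 outer_radius = (tree$nodes$depth + 1) * ring_width)
}

#' Structure-based region colors
#'
#' Leaves take their hue from their angular midpoint on the HSV color wheel
#' (full saturation and value); each non-leaf is the sweep-weighted mean of
#' its children's colors, computed bottom-up in linear RGB.  This conveys the
#' hierarchy: a category inherits a blend of its pathways' hues.
#'
#' @param tree A `spanning_tree`.
#' @param angles Output of [assign_angles()].
#' @return Tibble with `node`, `r`, `g`, `b`, `a` in `[0, 1]`.
#' @export
structure_colors <- function(tree, angles) {
  nd <- tree$nodes
  ang <- stats::setNames(split(angles[, c("start_angle", "sweep_angle")],
                               seq_len(nrow(angles))), angles$node)
  sweep <- stats::setNames(angles$sweep_angle, angles$node)
  mid <- stats::setNames((angles$start_angle + angles$sweep_angle / 2) %% 360,
                         angles$node)
  col <- matrix(NA_real_, nrow = nrow(nd), ncol = 3,
                dimnames = list(nd$node, c("r", "g", "b")))
  leaves <- nd$node[!(nd$node %in% nd$major_parent)]
  col[leaves, ] <- t(grDevices::col2rgb(grDevices::hsv(mid[leaves] / 360, 1, 1))) / 255
  children <- tree_children(tree)
  for (id in nd$node[order(-nd$depth)]) {
    kids <- children[[id]]
    if (length(kids) > 0) {
      wts <- sweep[kids] / sum(sweep[kids])
      col[id, ] <- as.numeric(wts %*% col[kids, , drop = FALSE])
    }
  }
  tibble::tibble(node = nd$node, r = col[, "r"], g = col[, "g"], b = col[, "b"],
                 a = 1)
}

#' Extrusion heights proportional to subtree height
#'
#' `height(node) = H0 * (1 + longest tree path from node to a descendant
#' leaf)`, so leaves get `H0` (not zero — they must remain visible) and the
#' root is tallest.
#'
#' @param tree A `spanning_tree`.
#' @param H0 Height unit in layout units (> 0).
#' @return Tibble with `node`, `height`.
#' @export
subtree_heights <- function(tree, H0 = 5) {
  stopifnot(H0 > 0)
  nd <- tree$nodes
  children <- tree_children(tree)
  h <- stats::setNames(rep(0L, nrow(nd)), nd$node)
  for (id in nd$node[order(-nd$depth)]) {
    kids <- children[[id]]
    if (length(kids) > 0) h[id] <- 1L + max(h[kids])
  }
  tibble::tibble(node = nd$node, height = H0 * (1 + unname(h[nd$node])))
}

#' Place satellite orbits for multi-parent terms
#'
#' One orbit circle per term with at least two parents, drawn on that term's
#' layer.  Orbits are confined to the middle band of the ring (default
#' fractions 0.3-0.7 of the ring width) so a visible gap separates orbits of
#' adjacent layers.  Within a layer, orbits sorted by `(downlink count,
#' child id)` get evenly spaced radii across the band and evenly spaced
#' altitudes above the layer's tallest region: the orbit with the most
#' downlinks is the most distant and the highest.
#'
#' @param tree A `spanning_tree`.
#' @param regions Region table with `node`, `layer`, `inner_radius`,
#'   `outer_radius`, `height` and color channels (see [ersf_layout()]).
#' @param band Length-2 fractions of the ring width bounding the orbit band.
#' @param altitude_step Vertical spacing between stacked orbits; also the
#'   clearance above the layer's tallest region.  Defaults to the layout `H0`.
#' @return Tibble with `child`, `layer`, `radius`, `altitude`,
#'   `downlink_count`, `r`, `g`, `b`, `a`; zero rows for a pure tree.
#' @export
place_orbits <- function(tree, regions, band = c(0.3, 0.7), altitude_step = 5) {
  nte <- tree$non_tree_edges
  empty <- tibble::tibble(child = character(0), layer = integer(0),
                          radius = double(0), altitude = double(0),
                          downlink_count = integer(0),
                          r = double(0), g = double(0), b = double(0),
                          a = double(0))
  if (nrow(nte) == 0) return(empty)
  stopifnot(length(band) == 2, band[1] < band[2], band[1] >= 0, band[2] <= 1)
  counts <- dplyr::count(nte, .data$child, name = "downlink_count")
  orb <- dplyr::inner_join(counts, regions, by = c(child = "node"))
  layer_top <- vapply(split(regions$height, regions$layer), max, numeric(1))
  orb <- dplyr::arrange(orb, .data$layer, .data$downlink_count, .data$child)
  out <- dplyr::group_modify(dplyr::group_by(orb, .data$layer), function(d, key) {
    k <- nrow(d)
    frac <- if (k == 1) mean(band) else seq(band[1], band[2], length.out = k)
    w <- d$outer_radius - d$inner_radius
    top <- layer_top[[as.character(key$layer)]]
    d$radius <- d$inner_radius + frac * w
    d$altitude <- top + altitude_step * seq_len(k)
    d
  })
  out <- dplyr::ungroup(out)
  tibble::as_tibble(out[, c("child", "layer", "radius", "altitude",
                            "downlink_count", "r", "g", "b", "a")])
}

#' Build downlink rays and access points for minor parents
#'
#' Each node that is a minor parent of one or more children gets exactly one
#' ray: all its downlinks share a single radial edge anchored at the angular
#' midpoint and radial center of its region, spanning from the nearest to the
#' farthest linked orbit (through the anchor).  Where the ray's angle crosses
#' a linked child's orbit circle lies that child's access point.
#'
#' @param tree A `spanning_tree`.
#' @param regions Region table (see [ersf_layout()]).
#' @param orbits Output of [place_orbits()].
#' @return List with tibbles `rays` (`parent`, `angle`, `r_anchor`, `r_from`,
#'   `r_to`, `anchor_height`) and `access_points` (`parent`, `child`,
#'   `angle`, `radius`, `altitude`, `x`, `y`).
#' @export
build_downlinks <- function(tree, regions, orbits) {
  nte <- tree$non_tree_edges
  rays <- tibble::tibble(parent = character(0), angle = double(0),
                         r_anchor = double(0), r_from = double(0),
                         r_to = double(0), anchor_height = double(0))
  aps <- tibble::tibble(parent = character(0), child = character(0),
                        angle = double(0), radius = double(0),
                        altitude = double(0), x = double(0), y = double(0))
  if (nrow(nte) == 0) return(list(rays = rays, access_points = aps))
  reg <- regions
  mid <- stats::setNames(reg$start_angle + reg$sweep_angle / 2, reg$node)
  rcen <- stats::setNames((reg$inner_radius + reg$outer_radius) / 2, reg$node)
  hgt <- stats::setNames(reg$height, reg$node)
  orad <- stats::setNames(orbits$radius, orbits$child)
  oalt <- stats::setNames(orbits$altitude, orbits$child)
  links <- split(nte$child, nte$parent)
  parents <- sort(names(links))
  rays <- purrr::map_dfr(parents, function(p) {
    radii <- orad[links[[p]]]
    tibble::tibble(parent = p, angle = mid[[p]] %% 360, r_anchor = rcen[[p]],
                   r_from = min(rcen[[p]], min(radii)),
                   r_to = max(rcen[[p]], max(radii)),
                   anchor_height = hgt[[p]])
  })
  aps <- purrr::map_dfr(parents, function(p) {
    ch <- sort(links[[p]])
    ang <- mid[[p]] %% 360
    tibble::tibble(parent = p, child = ch, angle = ang,
                   radius = unname(orad[ch]), altitude = unname(oalt[ch]),
                   x = unname(orad[ch]) * cospi(ang / 180),
                   y = unname(orad[ch]) * sinpi(ang / 180))
  })
  list(rays = rays, access_points = aps)
}

#' Compute the full ERSF layout of an ontology DAG
#'
#' Convenience pipeline: normalize the root, extract the major-parent
#' spanning tree, then assign angles, radii, structure colors, subtree
#' heights, orbits and downlink rays.
#'
#' @param g An `ontology_graph`, or a `spanning_tree` already extracted.
#' @param leaf_weights Passed to [assign_angles()].
#' @param ring_width,H0 Layout units for ring width and height unit.
#' @param orbit_band Passed to [place_orbits()] as `band`.
#' @param hide_root If `TRUE`, the root disc is dropped from the region table
#'   (the figures are readable either way; exposed as a flag).
#' @return An `ersf_layout`: list with tibbles `regions` (node, layer,
#'   angles, radii, height, color), `orbits`, `rays`, `access_points`, the
#'   `tree`, and `params`.
#' @examples
#' lay <- ersf_layout(make_g2())
#' nrow(lay$orbits)
#' @export
ersf_layout <- function(g, leaf_weights = NULL, ring_width = 10, H0 = 5,
                        orbit_band = c(0.3, 0.7), hide_root = FALSE) {
  tree <- if (inherits(g, "spanning_tree")) g else
    extract_spanning_tree(normalize_root(g))
  angles <- assign_angles(tree, leaf_weights)
  radii <- assign_radii(tree, ring_width)
  colors <- structure_colors(tree, angles)
  heights <- subtree_heights(tree, H0)
  regions <- angles |>
    dplyr::inner_join(radii, by = "node") |>
    dplyr::inner_join(heights, by = "node") |>
    dplyr::inner_join(colors, by = "node") |>
    dplyr::arrange(.data$node)
  orbits <- place_orbits(tree, regions, band = orbit_band, altitude_step = H0)
  dl <- build_downlinks(tree, regions, orbits)
  if (hide_root) regions <- regions[regions$node != tree$root, , drop = FALSE]
  structure(list(regions = regions, orbits = orbits, rays = dl$rays,
                 access_points = dl$access_points, tree = tree,
                 params = list(ring_width = ring_width, H0 = H0,
                               orbit_band = orbit_band,
                               hide_root = hide_root)),
            class = "ersf_layout")
}

#' @export
print.ersf_layout <- function(x, ...) {
  cat("<ersf_layout> ", nrow(x$regions), " regions over ",
      max(x$regions$layer) + 1, " layers, ", nrow(x$orbits), " orbit(s), ",
      nrow(x$rays), " downlink ray(s)\n", sep = "")
  invisible(x)
}

#' @rdname ersf_layout
#' @param x An `ersf_layout`.
#' @param ... Unused.
#' @method tidy ersf_layout
#' @export
tidy.ersf_layout <- function(x, ...) x$regions

#' @rdname ersf_layout
#' @method glance ersf_layout
#' @export
glance.ersf_layout <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$regions),
                 n_layers = max(x$regions$layer) + 1L,
                 n_orbits = nrow(x$orbits),
                 n_rays = nrow(x$rays),
                 n_access_points = nrow(x$access_points),
                 n_non_tree_edges = nrow(x$tree$non_tree_edges))
}

#' Plot an ERSF layout as a 2D sunburst
#'
#' Top-down projection: annular sectors in polar coordinates, orbit circles
#' dashed, downlink rays as radial segments, access points as dots.
#'
#' @param object An `ersf_layout`.
#' @param style Optional style map (see [style_by_value()]) overriding the
#'   structure colors.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ersf_layout
#' @export
autoplot.ersf_layout <- function(object, style = NULL, ...) {
  reg <- object$regions
  if (!is.null(style)) {
    st <- dplyr::select(style, "node", fr = "r", fg = "g", fb = "b", fa = "a",
                        "visible")
    reg <- dplyr::left_join(reg, st, by = "node") |>
      dplyr::mutate(
        r = dplyr::coalesce(.data$fr, .data$r),
        g = dplyr::coalesce(.data$fg, .data$g),
        b = dplyr::coalesce(.data$fb, .data$b),
        a = ifelse(!is.na(.data$visible) & !.data$visible, 0,
                   dplyr::coalesce(.data$fa, .data$a)))
  }
  reg$fill <- grDevices::rgb(reg$r, reg$g, reg$b, reg$a)
  p <- ggplot2::ggplot(reg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_angle, xmax = .data$start_angle + .data$sweep_angle,
      ymin = .data$inner_radius, ymax = .data$outer_radius,
      fill = .data$fill), color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_polar(theta = "x", direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360)) +
    ggplot2::theme_void()
  if (nrow(object$orbits) > 0) {
    p <- p + ggplot2::geom_hline(
      data = object$orbits,
      ggplot2::aes(yintercept = .data$radius), linetype = "dashed",
      color = "goldenrod")
  }
  if (nrow(object$rays) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$rays,
      ggplot2::aes(x = .data$angle, xend = .data$angle,
                   y = .data$r_from, yend = .data$r_to),
      color = "darkgreen")
  }
  if (nrow(object$access_points) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$access_points,
      ggplot2::aes(x = .data$angle, y = .data$radius),
      color = "red", size = 1.5)
  }
  p
}
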