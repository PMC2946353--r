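# Renderers: SVG (2D top-down projection of the ERSF), KML 2.2 (3D extruded
# scene for an Earth viewer, with optional TimeSpan animation frames), and a
# JSON layout dump.  All XML is built with xml2 so output is well-formed by
# construction; elements are emitted in sorted node order for byte-stable,
# diffable files.

KML_NS <- "http://www.opengis.net/kml/2.2"
SVG_NS <- "http://www.w3.org/2000/svg"

fmt <- function(x, digits = 4) {
  formatC(x, digits = digits, format = "f", drop0trailing = TRUE)
}

# hex "#rrggbb" and KML "aabbggrr" from 0-1 channels
hex_rgb <- function(r, g, b) grDevices::rgb(r, g, b)
kml_color <- function(r, g, b, a = 1) {
  ch <- function(v) sprintf("%02x", round(pmax(0, pmin(1, v)) * 255))
  paste0(ch(a), ch(b), ch(g), ch(r))
}

# polar to cartesian, y up, angle in degrees counter-clockwise from +x
pol2xy <- function(angle, radius) {
  cbind(x = radius * cospi(angle / 180), y = radius * sinpi(angle / 180))
}

# merge a style map over structure colors; returns regions with fill_*,
# height and visible resolved
resolve_style <- function(regions, style) {
  reg <- regions
  reg$fill_r <- reg$r; reg$fill_g <- reg$g; reg$fill_b <- reg$b
  reg$fill_a <- reg$a; reg$visible <- TRUE
  if (!is.null(style)) {
    i <- match(reg$node, style$node)
    hit <- !is.na(i)
    reg$fill_r[hit] <- style$r[i[hit]]
    reg$fill_g[hit] <- style$g[i[hit]]
    reg$fill_b[hit] <- style$b[i[hit]]
    reg$fill_a[hit] <- style$a[i[hit]]
    reg$visible[hit] <- style$visible[i[hit]]
    sh <- style$height[i[hit]]
    reg$height[hit] <- ifelse(is.na(sh), reg$height[hit], sh)
  }
  reg
}

# annular-sector (or disc/ring) path "d" attribute
sector_path_d <- function(start, sweep, r0, r1, cx, cy, px) {
  a0 <- start; a1 <- start + sweep
  pt <- function(a, r) {
    xy <- pol2xy(a, r)
    c(cx + xy[1] * px, cy - xy[2] * px)  # SVG y axis points down
  }
  if (sweep >= 360 - 1e-9) {
    circ <- function(r) {
      p1 <- pt(0, r); p2 <- pt(180, r)
      sprintf("M %s %s A %s %s 0 1 0 %s %s A %s %s 0 1 0 %s %s Z",
              fmt(p1[1]), fmt(p1[2]), fmt(r * px), fmt(r * px),
              fmt(p2[1]), fmt(p2[2]), fmt(r * px), fmt(r * px),
              fmt(p1[1]), fmt(p1[2]))
    }
    return(if (r0 <= 1e-12) circ(r1) else paste(circ(r1), circ(r0)))
  }
  large <- as.integer(sweep > 180)
  o0 <- pt(a0, r1); o1 <- pt(a1, r1)
  if (r0 <= 1e-12) {
    sprintf("M %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
            fmt(cx), fmt(cy), fmt(o0[1]), fmt(o0[2]),
            fmt(r1 * px), fmt(r1 * px), large, fmt(o1[1]), fmt(o1[2]))
  } else {
    i0 <- pt(a0, r0); i1 <- pt(a1, r0)
    sprintf("M %s %s A %s %s 0 %d 0 %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
            fmt(o0[1]), fmt(o0[2]), fmt(r1 * px), fmt(r1 * px), large,
            fmt(o1[1]), fmt(o1[2]), fmt(i1[1]), fmt(i1[2]),
            fmt(r0 * px), fmt(r0 * px), large, fmt(i0[1]), fmt(i0[2]))
  }
}

#' Render an ERSF layout to SVG
#'
#' Top-down 2D projection: one annular-sector `<path>` per region (two arcs
#' plus two radial lines), dashed `<circle>` per orbit, a `<line>` per
#' downlink ray and a small disc per access point.  Elements are sorted by
#' node id so identical layouts produce identical files.
#'
#' @param layout An `ersf_layout`.
#' @param path Output file path.
#' @param style Optional style map (e.g. [style_by_value()],
#'   [style_differential_view()]); when `NULL` the structure-based colors
#'   are used.
#' @param size Image side length in pixels.
#' @return `path`, invisibly.
#' @export
ersf_to_svg <- function(layout, path, style = NULL, size = 800) {
  reg <- resolve_style(layout$regions, style)
  reg <- reg[order(reg$node), , drop = FALSE]
  rmax <- max(reg$outer_radius, layout$orbits$radius, 0)
  px <- (size / 2 - 10) / rmax
  cx <- size / 2; cy <- size / 2
  doc <- xml2::xml_new_root(
    "svg", xmlns = SVG_NS, version = "1.1",
    width = as.character(size), height = as.character(size),
    viewBox = paste(0, 0, size, size))
  gr <- xml2::xml_add_child(doc, "g", id = "regions")
  for (i in seq_len(nrow(reg))) {
    xml2::xml_add_child(
      gr, "path",
      d = sector_path_d(reg$start_angle[i], reg$sweep_angle[i],
                        reg$inner_radius[i], reg$outer_radius[i], cx, cy, px),
      fill = hex_rgb(reg$fill_r[i], reg$fill_g[i], reg$fill_b[i]),
      `fill-opacity` = fmt(ifelse(reg$visible[i], reg$fill_a[i], 0)),
      `fill-rule` = "evenodd",
      stroke = "#444444", `stroke-width` = "0.5",
      id = paste0("region-", reg$node[i]))
  }
  orb <- layout$orbits[order(layout$orbits$child), , drop = FALSE]
  go <- xml2::xml_add_child(doc, "g", id = "orbits")
  for (i in seq_len(nrow(orb))) {
    xml2::xml_add_child(
      go, "circle", cx = fmt(cx), cy = fmt(cy), r = fmt(orb$radius[i] * px),
      fill = "none", stroke = hex_rgb(orb$r[i], orb$g[i], orb$b[i]),
      `stroke-width` = "1.5", `stroke-dasharray` = "6 3",
      id = paste0("orbit-", orb$child[i]))
  }
  rays <- layout$rays[order(layout$rays$parent), , drop = FALSE]
  gl <- xml2::xml_add_child(doc, "g", id = "downlinks")
  for (i in seq_len(nrow(rays))) {
    p0 <- pol2xy(rays$angle[i], rays$r_from[i])
    p1 <- pol2xy(rays$angle[i], rays$r_to[i])
    xml2::xml_add_child(
      gl, "line",
      x1 = fmt(cx + p0[1] * px), y1 = fmt(cy - p0[2] * px),
      x2 = fmt(cx + p1[1] * px), y2 = fmt(cy - p1[2] * px),
      stroke = "#1a7a1a", `stroke-width` = "1.5",
      id = paste0("ray-", rays$parent[i]))
  }
  aps <- layout$access_points
  aps <- aps[order(aps$parent, aps$child), , drop = FALSE]
  ga <- xml2::xml_add_child(doc, "g", id = "access-points")
  for (i in seq_len(nrow(aps))) {
    xml2::xml_add_child(
      ga, "circle",
      cx = fmt(cx + aps$x[i] * px), cy = fmt(cy - aps$y[i] * px),
      r = "3", fill = "#cc0000",
      id = paste0("ap-", aps$parent[i], "-", aps$child[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# local equirectangular projection: layout units -> lon/lat about the anchor
project_lonlat <- function(x, y, anchor, scale) {
  lat0 <- anchor[1]; lon0 <- anchor[2]
  if (abs(lat0) >= 85) {
    stop("anchor latitude must satisfy |lat| < 85 degrees", call. = FALSE)
  }
  m_per_deg <- 111320
  cbind(lon = lon0 + x * scale / (m_per_deg * cos(lat0 * pi / 180)),
        lat = lat0 + y * scale / m_per_deg)
}

coord_string <- function(x, y, alt, anchor, scale) {
  ll <- project_lonlat(x, y, anchor, scale)
  paste(sprintf("%.8f,%.8f,%.2f", ll[, "lon"], ll[, "lat"], alt),
        collapse = " ")
}

kml_placemark_polygon <- function(parent, name, ring_xy, altitude, color,
                                  anchor, scale, extrude = TRUE) {
  pm <- xml2::xml_add_child(parent, "Placemark")
  xml2::xml_add_child(pm, "name", name)
  st <- xml2::xml_add_child(pm, "Style")
  ps <- xml2::xml_add_child(st, "PolyStyle")
  xml2::xml_add_child(ps, "color", color)
  poly <- xml2::xml_add_child(pm, "Polygon")
  xml2::xml_add_child(poly, "extrude", if (extrude) "1" else "0")
  xml2::xml_add_child(poly, "altitudeMode", "relativeToGround")
  ob <- xml2::xml_add_child(poly, "outerBoundaryIs")
  lr <- xml2::xml_add_child(ob, "LinearRing")
  xml2::xml_add_child(lr, "coordinates",
                      coord_string(ring_xy[, 1], ring_xy[, 2], altitude,
                                   anchor, scale))
  pm
}

# closed tessellated ring of an annular sector (outer arc, inner arc back)
sector_ring <- function(start, sweep, r0, r1, arc_step) {
  n <- max(2L, ceiling(sweep / arc_step) + 1L)
  ang <- seq(start, start + sweep, length.out = n)
  outer <- pol2xy(ang, r1)
  inner <- if (r0 <= 1e-12) cbind(x = 0, y = 0) else pol2xy(rev(ang), r0)
  ring <- rbind(outer, inner)
  rbind(ring, ring[1, , drop = FALSE])
}

circle_ring <- function(radius, arc_step) {
  ang <- seq(0, 360, by = arc_step)
  if (ang[length(ang)] != 360) ang <- c(ang, 360)
  pol2xy(ang, radius)
}

frame_timespan <- function(folder, index) {
  # synthetic daily timeline: frame i spans day i of 2000-01
  begin <- as.Date("2000-01-01") + (index - 1)
  ts <- xml2::xml_add_child(folder, "TimeSpan")
  xml2::xml_add_child(ts, "begin", format(begin, "%Y-%m-%d"))
  xml2::xml_add_child(ts, "end", format(begin + 1, "%Y-%m-%d"))
  ts
}

add_ersf_frame <- function(parent, layout, style, anchor, scale, arc_step) {
  reg <- resolve_style(layout$regions, style)
  reg <- reg[order(reg$node), , drop = FALSE]
  freg <- xml2::xml_add_child(parent, "Folder")
  xml2::xml_add_child(freg, "name", "regions")
  for (i in seq_len(nrow(reg))) {
    ring <- sector_ring(reg$start_angle[i], reg$sweep_angle[i],
                        reg$inner_radius[i], reg$outer_radius[i], arc_step)
    a <- if (reg$visible[i]) reg$fill_a[i] else 0
    kml_placemark_polygon(freg, reg$node[i], ring, reg$height[i],
                          kml_color(reg$fill_r[i], reg$fill_g[i],
                                    reg$fill_b[i], a),
                          anchor, scale)
  }
  orb <- layout$orbits[order(layout$orbits$child), , drop = FALSE]
  forb <- xml2::xml_add_child(parent, "Folder")
  xml2::xml_add_child(forb, "name", "orbits")
  for (i in seq_len(nrow(orb))) {
    pm <- xml2::xml_add_child(forb, "Placemark")
    xml2::xml_add_child(pm, "name", paste0("orbit:", orb$child[i]))
    st <- xml2::xml_add_child(pm, "Style")
    ls <- xml2::xml_add_child(st, "LineStyle")
    xml2::xml_add_child(ls, "color",
                        kml_color(orb$r[i], orb$g[i], orb$b[i], 1))
    xml2::xml_add_child(ls, "width", "2")
    lstr <- xml2::xml_add_child(pm, "LineString")
    xml2::xml_add_child(lstr, "altitudeMode", "relativeToGround")
    ring <- circle_ring(orb$radius[i], arc_step)
    xml2::xml_add_child(lstr, "coordinates",
                        coord_string(ring[, 1], ring[, 2], orb$altitude[i],
                                     anchor, scale))
  }
  rays <- layout$rays[order(layout$rays$parent), , drop = FALSE]
  aps <- layout$access_points
  fray <- xml2::xml_add_child(parent, "Folder")
  xml2::xml_add_child(fray, "name", "downlinks")
  for (i in seq_len(nrow(rays))) {
    p <- rays$parent[i]
    pa <- aps[aps$parent == p, , drop = FALSE]
    pa <- pa[order(pa$radius), , drop = FALSE]
    anchor_xy <- pol2xy(rays$angle[i], rays$r_anchor[i])
    pts_x <- c(anchor_xy[1], pa$x)
    pts_y <- c(anchor_xy[2], pa$y)
    alts <- c(rays$anchor_height[i], pa$altitude)
    pm <- xml2::xml_add_child(fray, "Placemark")
    xml2::xml_add_child(pm, "name", paste0("downlink:", p))
    st <- xml2::xml_add_child(pm, "Style")
    ls <- xml2::xml_add_child(st, "LineStyle")
    xml2::xml_add_child(ls, "color", kml_color(0.1, 0.6, 0.1, 1))
    xml2::xml_add_child(ls, "width", "2")
    lstr <- xml2::xml_add_child(pm, "LineString")
    xml2::xml_add_child(lstr, "altitudeMode", "relativeToGround")
    coords <- paste(vapply(seq_along(pts_x), function(j) {
      coord_string(pts_x[j], pts_y[j], alts[j], anchor, scale)
    }, ""), collapse = " ")
    xml2::xml_add_child(lstr, "coordinates", coords)
  }
  fap <- xml2::xml_add_child(parent, "Folder")
  xml2::xml_add_child(fap, "name", "access-points")
  aps <- aps[order(aps$parent, aps$child), , drop = FALSE]
  for (i in seq_len(nrow(aps))) {
    pm <- xml2::xml_add_child(fap, "Placemark")
    xml2::xml_add_child(pm, "name",
                        paste0("access:", aps$parent[i], ">", aps$child[i]))
    pt <- xml2::xml_add_child(pm, "Point")
    xml2::xml_add_child(pt, "altitudeMode", "relativeToGround")
    xml2::xml_add_child(pt, "coordinates",
                        coord_string(aps$x[i], aps$y[i], aps$altitude[i],
                                     anchor, scale))
  }
  invisible(parent)
}

#' Render an ERSF layout to KML 2.2
#'
#' Regions become extruded Polygons (altitude = region height, relative to
#' ground), orbits become LineString rings at their altitude, and each
#' downlink becomes a LineString from the minor parent's region center
#' through its access points.  Layout coordinates are mapped to lon/lat by a
#' local equirectangular projection about `anchor`.  With more than one
#' style frame, each frame is wrapped in a `<Folder>` carrying a `TimeSpan`
#' (a synthetic daily timeline) so an Earth viewer animates the sequence.
#'
#' @param layout An `ersf_layout`.
#' @param path Output file path.
#' @param style A single style map, or `NULL` for structure colors.
#' @param frames Named list of style maps (e.g.
#'   [build_animation_frames()]); overrides `style`.
#' @param anchor `(lat, lon)` of the layout origin; `|lat|` must be < 85.
#' @param scale Meters per layout unit.
#' @param arc_step Arc tessellation step, degrees.
#' @return `path`, invisibly.
#' @export
ersf_to_kml <- function(layout, path, style = NULL, frames = NULL,
                        anchor = c(0, 0), scale = 10, arc_step = 4) {
  if (abs(anchor[1]) >= 85) {
    stop("anchor latitude must satisfy |lat| < 85 degrees", call. = FALSE)
  }
  doc <- xml2::xml_new_root("kml", xmlns = KML_NS)
  dc <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(dc, "name", "ERSF ontology layout")
  if (is.null(frames)) {
    frames <- list(style)
    names(frames) <- "layout"
    timed <- FALSE
  } else {
    if (length(frames) < 1) stop("frames must be non-empty", call. = FALSE)
    timed <- length(frames) > 1
  }
  for (i in seq_along(frames)) {
    fold <- xml2::xml_add_child(dc, "Folder")
    xml2::xml_add_child(fold, "name", names(frames)[i])
    if (timed) frame_timespan(fold, i)
    add_ersf_frame(fold, layout, frames[[i]], anchor, scale, arc_step)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Render a tiered pathway layout to KML 2.2
#'
#' One sub-Folder per plane holding its nodes as Point placemarks (altitudes
#' shifted so the lowest plane sits on the ground), then one LineString
#' placemark per edge connecting endpoints in 3D.
#'
#' @param positions A `tiered_positions`.
#' @param g The `pathway_graph` the positions were computed from.
#' @param path Output file path.
#' @param anchor,scale See [ersf_to_kml()].
#' @return `path`, invisibly.
#' @export
tiered_to_kml <- function(positions, g, path, anchor = c(0, 0), scale = 10) {
  pos <- positions$positions
  if (nrow(pos) == 0) stop("empty pathway graph", call. = FALSE)
  if (abs(anchor[1]) >= 85) {
    stop("anchor latitude must satisfy |lat| < 85 degrees", call. = FALSE)
  }
  alt0 <- -min(pos$z)
  doc <- xml2::xml_new_root("kml", xmlns = KML_NS)
  dc <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(dc, "name", "Aligned tiered pathway layout")
  for (pl in positions$plane_order) {
    sub <- pos[pos$plane == pl, , drop = FALSE]
    if (nrow(sub) == 0) next
    fold <- xml2::xml_add_child(dc, "Folder")
    xml2::xml_add_child(fold, "name", pl)
    for (i in order(sub$id)) {
      pm <- xml2::xml_add_child(fold, "Placemark")
      xml2::xml_add_child(pm, "name", sub$label[i])
      pt <- xml2::xml_add_child(pm, "Point")
      xml2::xml_add_child(pt, "extrude", "1")
      xml2::xml_add_child(pt, "altitudeMode", "relativeToGround")
      xml2::xml_add_child(pt, "coordinates",
                          coord_string(sub$x[i], sub$y[i], sub$z[i] + alt0,
                                       anchor, scale))
    }
  }
  ed <- g$edges[order(g$edges$source, g$edges$target), , drop = FALSE]
  idx <- match(ed$source, pos$id); jdx <- match(ed$target, pos$id)
  for (i in seq_len(nrow(ed))) {
    pm <- xml2::xml_add_child(dc, "Placemark")
    xml2::xml_add_child(pm, "name",
                        paste0(ed$source[i], ">", ed$target[i],
                               " [", ed$interaction[i], "]"))
    lstr <- xml2::xml_add_child(pm, "LineString")
    xml2::xml_add_child(lstr, "altitudeMode", "relativeToGround")
    co <- paste(
      coord_string(pos$x[idx[i]], pos$y[idx[i]], pos$z[idx[i]] + alt0,
                   anchor, scale),
      coord_string(pos$x[jdx[i]], pos$y[jdx[i]], pos$z[jdx[i]] + alt0,
                   anchor, scale))
    xml2::xml_add_child(lstr, "coordinates", co)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Dump an ERSF layout as JSON
#'
#' Stable schema: top-level keys `params`, `regions`, `orbits`, `rays`,
#' `access_points`, tables as row-wise record arrays sorted by id.
#'
#' @param layout An `ersf_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  obj <- list(
    params = layout$params,
    regions = dplyr::arrange(layout$regions, .data$node),
    orbits = dplyr::arrange(layout$orbits, .data$child),
    rays = dplyr::arrange(layout$rays, .data$parent),
    access_points = dplyr::arrange(layout$access_points, .data$parent,
                                   .data$child))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
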