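# Land-use polygon layers: legend harmonisation and point-in-polygon
# annotation of GPS fixes.

LANDUSE_UNITS <- c("homefields", "bushfields", "rangelands", "lowlands",
                   "fallows", "other", "unclassified")

#' Construct a land-use layer
#'
#' @param polygons list of polygons, each a list with `id` (unique within
#'   the layer), `label` (raw legend label) and `coords` (two-column
#'   lon/lat matrix of the outer ring; closure optional).
#' @param legend named character vector mapping every raw label to a
#'   harmonised unit (one of `r paste(LANDUSE_UNITS, collapse=", ")`).
#' @param priority integer; where layer extents overlap the
#'   highest-priority layer wins (fine map over coarse map).
#' @param resolution_tag free-text provenance tag (e.g. source resolution).
#' @return object of class `landuse_map`.
#' @export
landuse_map <- function(polygons, legend, priority = 1L,
                        resolution_tag = "") {
  ids <- vapply(polygons, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) stop("polygon ids must be unique within a layer")
  for (p in polygons) {
    m <- as.matrix(p$coords)
    if (ncol(m) != 2 || nrow(m) < 3 || any(!is.finite(m)))
      stop("invalid geometry in polygon ", p$id)
  }
  labels <- vapply(polygons, function(p) as.character(p$label), character(1))
  harmonize_legend(labels, legend) # errors on unmapped labels
  structure(list(polygons = polygons, legend = legend,
                 priority = as.integer(priority),
                 resolution_tag = resolution_tag),
            class = "landuse_map")
}

#' Harmonise raw legend labels to unified land-use units
#'
#' @param labels character vector of raw labels.
#' @param mapping named character vector: raw label -> unified unit. Must
#'   cover every observed label; unknown labels raise an error naming the
#'   offenders. Several raw labels may map to the same unit (e.g. distinct
#'   cropland classes both to `bushfields`).
#' @return character vector of unified units.
#' @export
harmonize_legend <- function(labels, mapping) {
  unknown <- setdiff(unique(labels), names(mapping))
  if (length(unknown))
    stop("unmapped land-use label(s): ", paste(unknown, collapse = ", "))
  bad_units <- setdiff(unique(unname(mapping)), LANDUSE_UNITS)
  if (length(bad_units))
    stop("legend maps to unknown unit(s): ",
         paste(bad_units, collapse = ", "))
  unname(mapping[labels])
}

# closed ring for the point-in-polygon test
close_ring <- function(coords) {
  m <- as.matrix(coords)
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

# TRUE if (px, py) lies on an edge of the ring, within tolerance
on_boundary <- function(px, py, ring, tol = 1e-12) {
  n <- nrow(ring) - 1
  for (k in seq_len(n)) {
    ax <- ring[k, 1]; ay <- ring[k, 2]
    bx <- ring[k + 1, 1]; by <- ring[k + 1, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) > tol) next
    if (px >= min(ax, bx) - tol && px <= max(ax, bx) + tol &&
        py >= min(ay, by) - tol && py <= max(ay, by) + tol)
      return(TRUE)
  }
  FALSE
}

# containment with a closed boundary rule: interior or on an edge
point_in_polygon <- function(px, py, coords) {
  ring <- close_ring(coords)
  if (on_boundary(px, py, ring)) return(TRUE)
  mgcv::in.out(ring, matrix(c(px, py), 1, 2))[1]
}

layer_bbox <- function(map) {
  all <- do.call(rbind, lapply(map$polygons, function(p) as.matrix(p$coords)))
  c(xmin = min(all[, 1]), ymin = min(all[, 2]),
    xmax = max(all[, 1]), ymax = max(all[, 2]))
}

#' Annotate fixes with land-use units
#'
#' Point-in-polygon join against one or more layers. Layers are tried in
#' decreasing priority; within a layer, polygons are tried in ascending id
#' order so that among same-priority overlaps the lowest polygon id wins.
#' Containment uses a closed-boundary rule (edge points count as inside),
#' making boundary fixes deterministic across runs. Fixes inside no polygon
#' of any layer get unit `unclassified`. Coordinates are WGS84 throughout;
#' containment is tested in geographic coordinates (the polygons are small
#' enough that geodesic effects are below GPS noise).
#'
#' @param fixes data.frame with `lon`, `lat`.
#' @param maps a `landuse_map` or list of them.
#' @return `fixes` with columns `unit` and `source_layer` appended.
#' @export
join_fixes <- function(fixes, maps) {
  if (inherits(maps, "landuse_map")) maps <- list(maps)
  if (!length(maps)) stop("maps must be non-empty")
  ord <- order(vapply(maps, `[[`, integer(1), "priority"),
               decreasing = TRUE)
  maps <- maps[ord]
  layers <- lapply(maps, function(m) {
    polys <- m$polygons[order(vapply(m$polygons,
                                     function(p) as.character(p$id),
                                     character(1)))]
    list(bbox = layer_bbox(m),
         rings = lapply(polys, function(p) close_ring(p$coords)),
         units = harmonize_legend(
           vapply(polys, function(p) as.character(p$label), character(1)),
           m$legend),
         tag = m$resolution_tag)
  })
  unit <- rep("unclassified", nrow(fixes))
  src <- rep(NA_character_, nrow(fixes))
  for (i in seq_len(nrow(fixes))) {
    px <- fixes$lon[i]; py <- fixes$lat[i]
    for (ly in layers) {
      bb <- ly$bbox
      if (px < bb["xmin"] || px > bb["xmax"] ||
          py < bb["ymin"] || py > bb["ymax"]) next
      hit <- 0L
      for (k in seq_along(ly$rings)) {
        r <- ly$rings[[k]]
        if (px < min(r[, 1]) || px > max(r[, 1]) ||
            py < min(r[, 2]) || py > max(r[, 2])) next
        if (on_boundary(px, py, r) ||
            mgcv::in.out(r, matrix(c(px, py), 1, 2))[1]) { hit <- k; break }
      }
      if (hit) { unit[i] <- ly$units[hit]; src[i] <- ly$tag; break }
    }
  }
  fixes$unit <- unit
  fixes$source_layer <- src
  fixes
}

#' Write a land-use layer as GeoJSON
#'
#' One Feature per polygon with properties `id` and `label`; the legend,
#' priority and resolution tag ride in top-level `properties`.
#'
#' @param map a `landuse_map`.
#' @param path output path.
#' @export
write_landuse_geojson <- function(map, path) {
  feats <- lapply(map$polygons, function(p) {
    ring <- close_ring(p$coords)
    list(type = "Feature",
         properties = list(id = p$id, label = p$label),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  doc <- list(type = "FeatureCollection",
              properties = list(legend = as.list(map$legend),
                                priority = map$priority,
                                resolution_tag = map$resolution_tag),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a land-use layer from GeoJSON
#'
#' Reads FeatureCollections of Polygon features with a `label` property
#' (outer ring only). The legend may be embedded (as written by
#' [write_landuse_geojson()]) or supplied.
#'
#' @param path GeoJSON path.
#' @param legend named character vector (overrides any embedded legend).
#' @param priority,resolution_tag overrides for the layer metadata.
#' @return a `landuse_map`.
#' @export
read_landuse_geojson <- function(path, legend = NULL, priority = NULL,
                                 resolution_tag = NULL) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  polys <- lapply(seq_along(doc$features), function(k) {
    f <- doc$features[[k]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature ", k, ": only Polygon geometries are supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) as.numeric(unlist(pt))))
    list(id = f$properties$id %||% k, label = f$properties$label,
         coords = ring)
  })
  emb <- doc$properties
  legend <- legend %||% unlist(emb$legend)
  if (is.null(legend)) stop("no legend embedded in file and none supplied")
  landuse_map(polys, legend,
              priority = priority %||% emb$priority %||% 1L,
              resolution_tag = resolution_tag %||% emb$resolution_tag %||% "")
}

#' Read a legend mapping from YAML
#'
#' A flat mapping `raw label: unit`.
#' @param path YAML file.
#' @return named character vector.
#' @export
read_legend_yaml <- function(path) {
  unlist(yaml::read_yaml(path))
}
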