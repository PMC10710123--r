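# Planar geometry in lon/lat degrees: ring areas, rectangle clipping, and
# GeoJSON (FeatureCollection of Polygon/MultiPolygon) read/write. Areas are
# in square degrees and documented as such; no equal-area reprojection.

# Signed shoelace area of a ring (matrix with columns x, y; open or closed).
#' @keywords internal
#' @noRd
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

# Sutherland-Hodgman clip of an arbitrary ring by an axis-aligned rectangle.
#' @keywords internal
#' @noRd
clip_ring_rect <- function(ring, rect) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  pts <- cbind(x, y)
  clip_edge <- function(pts, inside, intersect) {
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) out <- rbind(out, intersect(prev, cur))
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- clip_edge(pts, function(p) p[1] >= rect[1],
                   function(p, q) ix(p, q, rect[1], 1))
  pts <- clip_edge(pts, function(p) p[1] <= rect[3],
                   function(p, q) ix(p, q, rect[3], 1))
  pts <- clip_edge(pts, function(p) p[2] >= rect[2],
                   function(p, q) ix(p, q, rect[2], 2))
  pts <- clip_edge(pts, function(p) p[2] <= rect[4],
                   function(p, q) ix(p, q, rect[4], 2))
  pts
}

# Area of intersection between a polygon (list of rings, first = outer,
# rest = holes) and the rectangle c(lon0, lat0, lon1, lat1).
#' @keywords internal
#' @noRd
polygon_rect_area <- function(rings, rect) {
  a <- abs(ring_area(clip_ring_rect(rings[[1]], rect)))
  if (length(rings) > 1)
    for (h in rings[-1]) a <- a - abs(ring_area(clip_ring_rect(h, rect)))
  max(a, 0)
}

# Even-odd ray-casting point-in-ring test.
#' @keywords internal
#' @noRd
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Total polygon area (outer minus holes), square degrees.
#' @keywords internal
#' @noRd
polygon_area <- function(rings) {
  a <- abs(ring_area(rings[[1]]))
  if (length(rings) > 1) for (h in rings[-1]) a <- a - abs(ring_area(h))
  max(a, 0)
}

#' Read protected-area polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features in plain
#' lon/lat (WGS84). Each feature becomes one named protected area; the name
#' is taken from a `name` property, else `PA<i>`.
#'
#' @param path GeoJSON file.
#' @return a `pa_polygons`: named list; each element is a list of "parts",
#'   each part a list of rings (matrices with columns lon, lat; first ring
#'   outer, others holes).
#' @export
read_pa_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  ring_mat <- function(r)
    do.call(rbind, lapply(r, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  feats <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    geom <- f$geometry
    nm <- if (!is.null(f$properties$name)) f$properties$name else paste0("PA", i)
    parts <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(pp) lapply(pp, ring_mat)),
      stop("feature '", nm, "': unsupported geometry type ", geom$type))
    for (p in parts) for (r in p)
      if (nrow(r) < 4) stop("feature '", nm, "': ring with < 4 coordinates")
    structure(parts, name = nm)
  })
  names(feats) <- vapply(feats, attr, "", "name")
  structure(feats, class = "pa_polygons")
}

#' Write protected-area polygons as GeoJSON
#'
#' @param pa a `pa_polygons` object (see [read_pa_geojson()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pa_geojson <- function(pa, path) {
  feat <- lapply(names(pa), function(nm) {
    parts <- pa[[nm]]
    coords <- lapply(parts, function(p) lapply(p, function(r) {
      if (!(r[1, 1] == r[nrow(r), 1] && r[1, 2] == r[nrow(r), 2]))
        r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    }))
    geom <- if (length(parts) == 1)
      list(type = "Polygon", coordinates = coords[[1]])
    else list(type = "MultiPolygon", coordinates = coords)
    list(type = "Feature", properties = list(name = nm), geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
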