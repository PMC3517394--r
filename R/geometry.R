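# Planar geometry primitives for block polygons.
#
# Blocks live in a projected planar coordinate system (map units). A block
# geometry is normalized to a list of parts; each part is a list of rings;
# each ring is an n x 2 coordinate matrix *without* a repeated closing
# vertex. Ring containment uses the even-odd rule, so hole ordering is
# irrelevant.

# normalize a ring: numeric n x 2 matrix, drop repeated closing vertex
normalize_ring <- function(ring, block_id = "?") {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L) {
    stop("block ", block_id, ": ring must be an n x 2 numeric matrix")
  }
  if (nrow(ring) >= 2L && all(ring[1L, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (anyNA(ring)) stop("block ", block_id, ": ring contains missing coordinates")
  if (nrow(ring) < 3L) stop("block ", block_id, ": ring has fewer than 3 vertices")
  ring
}

# shoelace signed area of one ring
ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# segments of a ring as an m x 4 matrix (x1, y1, x2, y2)
ring_segments <- function(ring) {
  n <- nrow(ring)
  cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
}

# orientation of triplet, with tolerance for collinearity
orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (by - ay) * (cx - bx) - (bx - ax) * (cy - by)
  sign(v)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px <= pmax(ax, bx) & px >= pmin(ax, bx) & py <= pmax(ay, by) & py >= pmin(ay, by)
}

# vectorized proper/improper intersection test for segment pairs
segments_intersect <- function(a, b) {
  o1 <- orient(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 1L], b[, 2L])
  o2 <- orient(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 3L], b[, 4L])
  o3 <- orient(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 1L], a[, 2L])
  o4 <- orient(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 3L], a[, 4L])
  res <- (o1 != o2) & (o3 != o4)
  res <- res |
    (o1 == 0 & on_segment(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 1L], b[, 2L])) |
    (o2 == 0 & on_segment(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 3L], b[, 4L])) |
    (o3 == 0 & on_segment(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 1L], a[, 2L])) |
    (o4 == 0 & on_segment(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 3L], a[, 4L]))
  res
}

# squared distance from points (px, py) to segments (ax, ay, bx, by), recycled
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

# minimum distance between two segment sets (m x 4 matrices)
segset_min_dist <- function(s1, s2) {
  n1 <- nrow(s1); n2 <- nrow(s2)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  a <- s1[i, , drop = FALSE]; b <- s2[j, , drop = FALSE]
  if (any(segments_intersect(a, b))) return(0)
  d2 <- pmin(
    point_seg_dist2(a[, 1L], a[, 2L], b[, 1L], b[, 2L], b[, 3L], b[, 4L]),
    point_seg_dist2(a[, 3L], a[, 4L], b[, 1L], b[, 2L], b[, 3L], b[, 4L]),
    point_seg_dist2(b[, 1L], b[, 2L], a[, 1L], a[, 2L], a[, 3L], a[, 4L]),
    point_seg_dist2(b[, 3L], b[, 4L], a[, 1L], a[, 2L], a[, 3L], a[, 4L])
  )
  sqrt(min(d2))
}

# ring self-intersection check: any non-adjacent segment pair touching
ring_simple <- function(ring) {
  segs <- ring_segments(ring)
  n <- nrow(segs)
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 2L)) {
    js <- seq.int(i + 2L, n)
    if (i == 1L) js <- js[js != n]  # segment n is adjacent to segment 1
    if (length(js) == 0L) next
    a <- segs[rep(i, length(js)), , drop = FALSE]
    b <- segs[js, , drop = FALSE]
    if (any(segments_intersect(a, b))) return(FALSE)
  }
  TRUE
}

# even-odd containment of points in one ring; boundary treated separately
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xj <- x[c(n, seq_len(n - 1L))]; yj <- y[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    cross <- ((y[k] > py) != (yj[k] > py)) &
      (px < (xj[k] - x[k]) * (py - y[k]) / (yj[k] - y[k]) + x[k])
    inside <- xor(inside, cross)
  }
  inside
}

# geometry normalization: accepts a matrix (one ring), a list of ring
# matrices (one part with holes), or a list of such lists (multipart)
normalize_geometry <- function(geom, block_id = "?") {
  if (is.matrix(geom) || is.data.frame(geom)) {
    parts <- list(list(normalize_ring(geom, block_id)))
  } else if (is.list(geom) && length(geom) > 0L &&
             (is.matrix(geom[[1L]]) || is.data.frame(geom[[1L]]))) {
    parts <- list(lapply(geom, normalize_ring, block_id = block_id))
  } else if (is.list(geom)) {
    parts <- lapply(geom, function(p) lapply(p, normalize_ring, block_id = block_id))
  } else {
    stop("block ", block_id, ": unrecognized geometry")
  }
  for (p in parts) {
    for (r in p) {
      if (abs(ring_area(r)) <= 0) {
        stop("block ", block_id, ": ring with zero area")
      }
      if (!ring_simple(r)) {
        stop("block ", block_id, ": self-intersecting ring")
      }
    }
  }
  parts
}

# all boundary segments of a normalized geometry
geometry_segments <- function(parts) {
  do.call(rbind, lapply(parts, function(p) do.call(rbind, lapply(p, ring_segments))))
}

geometry_bbox <- function(parts) {
  xs <- unlist(lapply(parts, function(p) lapply(p, function(r) r[, 1L])))
  ys <- unlist(lapply(parts, function(p) lapply(p, function(r) r[, 2L])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# even-odd containment (holes respected) over all parts; points within
# boundary_eps of the boundary count as contained
points_in_geometry <- function(px, py, parts, boundary_eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  for (p in parts) {
    in_part <- rep(FALSE, length(px))
    for (r in p) in_part <- xor(in_part, points_in_ring(px, py, r))
    inside <- inside | in_part
  }
  if (boundary_eps > 0) {
    segs <- geometry_segments(parts)
    near <- rep(FALSE, length(px))
    for (k in seq_len(nrow(segs))) {
      idx <- which(!near & !inside)
      if (length(idx) == 0L) break
      d2 <- point_seg_dist2(px[idx], py[idx],
                            segs[k, 1L], segs[k, 2L], segs[k, 3L], segs[k, 4L])
      near[idx[d2 <= boundary_eps^2]] <- TRUE
    }
    inside <- inside | near
  }
  inside
}

#' Build a set of block geometries
#'
#' @param geometries named list of block geometries. Each geometry is an
#'   n x 2 coordinate matrix (one ring), a list of ring matrices (exterior
#'   plus holes), or a list of such lists (multipart). Coordinates are
#'   treated as planar/projected map units. Names are the block identifiers.
#' @return An object of class \code{block_set}.
#' @export
block_set <- function(geometries) {
  ids <- names(geometries)
  if (is.null(ids) || any(!nzchar(ids))) stop("every block needs a block_id name")
  if (anyDuplicated(ids)) {
    stop("duplicate block_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parts <- mapply(normalize_geometry, geometries, ids, SIMPLIFY = FALSE)
  bboxes <- t(vapply(parts, geometry_bbox, numeric(4L)))
  structure(list(ids = ids, parts = parts, bboxes = bboxes),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("block_set with", length(x$ids), "blocks\n")
  bb <- apply(x$bboxes, 2L, range)
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              bb[1L, 1L], bb[2L, 3L], bb[1L, 2L], bb[2L, 4L]))
  invisible(x)
}

#' @export
length.block_set <- function(x) length(x$ids)

#' Read block polygons from a GeoJSON FeatureCollection
#'
#' Supports Polygon and MultiPolygon geometries. Coordinates are expected in
#' a projected planar system.
#'
#' @param path path to a GeoJSON file.
#' @param id_property feature property holding the block identifier
#'   (default \code{"GEOID"}).
#' @param allow_geographic files whose \code{crs} member declares WGS84
#'   longitude/latitude (EPSG:4326 / CRS84) are rejected unless this is
#'   \code{TRUE}, because a snap tolerance expressed in degrees is hazardous.
#' @return A \code{block_set}.
#' @export
read_blocks_geojson <- function(path, id_property = "GEOID",
                                allow_geographic = FALSE) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("cannot parse GeoJSON: ",
                                          conditionMessage(e), call. = FALSE))
  if (!identical(gj$type, "FeatureCollection") || is.null(gj$features)) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  crs_name <- tryCatch(as.character(gj$crs$properties$name),
                       error = function(e) character())
  if (!allow_geographic && length(crs_name) == 1L &&
      grepl("4326|CRS84", crs_name)) {
    stop("GeoJSON declares geographic (lon/lat) coordinates (", crs_name,
         "); reproject to a planar system or set allow_geographic = TRUE")
  }
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  }
  geoms <- list()
  for (f in gj$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing id property '", id_property, "'")
    g <- f$geometry
    if (identical(g$type, "Polygon")) {
      geom <- lapply(g$coordinates, ring_mat)
    } else if (identical(g$type, "MultiPolygon")) {
      geom <- lapply(g$coordinates, function(poly) lapply(poly, ring_mat))
    } else {
      stop("unsupported geometry type '", g$type, "' for block ", id)
    }
    geoms[[as.character(id)]] <- geom
  }
  block_set(geoms)
}

#' Write a block set to a GeoJSON FeatureCollection
#'
#' @param blocks a \code{block_set}.
#' @param path output path.
#' @param id_property property name for the block identifier.
#' @return \code{path}, invisibly.
#' @export
write_blocks_geojson <- function(blocks, path, id_property = "GEOID") {
  stopifnot(inherits(blocks, "block_set"))
  feat <- function(i) {
    parts <- blocks$parts[[i]]
    close_ring <- function(r) {
      r <- rbind(r, r[1L, ])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1L], r[k, 2L]))
    }
    coords <- lapply(parts, function(p) lapply(p, close_ring))
    geom <- if (length(parts) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    props <- list(); props[[id_property]] <- blocks$ids[[i]]
    list(type = "Feature", properties = props, geometry = geom)
  }
  fc <- list(type = "FeatureCollection",
             features = lapply(seq_along(blocks$ids), feat))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
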