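# Contiguity graphs and river accessibility from planar polygon geometry.
#
# Coordinates are assumed planar (projected CRS); all geometry here is
# exact 2-D vector arithmetic with an absolute tolerance.

.geom_tol <- 1e-9

#' Construct a geometry set
#'
#' @param areas Named list (names = area ids). Each element is a polygon:
#'   either a single k x 2 coordinate matrix (outer ring, open or closed)
#'   or a list of such matrices (multi-part polygon).
#' @param rivers List of polylines, each a k x 2 coordinate matrix. May be
#'   empty.
#' @return An object of class `geometry_set`.
#' @export
geometry_set <- function(areas, rivers = list()) {
  if (is.null(names(areas)) || any(names(areas) == "")) {
    stop("area polygons must be named by area_id")
  }
  if (anyDuplicated(names(areas))) stop("duplicate area_id in geometry set")
  areas <- lapply(areas, function(p) {
    if (is.matrix(p)) list(p) else p
  })
  for (id in names(areas)) {
    for (ring in areas[[id]]) .validate_ring(ring, id)
  }
  rivers <- lapply(rivers, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 2) stop("river polyline needs >= 2 points")
    r
  })
  structure(list(areas = areas, rivers = rivers), class = "geometry_set")
}

.validate_ring <- function(ring, id) {
  if (!is.matrix(ring) || ncol(ring) != 2) {
    stop("polygon for area ", id, " is not a k x 2 coordinate matrix")
  }
  ring <- .close_ring(ring)
  if (nrow(ring) < 4) stop("polygon for area ", id, " has fewer than 3 vertices")
  # self-intersection among non-adjacent edges (before the area check, so
  # a bowtie is reported as self-intersecting, not as zero-area)
  segs <- .ring_segments(ring)
  n <- nrow(segs)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      adjacent <- (b == a + 1) || (a == 1 && b == n)
      if (adjacent) next
      if (.segments_intersect(segs[a, 1:2], segs[a, 3:4],
                              segs[b, 1:2], segs[b, 3:4])) {
        stop("polygon for area ", id, " is self-intersecting")
      }
    }
  }
  if (abs(.ring_area(ring)) < .geom_tol) {
    stop("polygon for area ", id, " is degenerate (zero area)")
  }
  invisible(TRUE)
}

.close_ring <- function(ring) {
  if (any(abs(ring[1, ] - ring[nrow(ring), ]) > .geom_tol)) {
    ring <- rbind(ring, ring[1, ])
  }
  ring
}

.ring_area <- function(ring) {
  ring <- .close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# segments of a closed ring as a matrix (x1, y1, x2, y2)
.ring_segments <- function(ring) {
  ring <- .close_ring(ring)
  n <- nrow(ring)
  cbind(ring[-n, , drop = FALSE], ring[-1, , drop = FALSE])
}

.poly_segments <- function(parts) {
  do.call(rbind, lapply(parts, .ring_segments))
}

.line_segments <- function(line) {
  n <- nrow(line)
  cbind(line[-n, , drop = FALSE], line[-1, , drop = FALSE])
}

.bbox <- function(coords) {
  c(min(coords[, 1]), min(coords[, 2]), max(coords[, 1]), max(coords[, 2]))
}

.bbox_overlap <- function(a, b, tol = .geom_tol) {
  a[1] <= b[3] + tol && b[1] <= a[3] + tol &&
    a[2] <= b[4] + tol && b[2] <= a[4] + tol
}

.cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

# segment intersection including endpoint touching and collinear overlap
.segments_intersect <- function(p1, p2, q1, q2, tol = .geom_tol) {
  d1 <- .cross2(q1, q2, p1); d2 <- .cross2(q1, q2, p2)
  d3 <- .cross2(p1, p2, q1); d4 <- .cross2(p1, p2, q2)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) {
    return(TRUE)
  }
  on_seg <- function(p, a, b) {
    abs(.cross2(a, b, p)) <= tol * (1 + max(abs(b - a))) &&
      p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
      p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol
  }
  on_seg(p1, q1, q2) || on_seg(p2, q1, q2) ||
    on_seg(q1, p1, p2) || on_seg(q2, p1, p2)
}

# length of the collinear overlap of two segments (0 if not collinear)
.collinear_overlap_length <- function(p1, p2, q1, q2, tol = .geom_tol) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  # perpendicular distance of q1, q2 from the p-line
  if (abs(.cross2(p1, p2, q1)) / len > tol) return(0)
  if (abs(.cross2(p1, p2, q2)) / len > tol) return(0)
  t1 <- sum((q1 - p1) * d) / len
  t2 <- sum((q2 - p1) * d) / len
  lo <- max(0, min(t1, t2)); hi <- min(len, max(t1, t2))
  max(0, hi - lo)
}

.point_in_ring <- function(pt, ring) {
  ring <- .close_ring(ring)
  n <- nrow(ring) - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- (xj - xi) * (pt[2] - yi) / (yj - yi) + xi
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.point_in_polygon <- function(pt, parts) {
  any(vapply(parts, function(r) .point_in_ring(pt, r), logical(1)))
}

.point_segment_distance <- function(pt, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- max(0, min(1, sum((pt - a) * d) / len2))
  sqrt(sum((pt - a - t * d)^2))
}

#' Polygon centroid (area-weighted)
#'
#' Standard shoelace centroid, summed over parts of a multi-part polygon.
#'
#' @param parts A polygon as stored in a [geometry_set()] (list of ring
#'   matrices) or a single ring matrix.
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(parts) {
  if (is.matrix(parts)) parts <- list(parts)
  A_tot <- 0; cx <- 0; cy <- 0
  for (ring in parts) {
    ring <- .close_ring(ring)
    x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
    cr <- x[-n] * y[-1] - x[-1] * y[-n]
    A <- sum(cr) / 2
    A_tot <- A_tot + A
    cx <- cx + sum((x[-n] + x[-1]) * cr) / 6
    cy <- cy + sum((y[-n] + y[-1]) * cr) / 6
  }
  if (abs(A_tot) < .geom_tol) stop("degenerate polygon: zero total area")
  c(cx, cy) / A_tot
}

# ---- adjacency graph --------------------------------------------------

#' Build an adjacency graph from an explicit edge list
#'
#' @param ids Character vector of node ids.
#' @param edges Two-column matrix (or data frame) of node indices or ids;
#'   may have zero rows.
#' @return An `adjacency_graph`: list with `ids`, `nb` (neighbor index
#'   list), `edges` (2-column index matrix, i < j).
#' @export
adjacency_from_edges <- function(ids, edges) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate node ids")
  n <- length(ids)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || nrow(edges) == 0) {
    em <- matrix(integer(0), 0, 2)
  } else {
    if (is.character(edges)) {
      em <- cbind(match(edges[, 1], ids), match(edges[, 2], ids))
      if (any(is.na(em))) stop("edge references unknown node id")
    } else {
      em <- matrix(as.integer(edges), ncol = 2)
      if (any(em < 1 | em > n)) stop("edge index out of range")
    }
    if (any(em[, 1] == em[, 2])) stop("self-loops are not allowed")
    em <- t(apply(em, 1, sort))
    em <- unique(em)
  }
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (nrow(em) > 0) {
    for (k in seq_len(nrow(em))) {
      i <- em[k, 1]; j <- em[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
    nb <- lapply(nb, sort)
  }
  structure(list(ids = ids, nb = nb, edges = em), class = "adjacency_graph")
}

#' Contiguity adjacency from polygon geometry
#'
#' Rook contiguity links two areas when their boundaries share a segment
#' of positive length; queen contiguity additionally links areas that
#' touch at a single point (shared corner).
#'
#' @param geoms A [geometry_set()].
#' @param contiguity `"rook"` (default) or `"queen"`.
#' @return An `adjacency_graph` over the areas of `geoms`.
#' @export
build_adjacency <- function(geoms, contiguity = c("rook", "queen")) {
  stopifnot(inherits(geoms, "geometry_set"))
  contiguity <- match.arg(contiguity)
  ids <- names(geoms$areas)
  n <- length(ids)
  segs <- lapply(geoms$areas, .poly_segments)
  boxes <- lapply(geoms$areas, function(p) .bbox(do.call(rbind, p)))

  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq((i + 1), n)) {
      if (!.bbox_overlap(boxes[[i]], boxes[[j]])) next
      if (.polys_contiguous(segs[[i]], segs[[j]], contiguity)) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  adjacency_from_edges(ids, edges)
}

.polys_contiguous <- function(sa, sb, contiguity) {
  for (a in seq_len(nrow(sa))) {
    p1 <- sa[a, 1:2]; p2 <- sa[a, 3:4]
    for (b in seq_len(nrow(sb))) {
      q1 <- sb[b, 1:2]; q2 <- sb[b, 3:4]
      if (contiguity == "rook") {
        if (.collinear_overlap_length(p1, p2, q1, q2) > 1e-7) return(TRUE)
      } else {
        if (.segments_intersect(p1, p2, q1, q2)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Connected components of an adjacency graph
#'
#' @param graph An `adjacency_graph`.
#' @return Integer vector of component labels (1-based), one per node.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$ids)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in graph$nb[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", length(x$ids), " nodes, ", nrow(x$edges),
      " edges, ", max(graph_components(x)), " component(s)\n", sep = "")
  invisible(x)
}

# ---- river indicators -------------------------------------------------

#' Binary river adjacency indicator
#'
#' Flags an area when any river polyline passes through the area polygon
#' or runs along its boundary.
#'
#' @param geoms A [geometry_set()] with a nonempty river layer.
#' @return Named integer vector (0/1) over areas.
#' @export
river_adjacent <- function(geoms) {
  stopifnot(inherits(geoms, "geometry_set"))
  if (length(geoms$rivers) == 0) stop("geometry set has no river layer")
  ids <- names(geoms$areas)
  rsegs <- lapply(geoms$rivers, .line_segments)
  out <- setNames(integer(length(ids)), ids)
  for (id in ids) {
    parts <- geoms$areas[[id]]
    psegs <- .poly_segments(parts)
    pbox <- .bbox(do.call(rbind, parts))
    hit <- FALSE
    for (k in seq_along(geoms$rivers)) {
      riv <- geoms$rivers[[k]]
      if (!.bbox_overlap(pbox, .bbox(riv))) next
      # river vertex strictly inside the polygon
      for (v in seq_len(nrow(riv))) {
        if (.point_in_polygon(riv[v, ], parts)) { hit <- TRUE; break }
      }
      if (hit) break
      # river segment crossing or touching the boundary
      rs <- rsegs[[k]]
      for (a in seq_len(nrow(rs))) {
        for (b in seq_len(nrow(psegs))) {
          if (.segments_intersect(rs[a, 1:2], rs[a, 3:4],
                                  psegs[b, 1:2], psegs[b, 3:4])) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit) break
    }
    out[id] <- as.integer(hit)
  }
  out
}

#' Distance from each area centroid to the nearest river
#'
#' Euclidean distance, in the coordinate units of the input, from the
#' polygon centroid to the nearest point on any river polyline.
#'
#' @param geoms A [geometry_set()] with a nonempty river layer.
#' @return Named numeric vector of nonnegative distances.
#' @export
centroid_river_distance <- function(geoms) {
  stopifnot(inherits(geoms, "geometry_set"))
  if (length(geoms$rivers) == 0) stop("geometry set has no river layer")
  ids <- names(geoms$areas)
  rsegs <- do.call(rbind, lapply(geoms$rivers, .line_segments))
  out <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    ct <- polygon_centroid(geoms$areas[[id]])
    d <- Inf
    for (a in seq_len(nrow(rsegs))) {
      d <- min(d, .point_segment_distance(ct, rsegs[a, 1:2], rsegs[a, 3:4]))
    }
    out[id] <- d
  }
  out
}

# ---- GeoJSON interfaces -----------------------------------------------

#' Read a geometry set from GeoJSON files
#'
#' Areas: a FeatureCollection of Polygon/MultiPolygon features with an
#' `area_id` property. Rivers: a FeatureCollection of LineString /
#' MultiLineString features (optional).
#'
#' @param areas_path GeoJSON file of area polygons.
#' @param rivers_path GeoJSON file of river polylines, or `NULL`.
#' @return A [geometry_set()].
#' @export
read_geojson <- function(areas_path, rivers_path = NULL) {
  gj <- jsonlite::fromJSON(areas_path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop(areas_path, " is not a FeatureCollection")
  areas <- list()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop("area feature lacks an area_id property")
    geom <- f$geometry
    coords_to_ring <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    parts <- switch(geom$type,
      Polygon = list(coords_to_ring(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates,
                            function(poly) coords_to_ring(poly[[1]])),
      stop("unsupported area geometry type: ", geom$type))
    areas[[as.character(id)]] <- parts
  }
  rivers <- list()
  if (!is.null(rivers_path)) {
    rj <- jsonlite::fromJSON(rivers_path, simplifyVector = FALSE)
    for (f in rj$features) {
      geom <- f$geometry
      lines <- switch(geom$type,
        LineString = list(geom$coordinates),
        MultiLineString = geom$coordinates,
        stop("unsupported river geometry type: ", geom$type))
      for (ln in lines) {
        rivers[[length(rivers) + 1]] <-
          do.call(rbind, lapply(ln, function(pt) c(pt[[1]], pt[[2]])))
      }
    }
  }
  geometry_set(areas, rivers)
}

#' Write a geometry set to GeoJSON files
#'
#' @param geoms A [geometry_set()].
#' @param areas_path Output path for the area FeatureCollection.
#' @param rivers_path Output path for the river FeatureCollection, or
#'   `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_geojson <- function(geoms, areas_path, rivers_path = NULL) {
  stopifnot(inherits(geoms, "geometry_set"))
  ring_to_coords <- function(ring) {
    ring <- .close_ring(ring)
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  }
  feats <- lapply(names(geoms$areas), function(id) {
    parts <- geoms$areas[[id]]
    geom <- if (length(parts) == 1) {
      list(type = "Polygon", coordinates = list(ring_to_coords(parts[[1]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(parts, function(r) list(ring_to_coords(r))))
    }
    list(type = "Feature", properties = list(area_id = id), geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       areas_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(rivers_path)) {
    rfeats <- lapply(geoms$rivers, function(ln) {
      list(type = "Feature", properties = list(),
           geometry = list(
             type = "LineString",
             coordinates = lapply(seq_len(nrow(ln)),
                                  function(i) c(ln[i, 1], ln[i, 2]))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = rfeats),
                         rivers_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(areas_path, rivers_path))
}

#' Write an adjacency graph as an edge-list CSV
#'
#' @param graph An `adjacency_graph`.
#' @param path Output CSV (columns `from`, `to`, area ids).
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  df <- data.frame(from = graph$ids[graph$edges[, 1]],
                   to = graph$ids[graph$edges[, 2]],
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an adjacency graph from an edge-list CSV
#'
#' @param path CSV with columns `from`, `to`.
#' @param ids Full node id set (isolates have no edges).
#' @return An `adjacency_graph`.
#' @export
read_adjacency_csv <- function(path, ids) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(from = "character", to = "character"))
  adjacency_from_edges(ids, as.matrix(df[c("from", "to")]))
}
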