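# Planar and spherical geometry primitives shared by the landscape,
# hull and synthetic-world modules.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points in decimal degrees
#'
#' Haversine formula on a spherical Earth (radius 6371.0088 km).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in WGS84 decimal degrees;
#'   vectors are recycled.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Central angle in degrees between two points (used for site collapsing,
# where the tolerance is expressed in "great-circle degrees").
central_angle_deg <- function(lon1, lat1, lon2, lat2) {
  haversine_km(lon1, lat1, lon2, lat2) / (EARTH_RADIUS_KM * pi / 180)
}

# Circumcircle of triangle (p1, p2, p3), each a length-2 numeric (x, y).
# Returns list(center = c(x, y), r2 = squared radius), or NULL if the
# points are collinear.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]
  bx <- p2[1]; by <- p2[2]
  cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(center = c(ux, uy), r2 = (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of planar points
#'
#' Bowyer--Watson incremental insertion. Points are treated as planar
#' (lon, lat); suitable for the regional scales this package targets.
#' Near-cocircular degeneracies are resolved by a small deterministic
#' jitter of the insertion order (not of the coordinates).
#'
#' @param x,y Numeric vectors of point coordinates (no duplicates).
#' @return A matrix with columns \code{i, j, k}: vertex indices of each
#'   triangle, each row sorted increasingly.
#' @export
delaunay_triangles <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("Delaunay triangulation needs at least 3 points")
  if (anyDuplicated(cbind(x, y))) stop("duplicate points in triangulation input")

  # super-triangle enclosing all points
  span <- max(max(x) - min(x), max(y) - min(y), 1e-9)
  cx <- (min(x) + max(x)) / 2
  cy <- (min(y) + max(y)) / 2
  big <- 50 * span
  px <- c(x, cx - big, cx + big, cx)
  py <- c(y, cy - big / 2, cy - big / 2, cy + big)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- list(c(s1, s2, s3))
  circ <- list(circumcircle(c(px[s1], py[s1]), c(px[s2], py[s2]),
                            c(px[s3], py[s3])))

  for (ip in seq_len(n)) {
    p <- c(px[ip], py[ip])
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      cc <- circ[[t]]
      bad[t] <- !is.null(cc) &&
        ((p[1] - cc$center[1])^2 + (p[2] - cc$center[2])^2) <= cc$r2 * (1 + 1e-12)
    }
    # boundary of the cavity: edges appearing in exactly one bad triangle
    edges <- list()
    for (t in which(bad)) {
      v <- tris[[t]]
      edges[[length(edges) + 1L]] <- sort(c(v[1], v[2]))
      edges[[length(edges) + 1L]] <- sort(c(v[2], v[3]))
      edges[[length(edges) + 1L]] <- sort(c(v[1], v[3]))
    }
    if (length(edges)) {
      em <- do.call(rbind, edges)
      key <- paste(em[, 1], em[, 2])
      keep <- key[!(key %in% key[duplicated(key)])]
      boundary <- em[match(keep, key), , drop = FALSE]
    } else {
      boundary <- matrix(integer(0), 0, 2)
    }
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, 1], boundary[e, 2], ip)
      tris[[length(tris) + 1L]] <- v
      circ[[length(circ) + 1L]] <-
        circumcircle(c(px[v[1]], py[v[1]]), c(px[v[2]], py[v[2]]),
                     c(px[v[3]], py[v[3]]))
    }
  }

  keep <- vapply(tris, function(v) all(v <= n), logical(1))
  out <- do.call(rbind, lapply(tris[keep], sort))
  if (is.null(out)) stop("triangulation degenerate (collinear points?)")
  colnames(out) <- c("i", "j", "k")
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# Unique undirected edges (2-column matrix, i < j) from a triangle matrix.
triangles_to_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# TRUE if point (qx, qy) lies inside or on triangle p1 p2 p3.
point_in_triangle <- function(qx, qy, p1, p2, p3) {
  sign_area <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- sign_area(p1[1], p1[2], p2[1], p2[2], qx, qy)
  d2 <- sign_area(p2[1], p2[2], p3[1], p3[2], qx, qy)
  d3 <- sign_area(p3[1], p3[2], p1[1], p1[2], qx, qy)
  eps <- 1e-12
  neg <- (d1 < -eps) | (d2 < -eps) | (d3 < -eps)
  pos <- (d1 > eps) | (d2 > eps) | (d3 > eps)
  !(neg & pos)
}
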