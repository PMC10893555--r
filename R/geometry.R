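# Exact convex-polygon geometry for signalling-niche overlap.
#
# All polygons are n x 2 numeric matrices of vertices in counter-clockwise
# (CCW) order, without a repeated closing vertex. Areas are by the shoelace
# formula; intersections by Sutherland-Hodgman half-plane clipping (exact for
# convex operands); union areas by a vertical slab decomposition that is exact
# because the union's cross-section length is linear in x within each slab.

# numerical conventions: vertices closer than .coincident_tol are one point;
# areas below .area_tol count as zero (suppresses floating-point slivers that
# would otherwise inflate "nonzero overlap" counts)
.coincident_tol <- 1e-9
.area_tol <- 1e-12

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order, negative for clockwise.
#'
#' @param xy n x 2 matrix of polygon vertices, no repeated closing vertex.
#' @return Signed area.
#' @keywords internal
polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area
#'
#' Absolute area of a simple polygon by the shoelace formula.
#'
#' @param xy n x 2 matrix of vertices.
#' @return Non-negative area.
#' @export
polygon_area <- function(xy) abs(polygon_area_signed(xy))

#' Area-weighted polygon centroid
#'
#' @param xy n x 2 matrix of vertices of a simple polygon with positive area.
#' @return Length-2 numeric (x, y). For degenerate (zero-area) input, the
#'   vertex mean is returned.
#' @export
polygon_centroid <- function(xy) {
  a <- polygon_area_signed(xy)
  if (abs(a) < .area_tol) return(colMeans(xy))
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Convex hull of a 2-D point set
#'
#' Thin wrapper around [grDevices::chull()] returning vertices in CCW order.
#'
#' @param xy n x 2 matrix of points.
#' @return Matrix of hull vertices in CCW order.
#' @export
convex_hull <- function(xy) {
  xy <- as.matrix(xy)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  h <- xy[idx, , drop = FALSE]
  if (nrow(h) >= 3 && polygon_area_signed(h) < 0) h <- h[nrow(h):1, , drop = FALSE]
  unname(h)
}

#' Test points for inclusion in a convex polygon
#'
#' A point is inside if it lies on the inner side of every edge of the CCW
#' polygon, within tolerance `tol` (so boundary points count as inside).
#'
#' @param points m x 2 matrix of query points.
#' @param hull n x 2 CCW convex polygon.
#' @param tol slack on the cross-product sign test.
#' @return Logical vector of length m.
#' @export
point_in_convex <- function(points, hull, tol = .coincident_tol) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(hull)
  inside <- rep(TRUE, nrow(points))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    cr <- ex * (points[, 2] - hull[i, 2]) - ey * (points[, 1] - hull[i, 1])
    inside <- inside & (cr >= -tol)
  }
  inside
}

# drop consecutive (near-)duplicate vertices
.dedupe_vertices <- function(xy, tol = .coincident_tol) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  keep <- sqrt(rowSums((xy - nxt)^2)) > tol
  # keep[i] FALSE means vertex i duplicates its successor
  xy[keep | !any(keep), , drop = FALSE]
}

#' Clip a polygon to a convex polygon (Sutherland-Hodgman)
#'
#' Clips `subject` against each half-plane defined by the CCW edges of
#' `clip`. Exact for convex `subject`; for convex inputs the result is the
#' (convex) intersection polygon.
#'
#' @param subject n x 2 CCW polygon.
#' @param clip m x 2 CCW convex polygon.
#' @return Matrix of vertices of the clipped polygon (possibly with fewer
#'   than 3 rows when the intersection is empty or degenerate).
#' @export
clip_convex <- function(subject, clip) {
  out <- subject
  m <- nrow(clip)
  for (i in seq_len(m)) {
    if (nrow(out) == 0) break
    j <- if (i == m) 1L else i + 1L
    ax <- clip[i, 1]; ay <- clip[i, 2]
    ex <- clip[j, 1] - ax; ey <- clip[j, 2] - ay
    d <- ex * (out[, 2] - ay) - ey * (out[, 1] - ax)   # >= 0 means inside
    n <- nrow(out)
    res <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      din <- d[k] >= -.coincident_tol
      d2in <- d[k2] >= -.coincident_tol
      if (din) res <- rbind(res, out[k, ])
      if (din != d2in) {
        t <- d[k] / (d[k] - d[k2])
        res <- rbind(res, out[k, ] + t * (out[k2, ] - out[k, ]))
      }
    }
    out <- res
  }
  .dedupe_vertices(out)
}

#' Intersection of two convex polygons
#'
#' @param hull_a,hull_b CCW convex polygons (n x 2 matrices) with positive
#'   area; degenerate input is an error.
#' @return List with `polygon` (CCW matrix, possibly empty) and `area`.
#'   Areas below `1e-12` are reported as exactly 0 and the polygon as empty.
#' @export
intersect_convex <- function(hull_a, hull_b) {
  for (h in list(hull_a, hull_b)) {
    if (is.null(nrow(h)) || nrow(h) < 3 || polygon_area(h) < .area_tol)
      stop("intersect_convex: degenerate input hull")
  }
  p <- clip_convex(hull_a, hull_b)
  a <- if (nrow(p) >= 3) polygon_area(p) else 0
  if (a < .area_tol) {
    list(polygon = matrix(numeric(0), ncol = 2), area = 0)
  } else {
    if (polygon_area_signed(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
    list(polygon = p, area = a)
  }
}

# edge table for a list of polygons: columns x1 y1 x2 y2, attr poly id
.edge_table <- function(polys) {
  do.call(rbind, lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    cbind(p, nxt, i)
  }))
}

# x-coordinates where any two edges (from a flat edge table) intersect
.edge_crossing_x <- function(ed) {
  n <- nrow(ed)
  if (n < 2) return(numeric(0))
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  p1x <- ed[ii, 1]; p1y <- ed[ii, 2]; p2x <- ed[ii, 3]; p2y <- ed[ii, 4]
  q1x <- ed[jj, 1]; q1y <- ed[jj, 2]; q2x <- ed[jj, 3]; q2y <- ed[jj, 4]
  rx <- p2x - p1x; ry <- p2y - p1y
  sx <- q2x - q1x; sy <- q2y - q1y
  den <- rx * sy - ry * sx
  ok <- abs(den) > 1e-14
  t <- ((q1x - p1x) * sy - (q1y - p1y) * sx) / den
  u <- ((q1x - p1x) * ry - (q1y - p1y) * rx) / den
  ok <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
  (p1x + t * rx)[ok]
}

#' Area of the union of convex polygons
#'
#' Exact union area by vertical slab decomposition: the x axis is cut at
#' every vertex and every pairwise edge crossing, so that within a slab each
#' polygon's vertical cross-section has linear endpoints and the set of
#' merged intervals is combinatorially constant. The union's cross-section
#' length is then linear in x within the slab and the midpoint rule
#' integrates it exactly.
#'
#' @param polys List of CCW convex polygons (n x 2 matrices); zero-area
#'   entries are dropped.
#' @return Union area (0 for an empty list).
#' @export
union_area_convex <- function(polys) {
  polys <- Filter(function(p) !is.null(nrow(p)) && nrow(p) >= 3 &&
                    polygon_area(p) >= .area_tol, polys)
  if (length(polys) == 0) return(0)
  if (length(polys) == 1) return(polygon_area(polys[[1]]))
  ed <- .edge_table(polys)
  cuts <- sort(unique(c(ed[, 1], ed[, 3], .edge_crossing_x(ed))))
  area <- 0
  for (s in seq_len(length(cuts) - 1)) {
    x0 <- cuts[s]; x1 <- cuts[s + 1]
    w <- x1 - x0
    if (w <= .area_tol) next
    xm <- (x0 + x1) / 2
    # vertical extent of each polygon at xm
    spans <- (pmin(ed[, 1], ed[, 3]) <= xm) & (pmax(ed[, 1], ed[, 3]) >= xm) &
      (abs(ed[, 3] - ed[, 1]) > 1e-14)
    if (!any(spans)) next
    e <- ed[spans, , drop = FALSE]
    yv <- e[, 2] + (xm - e[, 1]) * (e[, 4] - e[, 2]) / (e[, 3] - e[, 1])
    lo <- tapply(yv, e[, 5], min)
    hi <- tapply(yv, e[, 5], max)
    # merge intervals and accumulate union length
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    len <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
    for (k in seq_along(lo)[-1]) {
      if (lo[k] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[k])
      } else {
        len <- len + (cur_hi - cur_lo)
        cur_lo <- lo[k]; cur_hi <- hi[k]
      }
    }
    len <- len + (cur_hi - cur_lo)
    area <- area + w * len
  }
  unname(area)
}
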