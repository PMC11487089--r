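#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer–Watson triangulation. Points are inserted one at a
#' time into a super-triangle; triangles whose circumcircle contains the new
#' point are removed and the resulting cavity is re-triangulated. Triangles
#' touching the super-triangle are dropped at the end, leaving the Delaunay
#' triangulation of the convex hull.
#'
#' @param points a [point_set] or a data.frame with columns `x_um`, `y_um`.
#' @return integer matrix with one row per triangle and columns `i`, `j`,
#'   `k` (point indices, each row sorted increasingly).
#' @export
delaunay <- function(points) {
  x <- points$x_um; y <- points$y_um
  n <- length(x)
  if (n < 3) ds_stop("need at least 3 points", "geometry_error")
  if (anyDuplicated(cbind(x, y)))
    ds_stop("duplicate points", "geometry_error")
  span <- max(max(x) - min(x), max(y) - min(y), 1)
  if (all(abs(cross_all(x, y)) < 1e-9 * span^2))
    ds_stop("all points are collinear", "geometry_error")

  # super-triangle far enough out that no real circumcircle reaches it
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- span * 4096 + 1
  px <- c(x, cx - 2 * r, cx + 2 * r, cx)
  py <- c(y, cy - r, cy - r, cy + 2 * r)
  sup <- n + 1:3

  # triangle store: vertex indices and cached circumcenter/radius^2
  tri <- matrix(sup, 1, 3)
  cc <- matrix(circumcircle(px[sup], py[sup]), 1, 3)

  for (p in seq_len(n)) {
    bad <- which((px[p] - cc[, 1])^2 + (py[p] - cc[, 2])^2 <= cc[, 3])
    # boundary of the cavity: edges of bad triangles that appear exactly once
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(1, 3), drop = FALSE])
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(keep, p)
    newc <- t(apply(newt, 1, function(v) circumcircle(px[v], py[v])))
    tri <- rbind(tri, newt)
    cc <- rbind(cc, newc)
  }
  tri <- tri[rowSums(matrix(tri %in% sup, nrow(tri))) == 0L, , drop = FALSE]
  if (nrow(tri) == 0L)
    ds_stop("degenerate point set: no finite triangles", "geometry_error")
  out <- t(apply(tri, 1, sort))
  colnames(out) <- c("i", "j", "k")
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# cross products of (p_i - p_1) x (p_2 - p_1) for all i; used to detect
# collinear input quickly
cross_all <- function(x, y) {
  (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
}

# circumcenter (cx, cy) and squared radius of the triangle through three
# points; degenerate (collinear) triples get an infinite circle
circumcircle <- function(x, y) {
  ax <- x[1]; ay <- y[1]; bx <- x[2]; by <- y[2]; cx <- x[3]; cy <- y[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

# area of each triangle (rows of `tri`) over the coordinates
triangle_areas <- function(points, tri) {
  x <- points$x_um; y <- points$y_um
  abs((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
        (x[tri[, 3]] - x[tri[, 1]]) * (y[tri[, 2]] - y[tri[, 1]])) / 2
}
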