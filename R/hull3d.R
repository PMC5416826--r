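# 3D convex hull (incremental algorithm) and its volume. Self-contained
# geometry used by the foci morphometry; exact up to floating point, so
# hull volume is exactly scale-equivariant (factor s^3 under isotropic
# scaling).

# Signed Euclidean distance of points `p` (m x 3) above the plane of
# facet (a, b, c); positive on the side of the outward normal. The
# normal is normalized so the tolerance is a length, independent of
# facet area.
facet_dist <- function(p, a, b, c) {
  nrm <- crossprod3(b - a, c - a)
  len <- sqrt(sum(nrm^2))
  if (len == 0) return(rep(0, nrow(p)))
  (p - matrix(a, nrow(p), 3, byrow = TRUE)) %*% (nrm / len)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' 3D convex hull of a point set
#'
#' Incremental construction: an initial non-degenerate tetrahedron is
#' grown by inserting each remaining point, removing the facets it sees,
#' and stitching new facets over the horizon edges. Points coplanar with
#' a facet (within tolerance) are treated as interior to it, which
#' leaves the enclosed volume unchanged.
#'
#' @param pts numeric n x 3 matrix (n >= 4, not all coplanar).
#' @return list with `facets` (m x 3 matrix of point indices, outward
#'   orientation) and `vertices` (indices of points on the hull).
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop_param("need at least 4 points for a 3D hull")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop_param("all points coincide")
  eps <- 1e-9 * scale       # length tolerance for coplanarity

  # initial tetrahedron: two extreme points, farthest from their line,
  # farthest from their plane
  i1 <- which.min(pts[, 1])
  d2 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d2)
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(w[, 2] * u[3] - w[, 3] * u[2],
              w[, 3] * u[1] - w[, 1] * u[3],
              w[, 1] * u[2] - w[, 2] * u[1])
  i3 <- which.max(rowSums(cr^2))
  dd <- abs(facet_dist(pts, pts[i1, ], pts[i2, ], pts[i3, ]))
  i4 <- which.max(dd)
  if (dd[i4] <= eps) stop_param("points are coplanar; 3D hull undefined")

  # orient the initial facets outward w.r.t. the tetrahedron centroid
  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  mk <- function(a, b, c) {
    if (facet_dist(matrix(ctr, 1), pts[a, ], pts[b, ], pts[c, ]) > 0)
      c(a, c, b) else c(a, b, c)
  }
  facets <- rbind(mk(i1, i2, i3), mk(i1, i2, i4),
                  mk(i1, i3, i4), mk(i2, i3, i4))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    pp <- matrix(pts[p, ], 1)
    vis <- vapply(seq_len(nrow(facets)), function(f)
      facet_dist(pp, pts[facets[f, 1], ], pts[facets[f, 2], ],
                 pts[facets[f, 3], ]) > eps, logical(1))
    if (!any(vis)) next
    # horizon: directed edges of visible facets whose reverse is not in
    # a visible facet
    vf <- facets[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    ekey <- paste(edges[, 1], edges[, 2])
    rkey <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rkey %in% ekey), , drop = FALSE]
    facets <- facets[!vis, , drop = FALSE]
    new_f <- cbind(horizon[, 1], horizon[, 2], p)
    facets <- rbind(facets, new_f)
  }
  list(facets = facets, vertices = sort(unique(as.vector(facets))))
}

#' Volume enclosed by the 3D convex hull of a point set
#'
#' Sum of signed tetrahedron volumes from an interior reference point to
#' each outward-oriented hull facet.
#'
#' @param pts numeric n x 3 matrix.
#' @return hull volume in the cube of the input units.
#' @export
convex_hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  hull <- convex_hull_3d(pts)
  ref <- colMeans(pts[hull$vertices, , drop = FALSE])
  vol <- 0
  for (f in seq_len(nrow(hull$facets))) {
    a <- pts[hull$facets[f, 1], ] - ref
    b <- pts[hull$facets[f, 2], ] - ref
    c <- pts[hull$facets[f, 3], ] - ref
    vol <- vol + sum(crossprod3(a, b) * c) / 6
  }
  abs(vol)
}
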