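# Super-resolution rendering: 2D binned histogram images and Voronoi
# ("Wigner-Seitz" cell) density images.

new_rendered_image <- function(values, pixel_size_nm, origin_nm, mode) {
  structure(list(values = values, pixel_size_nm = pixel_size_nm,
                 origin_nm = origin_nm, mode = mode),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("Rendered image (%s): %d x %d px at %.1f nm/px, sum %.4g\n",
              x$mode, nrow(x$values), ncol(x$values), x$pixel_size_nm,
              sum(x$values)))
  invisible(x)
}

#' @export
plot.rendered_image <- function(x, q = 0.999, ...) {
  v <- x$values
  hi <- quantile(v[v > 0], q, na.rm = TRUE)
  if (!is.finite(hi) || hi <= 0) hi <- max(v, 1e-12)
  image(t(pmin(v, hi))[, nrow(v):1], col = gray(seq(0, 1, length.out = 256)),
        asp = nrow(v) / ncol(v), axes = FALSE, ...)
  invisible(x)
}

#' Render a binned 2D histogram image from a localization table
#'
#' Each localization contributes one count to the half-open bin
#' `[k * bin, (k + 1) * bin)` containing it, so the image sum equals the
#' number of rendered localizations exactly, at any bin size.
#'
#' @param table a `loc_table`.
#' @param bin_nm bin (output pixel) size in nm.
#' @param extent_nm optional `c(xmin, xmax, ymin, ymax)` in nm; defaults
#'   to `[0, max]` of the data rounded up to whole bins. Localizations
#'   outside the extent are not rendered.
#' @return a `rendered_image` (mode `"histogram"`).
#' @export
render_histogram <- function(table, bin_nm, extent_nm = NULL) {
  check_positive(bin_nm, "bin_nm")
  if (is.null(extent_nm)) {
    if (nrow(table) == 0L) extent_nm <- c(0, bin_nm, 0, bin_nm)
    else extent_nm <- c(0, (floor(max(table$x_nm) / bin_nm) + 1) * bin_nm,
                        0, (floor(max(table$y_nm) / bin_nm) + 1) * bin_nm)
  }
  nx <- max(1L, round((extent_nm[2] - extent_nm[1]) / bin_nm))
  ny <- max(1L, round((extent_nm[4] - extent_nm[3]) / bin_nm))
  vals <- matrix(0, ny, nx)
  if (nrow(table) > 0L) {
    ix <- floor((table$x_nm - extent_nm[1]) / bin_nm) + 1L
    iy <- floor((table$y_nm - extent_nm[3]) / bin_nm) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (any(ok)) {
      tab <- table(factor((ix[ok] - 1L) * ny + iy[ok],
                          levels = seq_len(nx * ny)))
      vals <- matrix(as.numeric(tab), ny, nx)
    }
  }
  new_rendered_image(vals, bin_nm, c(extent_nm[1], extent_nm[3]),
                     "histogram")
}

# ---- convex polygon helpers (counter-clockwise vertex matrices) -------

# Clip a convex polygon by the halfplane  n . p <= c  (Sutherland-Hodgman).
clip_halfplane <- function(poly, nvec, cval) {
  np <- nrow(poly)
  if (np == 0L) return(poly)
  d <- poly %*% nvec - cval
  if (all(d <= 0)) return(poly)
  if (all(d > 0)) return(poly[0, , drop = FALSE])
  out <- matrix(NA_real_, np + 2L, 2L)
  m <- 0L
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    if (d[i] <= 0) { m <- m + 1L; out[m, ] <- poly[i, ] }
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Convex hull of points, counter-clockwise, offset outward by `r` using
# edge-halfplane shifts (miter joins).
dilated_hull <- function(pts, r) {
  h <- chull(pts)                    # clockwise in R's convention
  hull <- pts[rev(h), , drop = FALSE]  # counter-clockwise
  n <- nrow(hull)
  if (n < 3L) stop_param("points are collinear; no planar hull")
  # start from the bounding box of hull + r, clip by shifted edges
  lo <- apply(hull, 2, min) - 2 * r
  hi <- apply(hull, 2, max) + 2 * r
  poly <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]),
                c(hi[1], hi[2]), c(lo[1], hi[2]))
  for (i in seq_len(n)) {
    jp <- if (i == n) 1L else i + 1L
    e <- hull[jp, ] - hull[i, ]
    nv <- c(e[2], -e[1])             # outward normal for CCW polygon
    nv <- nv / sqrt(sum(nv^2))
    cv <- sum(nv * hull[i, ]) + r
    poly <- clip_halfplane(poly, nv, cv)
  }
  poly
}

# Mean 2D nearest-neighbour distance (used as the hull dilation radius).
mean_nn_2d <- function(pts) {
  n <- nrow(pts)
  nnd <- numeric(n)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(pts[s:e, 1], pts[, 1], "-")^2 +
          outer(pts[s:e, 2], pts[, 2], "-")^2
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    nnd[s:e] <- sqrt(apply(d2, 1, min))
  }
  mean(nnd)
}

#' Render a Voronoi-cell density image from a localization table
#'
#' Each localization's planar Voronoi ("Wigner-Seitz") cell, clipped to
#' the convex hull of the points dilated by the mean nearest-neighbour
#' distance, is assigned the value `1 / area` (a local density in
#' nm^-2). The tessellation is rasterized at `pixel_nm` by nearest-site
#' assignment (equidistant pixels go to the lowest site index); pixels
#' outside the clip region are 0.
#'
#' Cell areas are computed exactly by halfplane clipping (each cell is
#' the intersection of the clip polygon with the perpendicular-bisector
#' halfplanes against the other sites, visited in order of increasing
#' distance with an early exit), so the integral of the image equals the
#' number of localizations up to rasterization error.
#'
#' @param table a `loc_table` (or any data frame with `x_nm`, `y_nm`);
#'   at least 4 non-collinear points.
#' @param pixel_nm output pixel size, nm (default 5, the standard fBALM
#'   reconstruction pixel).
#' @return a `rendered_image` (mode `"voronoi"`) with attributes
#'   `cell_areas_nm2` and `clip_polygon`.
#' @export
render_voronoi <- function(table, pixel_nm = 5) {
  check_positive(pixel_nm, "pixel_nm")
  pts <- cbind(table$x_nm, table$y_nm)
  if (nrow(pts) < 4L)
    stop_param(paste("need at least 4 points for a Voronoi rendering;",
                     "use render_histogram() instead"))
  if (length(chull(pts)) < 3L)
    stop_param(paste("points are collinear; Voronoi cells are unbounded",
                     "- use render_histogram() instead"))
  n <- nrow(pts)
  r_dilate <- mean_nn_2d(pts)
  clip <- dilated_hull(pts, r_dilate)

  # exact cell areas by incremental bisector clipping
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    ord <- order(d2)
    poly <- clip
    for (j in ord) {
      if (j == i) next
      dj <- d2[j]
      if (nrow(poly) == 0L) break
      # early exit: no farther site can cut the current cell
      maxr2 <- max((poly[, 1] - pts[i, 1])^2 + (poly[, 2] - pts[i, 2])^2)
      if (dj > 4 * maxr2) break
      nv <- pts[j, ] - pts[i, ]
      cv <- sum(nv * (pts[i, ] + pts[j, ]) / 2)
      poly <- clip_halfplane(poly, nv, cv)
    }
    areas[i] <- polygon_area(poly)
  }
  vals_per_site <- ifelse(areas > 0, 1 / areas, 0)

  # rasterize: nearest site per pixel centre, lowest index wins ties
  lo <- apply(clip, 2, min)
  hi <- apply(clip, 2, max)
  x0 <- floor(lo[1] / pixel_nm) * pixel_nm
  y0 <- floor(lo[2] / pixel_nm) * pixel_nm
  nx <- ceiling((hi[1] - x0) / pixel_nm)
  ny <- ceiling((hi[2] - y0) / pixel_nm)
  cx <- x0 + (seq_len(nx) - 0.5) * pixel_nm
  cy <- y0 + (seq_len(ny) - 0.5) * pixel_nm
  px <- rep(cx, each = ny)
  py <- rep(cy, times = nx)
  lab <- nearest_site(px, py, pts)
  vals <- vals_per_site[lab]
  # zero out pixels outside the clip polygon
  inside <- in_convex_polygon(px, py, clip)
  vals[!inside] <- 0
  img <- new_rendered_image(matrix(vals, ny, nx), pixel_nm, c(x0, y0),
                            "voronoi")
  attr(img, "cell_areas_nm2") <- areas
  attr(img, "clip_polygon") <- clip
  img
}

# Nearest site index for query points (blocked; ties -> lowest index).
nearest_site <- function(px, py, pts) {
  m <- length(px)
  lab <- integer(m)
  s2 <- pts[, 1]^2 + pts[, 2]^2
  block <- max(1L, floor(4e6 / nrow(pts)))
  for (s in seq(1L, m, by = block)) {
    e <- min(s + block - 1L, m)
    d2 <- -2 * cbind(px[s:e], py[s:e]) %*% t(pts)
    d2 <- sweep(d2, 2, s2, "+")
    lab[s:e] <- max.col(-d2, ties.method = "first")
  }
  lab
}

in_convex_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  ok <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    # CCW polygon: inside points have cross product >= 0
    ok <- ok & (e[1] * (py - poly[i, 2]) - e[2] * (px - poly[i, 1]) >= -tol)
  }
  ok
}
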