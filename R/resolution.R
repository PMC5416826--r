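# Structural resolution: Fourier ring correlation between half-dataset
# reconstructions, and multi-Gaussian line-profile FWHM fitting.

#' Split a localization table into two halves for FRC
#'
#' @param table a `loc_table` with at least 2 rows.
#' @param mode `"odd_even"` partitions deterministically by frame
#'   parity; `"random"` partitions rows 50/50 under `seed`. Merged
#'   multi-frame bursts are assigned wholly to one half by their first
#'   frame, which avoids splitting a single binding event across halves.
#' @param seed seed for `mode = "random"`.
#' @return list of two `loc_table`s whose union is the input and whose
#'   intersection is empty.
#' @export
split_halves <- function(table, mode = c("odd_even", "random"),
                         seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(table)
  if (n < 2L) stop_param("need at least 2 localizations to split")
  if (mode == "odd_even") {
    if (length(unique(table$frame)) < 2L)
      stop_param(paste("all localizations share one frame; odd/even",
                       "split is degenerate - use mode = 'random'"))
    sel <- table$frame %% 2 == 1
  } else {
    sel <- rep(FALSE, n)
    sel[with_seed(seed, sample.int(n, floor(n / 2)))] <- TRUE
  }
  list(table[sel, , drop = FALSE], table[!sel, , drop = FALSE])
}

#' Fourier ring correlation between two images
#'
#' Computes, for every ring of one-Fourier-pixel width,
#' \deqn{FRC(q) = \frac{\sum_{ring} Re[F_1 \bar F_2]}
#'   {\sqrt{\sum_{ring} |F_1|^2 \sum_{ring} |F_2|^2}}}
#' The DC ring is excluded; rings with zero denominator are undefined
#' (`NA`) and skipped by [estimate_resolution()]. Non-square images are
#' zero-padded to square.
#'
#' @param img1,img2 `rendered_image`s of identical shape and pixel size
#'   (typically histogram renderings of the two half datasets).
#' @param threshold stored on the curve for later resolution estimation
#'   (default 1/7, the standard SMLM FRC criterion).
#' @return object of class `frc_curve`: data frame columns `q_per_nm`,
#'   `frc`, `n_pixels`, plus attributes `pixel_size_nm` and `threshold`.
#' @export
compute_frc <- function(img1, img2, threshold = 1 / 7) {
  if (!identical(dim(img1$values), dim(img2$values)))
    stop_param("images differ in shape")
  if (!isTRUE(all.equal(img1$pixel_size_nm, img2$pixel_size_nm)))
    stop_param("images differ in pixel size")
  v1 <- img1$values; v2 <- img2$values
  n <- max(dim(v1))
  if (nrow(v1) != n || ncol(v1) != n) {
    pad <- function(v) {
      out <- matrix(0, n, n)
      out[seq_len(nrow(v)), seq_len(ncol(v))] <- v
      out
    }
    v1 <- pad(v1); v2 <- pad(v2)
  }
  f1 <- fft(v1); f2 <- fft(v2)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n   # cycles per pixel
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  ring <- round(sqrt(kx^2 + ky^2) * n)
  maxr <- n %/% 2
  sel <- ring >= 1 & ring <= maxr
  rf <- factor(ring[sel], levels = seq_len(maxr))
  num <- tapply(Re(f1[sel] * Conj(f2[sel])), rf, sum)
  d1 <- tapply(Mod(f1[sel])^2, rf, sum)
  d2 <- tapply(Mod(f2[sel])^2, rf, sum)
  npix <- tapply(rep(1, sum(sel)), rf, sum)
  den <- sqrt(d1 * d2)
  frc <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  curve <- data.frame(q_per_nm = seq_len(maxr) / (n * img1$pixel_size_nm),
                      frc = as.numeric(frc),
                      n_pixels = as.integer(ifelse(is.na(npix), 0, npix)))
  attr(curve, "pixel_size_nm") <- img1$pixel_size_nm
  attr(curve, "threshold") <- threshold
  class(curve) <- c("frc_curve", "data.frame")
  curve
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("FRC curve: %d rings, threshold %.4f\n", nrow(x),
              attr(x, "threshold")))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, ...) {
  plot(x$q_per_nm, x$frc, type = "l", xlab = "spatial frequency (1/nm)",
       ylab = "FRC", ylim = c(min(0, min(x$frc, na.rm = TRUE)), 1), ...)
  abline(h = attr(x, "threshold"), lty = 2, col = 2)
  invisible(x)
}

#' Estimate image resolution from an FRC curve
#'
#' Fits a least-squares polynomial to the defined rings of the curve and
#' reports `1 / q*` at the smallest frequency where the fit descends
#' through the threshold. If the polynomial never crosses, the raw
#' curve's first downward crossing (linear interpolation) is used; if
#' neither crosses, the curve is "unresolved" at the frequencies
#' examined.
#'
#' @param curve an `frc_curve`.
#' @param threshold correlation threshold (default 1/7).
#' @param fit_order polynomial order for smoothing (default 8).
#' @return object of class `frc_resolution`: list with `resolution_nm`
#'   (`NA` if unresolved), `q_cross_per_nm`, `method` (`"fit"`, `"raw"`
#'   or `"unresolved"`), `threshold`, `fit_order` and `min_q_examined`.
#' @export
estimate_resolution <- function(curve, threshold = 1 / 7, fit_order = 8) {
  ok <- is.finite(curve$frc)
  if (!any(ok)) stop_param("FRC curve has no defined rings")
  q <- curve$q_per_nm[ok]; y <- curve$frc[ok]
  if (length(q) < fit_order + 2)
    stop_param("need at least fit_order + 2 defined rings")
  qs <- q / max(q)   # scale to [0, 1] for numerical conditioning
  fit <- lm(y ~ poly(qs, degree = fit_order, raw = TRUE))
  grid_q <- seq(min(q), max(q), length.out = 4000L)
  yy <- predict(fit, newdata = data.frame(qs = grid_q / max(q)))

  first_down_crossing <- function(xv, yv) {
    below <- yv < threshold
    idx <- which(!below[-length(below)] & below[-1])
    if (length(idx) == 0L) return(NA_real_)
    i <- idx[1]
    t <- (threshold - yv[i]) / (yv[i + 1] - yv[i])
    xv[i] + t * (xv[i + 1] - xv[i])
  }
  qcross <- first_down_crossing(grid_q, yy)
  method <- "fit"
  if (is.na(qcross)) {
    qcross <- first_down_crossing(q, y)
    method <- "raw"
  }
  if (is.na(qcross)) {
    # curve starts below threshold, or never descends through it
    if (y[1] < threshold) { qcross <- q[1]; method <- "raw" }
    else method <- "unresolved"
  }
  structure(list(resolution_nm = if (method == "unresolved") NA_real_
                                 else 1 / qcross,
                 q_cross_per_nm = if (method == "unresolved") NA_real_
                                  else qcross,
                 method = method, threshold = threshold,
                 fit_order = fit_order, min_q_examined = min(q)),
            class = "frc_resolution")
}

#' @export
print.frc_resolution <- function(x, ...) {
  if (x$method == "unresolved")
    cat(sprintf("FRC resolution: unresolved above %.3g nm (no crossing)\n",
                1 / x$min_q_examined))
  else
    cat(sprintf("FRC resolution: %.1f nm (threshold %.4f, %s crossing)\n",
                x$resolution_nm, x$threshold, x$method))
  invisible(x)
}

#' FRC resolution of a localization dataset, end to end
#'
#' Convenience wrapper: split the table, render the two half-dataset
#' histogram images on a common extent, compute the FRC curve, and
#' estimate the threshold-crossing resolution.
#'
#' @param table a `loc_table`.
#' @param render_pixel_nm pixel size of the half-dataset renderings
#'   (default 10 nm).
#' @param split `"odd_even"` or `"random"`.
#' @param threshold,fit_order passed to [estimate_resolution()].
#' @param seed seed for a random split.
#' @return list with `resolution` (an `frc_resolution`) and `curve` (an
#'   `frc_curve`).
#' @export
frc_resolution <- function(table, render_pixel_nm = 10,
                           split = "odd_even", threshold = 1 / 7,
                           fit_order = 8, seed = NULL) {
  halves <- split_halves(table, mode = split, seed = seed)
  ext <- c(0, (floor(max(table$x_nm) / render_pixel_nm) + 1) * render_pixel_nm,
           0, (floor(max(table$y_nm) / render_pixel_nm) + 1) * render_pixel_nm)
  i1 <- render_histogram(halves[[1]], render_pixel_nm, extent_nm = ext)
  i2 <- render_histogram(halves[[2]], render_pixel_nm, extent_nm = ext)
  curve <- compute_frc(i1, i2, threshold = threshold)
  res <- estimate_resolution(curve, threshold = threshold,
                             fit_order = fit_order)
  list(resolution = res, curve = curve)
}

# Bilinear interpolation of image values at (x, y) nm positions.
bilinear_at <- function(img, x_nm, y_nm) {
  a <- img$pixel_size_nm
  gx <- (x_nm - img$origin_nm[1]) / a + 0.5   # fractional column index
  gy <- (y_nm - img$origin_nm[2]) / a + 0.5
  v <- img$values
  nr <- nrow(v); nc <- ncol(v)
  c0 <- pmin(pmax(floor(gx), 1), nc - 1)
  r0 <- pmin(pmax(floor(gy), 1), nr - 1)
  tx <- pmin(pmax(gx - c0, 0), 1)
  ty <- pmin(pmax(gy - r0, 0), 1)
  v00 <- v[cbind(r0, c0)]; v01 <- v[cbind(r0, c0 + 1)]
  v10 <- v[cbind(r0 + 1, c0)]; v11 <- v[cbind(r0 + 1, c0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
}

#' Multi-Gaussian FWHM fit of an intensity profile across an image
#'
#' Samples the image along a line segment (bilinear interpolation, step
#' half the image pixel, optionally averaged across a perpendicular
#' width), then fits a sum of `n_components` Gaussians plus a constant
#' baseline by Levenberg-Marquardt least squares. Initial centres are
#' the `n_components` largest local maxima of the profile. The FWHM of
#' each component is `2 sqrt(2 ln 2) x sigma ~= 2.3548 sigma`.
#'
#' @param image a `rendered_image`.
#' @param p0,p1 numeric length 2: segment endpoints `(x, y)` in nm.
#' @param n_components number of Gaussian components (>= 1).
#' @param line_width_nm averaging width perpendicular to the line.
#' @return object of class `profile_fit`: list with `positions_nm`,
#'   `values`, `fitted`, `components` (data frame `center_nm`,
#'   `sigma_nm`, `amplitude`, `fwhm_nm`, sorted by centre), `baseline`
#'   and `residual_norm`.
#' @export
profile_fwhm <- function(image, p0, p1, n_components = 1,
                         line_width_nm = 0) {
  if (n_components < 1) stop_param("`n_components` must be >= 1")
  a <- image$pixel_size_nm
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop_param("degenerate profile segment")
  step <- a / 2
  tt <- seq(0, len, by = step)
  ux <- (p1[1] - p0[1]) / len; uy <- (p1[2] - p0[2]) / len
  px <- p0[1] + tt * ux; py <- p0[2] + tt * uy
  offs <- if (line_width_nm > 0)
    seq(-line_width_nm / 2, line_width_nm / 2, by = step) else 0
  prof <- rowMeans(vapply(offs, function(o)
    bilinear_at(image, px - o * uy, py + o * ux), numeric(length(tt))))

  # initial centres: largest strict local maxima of the profile
  m <- length(prof)
  is_max <- c(FALSE, prof[2:(m - 1)] > prof[1:(m - 2)] &
                     prof[2:(m - 1)] >= prof[3:m], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < n_components)
    stop_param("found only %d local maxima but %d components requested",
               length(peaks), n_components)
  peaks <- peaks[order(prof[peaks], decreasing = TRUE)][seq_len(n_components)]

  base0 <- min(prof)
  start <- list(c0 = base0)
  form <- "y ~ c0"
  dat <- data.frame(t = tt, y = prof)
  for (i in seq_len(n_components)) {
    form <- paste0(form, sprintf(
      " + A%d * exp(-(t - mu%d)^2 / (2 * s%d^2))", i, i, i))
    start[[paste0("A", i)]] <- max(prof[peaks[i]] - base0, 1e-6)
    start[[paste0("mu", i)]] <- tt[peaks[i]]
    start[[paste0("s", i)]] <- 2 * a
  }
  fit <- minpack.lm::nlsLM(stats::as.formula(form), data = dat,
                           start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400))
  cf <- coef(fit)
  comp <- data.frame(center_nm = cf[paste0("mu", seq_len(n_components))],
                     sigma_nm = abs(cf[paste0("s", seq_len(n_components))]),
                     amplitude = cf[paste0("A", seq_len(n_components))])
  comp$fwhm_nm <- 2 * sqrt(2 * log(2)) * comp$sigma_nm
  comp <- comp[order(comp$center_nm), ]
  rownames(comp) <- NULL
  structure(list(positions_nm = tt, values = prof,
                 fitted = predict(fit), components = comp,
                 baseline = unname(cf["c0"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2))),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("Profile fit: %d Gaussian component(s)\n",
              nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' @export
plot.profile_fit <- function(x, ...) {
  plot(x$positions_nm, x$values, pch = 16, cex = 0.6,
       xlab = "position (nm)", ylab = "intensity", ...)
  lines(x$positions_nm, x$fitted, col = 2, lwd = 2)
  invisible(x)
}
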