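# Single-molecule localization: background estimation, peak detection at
# 3x noise SD above background, centroid fitting, Thompson-style
# precision, PSF-diameter filtering and consecutive-frame merging.

#' Construct a localization table
#'
#' The central record of the pipeline: one row per single-molecule
#' signal. Used internally; end users normally obtain tables from
#' [localize_movie()] or [read_localizations()].
#'
#' @param df data frame with columns `frame`, `x_nm`, `y_nm`,
#'   `sigma_nm`, `photons`, `background`, `precision_nm`, `n_merged`.
#' @param pixel_size_nm camera pixel size, nm.
#' @param source free-text provenance string.
#' @return object of class `loc_table` (a data frame).
#' @export
loc_table <- function(df, pixel_size_nm, source = "") {
  need <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons", "background",
            "precision_nm", "n_merged")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_param("missing localization column(s): %s",
               paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  attr(df, "pixel_size_nm") <- pixel_size_nm
  attr(df, "source") <- source
  class(df) <- c("loc_table", "data.frame")
  df
}

empty_loc_table <- function(pixel_size_nm, source = "") {
  loc_table(data.frame(frame = integer(0), x_nm = numeric(0),
                       y_nm = numeric(0), sigma_nm = numeric(0),
                       photons = numeric(0), background = numeric(0),
                       precision_nm = numeric(0), n_merged = integer(0)),
            pixel_size_nm, source)
}

#' @export
`[.loc_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "pixel_size_nm") <- attr(x, "pixel_size_nm")
    attr(out, "source") <- attr(x, "source")
    class(out) <- class(x)
  }
  out
}

#' Mean localization precision of a table
#'
#' Recomputed from the rows on every call (never cached) so it can never
#' go stale after filtering or merging.
#'
#' @param table a `loc_table`.
#' @return arithmetic mean of `precision_nm`, `NA` for an empty table.
#' @export
mean_precision <- function(table) {
  if (nrow(table) == 0L) return(NA_real_)
  mean(table$precision_nm)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf(paste0("Localization table: %d localizations, %d frames, ",
                     "mean precision %.2f nm (pixel %.0f nm)\n"),
              nrow(x), length(unique(x$frame)), mean_precision(x),
              attr(x, "pixel_size_nm")))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Estimate smooth background and noise SD of a camera frame
#'
#' Background is a per-frame spatial median filter (robust to the sparse
#' emitters themselves); the noise standard deviation is the scaled
#' median absolute deviation (MAD, consistent for Gaussian noise) of the
#' residuals. Both are in camera counts.
#'
#' @param frame numeric matrix (one movie frame, counts).
#' @param radius median filter radius in pixels (window is
#'   `2 * radius + 1` square; default 5, i.e. 11 x 11).
#' @return list with `background` (matrix) and `noise_sd` (scalar).
#' @export
estimate_background_noise <- function(frame, radius = 5L) {
  if (length(frame) == 0L) stop_param("empty frame")
  storage.mode(frame) <- "double"
  hi <- max(frame)
  bg <- if (hi <= 0) {
    frame * 0
  } else {
    # EBImage's constant-time median filter works on [0, 1] data
    EBImage::medianFilter(frame / hi, radius) * hi
  }
  res <- frame - bg
  noise_sd <- mad(res, center = 0)
  list(background = bg, noise_sd = noise_sd)
}

#' Detect candidate single-molecule peaks in a frame
#'
#' A pixel is a candidate iff its value exceeds the local background by
#' more than `k` noise standard deviations and it is a strict local
#' maximum in its 8-neighbourhood. Candidates closer than one ROI width
#' are reduced to the brighter one.
#'
#' @param frame numeric matrix, counts.
#' @param background background matrix from
#'   [estimate_background_noise()].
#' @param noise_sd noise standard deviation, counts.
#' @param k threshold multiplier (default 3, the fBALM detection rule).
#' @param roi_halfwidth fitting ROI half-width in pixels (sets the
#'   minimum candidate separation `2 * roi_halfwidth + 1`).
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
detect_peaks <- function(frame, background, noise_sd, k = 3,
                         roi_halfwidth = 3L) {
  if (noise_sd < 0) stop_param("`noise_sd` must be >= 0")
  nr <- nrow(frame); nc <- ncol(frame)
  above <- frame > background + k * noise_sd
  if (!any(above)) return(cbind(row = integer(0), col = integer(0)))
  # strict 8-neighbourhood local maximum (border pixels excluded)
  ok <- matrix(FALSE, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- frame[ri, ci]
  ok[ri, ci] <- above[ri, ci] &
    ctr > frame[ri - 1, ci] & ctr > frame[ri + 1, ci] &
    ctr > frame[ri, ci - 1] & ctr > frame[ri, ci + 1] &
    ctr > frame[ri - 1, ci - 1] & ctr > frame[ri - 1, ci + 1] &
    ctr > frame[ri + 1, ci - 1] & ctr > frame[ri + 1, ci + 1]
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) <= 1L) {
    colnames(cand) <- c("row", "col")
    return(cand)
  }
  # minimum separation: brighter candidate wins
  vals <- frame[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  minsep <- 2 * roi_halfwidth + 1
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    prior <- cand[seq_len(i - 1L)[keep[seq_len(i - 1L)]], , drop = FALSE]
    d2 <- (prior[, 1] - cand[i, 1])^2 + (prior[, 2] - cand[i, 2])^2
    if (any(d2 < minsep^2)) keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  colnames(cand) <- c("row", "col")
  cand
}

#' Thompson-style localization precision
#'
#' Standard error of a fitted emitter position for a centroid-class
#' fitter:
#' \deqn{\sigma_{loc}^2 = \frac{\sigma^2 + a^2/12}{N}
#'   + \frac{8 \pi \sigma^4 b^2}{a^2 N^2}}
#' with \eqn{\sigma} the fitted PSF SD (nm), \eqn{a} the pixel size
#' (nm), \eqn{N} the signal photons and \eqn{b} the background SD in
#' photons per pixel.
#'
#' @param sigma_nm fitted PSF Gaussian SD, nm.
#' @param photons estimated signal photons (> 0).
#' @param background background standard deviation, photons per pixel.
#' @param pixel_size_nm camera pixel size, nm.
#' @return localization precision in nm (vectorized).
#' @export
estimate_precision <- function(sigma_nm, photons, background,
                               pixel_size_nm) {
  if (any(photons <= 0)) stop_param("`photons` must be > 0")
  sqrt((sigma_nm^2 + pixel_size_nm^2 / 12) / photons +
         8 * pi * sigma_nm^4 * background^2 /
         (pixel_size_nm^2 * photons^2))
}

# Centre-of-gravity fit of one candidate. Returns NULL when the ROI
# leaves the frame or has no positive mass after background subtraction.
fit_candidate <- function(frame, background, cand_row, cand_col,
                          roi_halfwidth, pixel_size_nm, gain, noise_sd) {
  h <- roi_halfwidth
  nr <- nrow(frame); nc <- ncol(frame)
  if (cand_row - h < 1L || cand_row + h > nr ||
      cand_col - h < 1L || cand_col + h > nc)
    return(NULL)
  ri <- (cand_row - h):(cand_row + h)
  ci <- (cand_col - h):(cand_col + h)
  sub <- frame[ri, ci] - background[ri, ci]
  sub[sub < 0] <- 0
  s <- sum(sub)
  if (s <= 0) return(NULL)
  # pixel centres in nm: (index - 0.5) * a
  rw <- rowSums(sub); cw <- colSums(sub)
  yc <- sum((ri - 0.5) * rw) / s
  xc <- sum((ci - 0.5) * cw) / s
  # intensity-weighted radial SD, converted to a per-axis Gaussian sigma
  dy <- (ri - 0.5) - yc
  dx <- (ci - 0.5) - xc
  r2 <- outer(dy^2, rep(1, length(ci))) + outer(rep(1, length(ri)), dx^2)
  sigma_px <- sqrt(0.5 * sum(sub * r2) / s)
  photons <- s / gain
  a <- pixel_size_nm
  c(x_nm = xc * a, y_nm = yc * a, sigma_nm = sigma_px * a,
    photons = photons, background = noise_sd / gain)
}

#' Fit a single localization by background-subtracted centre of gravity
#'
#' Subtracts the background map over a square ROI, clamps negative
#' pixels to zero, and computes the intensity-weighted centroid (sub-
#' pixel position), total signal photons (ROI sum / gain) and the
#' intensity-weighted radial SD as the fitted PSF sigma.
#'
#' @param frame numeric matrix, counts.
#' @param background background matrix, counts.
#' @param noise_sd noise SD, counts.
#' @param cand length-2 integer (row, col) candidate pixel.
#' @param roi_halfwidth ROI half-width, pixels (default 3: 7 x 7 ROI).
#' @param pixel_size_nm camera pixel size, nm.
#' @param gain camera gain, counts per photon.
#' @return one-row `loc_table` (frame set to `NA`), or an empty table if
#'   the candidate is dropped (ROI outside frame or nonpositive mass).
#' @export
fit_localization <- function(frame, background, noise_sd, cand,
                             roi_halfwidth = 3L, pixel_size_nm = 100,
                             gain = 1) {
  v <- fit_candidate(frame, background, cand[1], cand[2], roi_halfwidth,
                     pixel_size_nm, gain, noise_sd)
  if (is.null(v)) return(empty_loc_table(pixel_size_nm))
  prec <- estimate_precision(v[["sigma_nm"]], v[["photons"]],
                             v[["background"]], pixel_size_nm)
  loc_table(data.frame(frame = NA_integer_, x_nm = v[["x_nm"]],
                       y_nm = v[["y_nm"]], sigma_nm = v[["sigma_nm"]],
                       photons = v[["photons"]],
                       background = v[["background"]],
                       precision_nm = prec, n_merged = 1L),
            pixel_size_nm)
}

#' Filter out the broadest localizations by fitted PSF diameter
#'
#' Implements the fBALM diameter filter: the broadest ~30% of signals
#' (by fitted PSF sigma) are removed. The kept set is
#' `sigma_nm <= q`, where `q` is the `ceiling((1 - remove_fraction) * n)`-th
#' smallest sigma; ties at the threshold are all kept, so with distinct
#' sigmas exactly `ceiling(0.7 n)` rows survive at the default fraction.
#'
#' @param table a `loc_table`.
#' @param remove_fraction fraction of broadest signals to remove
#'   (default 0.30).
#' @param verbose log the retention fraction.
#' @return the filtered `loc_table`.
#' @export
filter_by_diameter <- function(table, remove_fraction = 0.30,
                               verbose = FALSE) {
  if (remove_fraction < 0 || remove_fraction >= 1)
    stop_param("`remove_fraction` must be in [0, 1)")
  n <- nrow(table)
  if (n == 0L || remove_fraction == 0) return(table)
  kth <- ceiling((1 - remove_fraction) * n)
  thr <- sort(table$sigma_nm, partial = kth)[kth]
  out <- table[table$sigma_nm <= thr, , drop = FALSE]
  log_stage(verbose, "diameter filter: kept %d/%d (%.1f%%)",
            nrow(out), n, 100 * nrow(out) / n)
  out
}

#' Merge localizations of the same emitter across consecutive frames
#'
#' A transiently bound dye that stays on for several frames produces one
#' localization per frame; these are combined into a single signal.
#' Localizations in strictly consecutive frames closer than
#' `2 x mean localization precision` (recomputed from the table) are
#' linked greedily (each row links to at most one partner in the next
#' frame; conflicts resolved by smallest distance); maximal chains
#' collapse to one row with photon-weighted mean position, summed
#' photons, the first frame index, `n_merged` equal to the number of raw
#' detections combined, and precision recomputed from the summed
#' photons.
#'
#' @param table a `loc_table`.
#' @param radius_nm optional explicit linking radius; default
#'   `2 * mean_precision(table)`.
#' @param verbose log the merge summary.
#' @return the merged `loc_table`.
#' @export
merge_consecutive <- function(table, radius_nm = NULL, verbose = FALSE) {
  n <- nrow(table)
  if (n <= 1L) return(table)
  a <- attr(table, "pixel_size_nm")
  if (is.null(radius_nm)) radius_nm <- 2 * mean_precision(table)
  ord <- order(table$frame, table$x_nm, table$y_nm)
  tb <- as.data.frame(table)[ord, ]
  nxt <- rep(NA_integer_, n)   # index (in tb) of the linked partner
  prv <- rep(NA_integer_, n)
  frames <- sort(unique(tb$frame))
  by_frame <- split(seq_len(n), tb$frame)
  for (fi in seq_len(length(frames) - 1L)) {
    if (frames[fi + 1L] != frames[fi] + 1L) next
    i1 <- by_frame[[as.character(frames[fi])]]
    i2 <- by_frame[[as.character(frames[fi + 1L])]]
    d2 <- outer(tb$x_nm[i1], tb$x_nm[i2], "-")^2 +
          outer(tb$y_nm[i1], tb$y_nm[i2], "-")^2
    cand <- which(d2 <= radius_nm^2, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    cand <- cand[order(d2[cand]), , drop = FALSE]
    used1 <- logical(length(i1)); used2 <- logical(length(i2))
    for (r in seq_len(nrow(cand))) {
      p <- cand[r, 1]; q <- cand[r, 2]
      if (used1[p] || used2[q]) next
      used1[p] <- TRUE; used2[q] <- TRUE
      nxt[i1[p]] <- i2[q]
      prv[i2[q]] <- i1[p]
    }
  }
  # collapse chains starting at rows with no predecessor
  heads <- which(is.na(prv))
  out <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    chain <- heads[h]
    while (!is.na(nxt[chain[length(chain)]]))
      chain <- c(chain, nxt[chain[length(chain)]])
    rows <- tb[chain, ]
    w <- rows$photons
    tot <- sum(w)
    sigma <- sum(w * rows$sigma_nm) / tot
    bg <- mean(rows$background)
    out[[h]] <- data.frame(
      frame = rows$frame[1],
      x_nm = sum(w * rows$x_nm) / tot,
      y_nm = sum(w * rows$y_nm) / tot,
      sigma_nm = sigma, photons = tot, background = bg,
      precision_nm = estimate_precision(sigma, tot, bg, a),
      n_merged = sum(rows$n_merged))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$x_nm, res$y_nm), ]
  rownames(res) <- NULL
  log_stage(verbose, "merge: %d -> %d localizations (radius %.2f nm)",
            n, nrow(res), radius_nm)
  loc_table(res, a, source = attr(table, "source"))
}

#' Localization configuration
#'
#' @param threshold_k detection threshold in noise SDs above background.
#' @param roi_halfwidth fitting ROI half-width, pixels.
#' @param bg_radius background median-filter radius, pixels.
#' @param smooth_sigma_px Gaussian matched-filter sigma (pixels) applied
#'   to the background-subtracted frame before peak detection; the
#'   threshold is `k` noise SDs of the *filtered* image, which
#'   suppresses single-pixel shot-noise outliers that a raw-pixel
#'   threshold cannot separate from genuine peaks. Set 0 to detect on
#'   raw pixels. Default 1.3 (a 130 nm PSF at 100 nm pixels).
#' @param filter_fraction fraction of broadest signals removed.
#' @param merge logical; combine consecutive-frame localizations.
#' @param merge_radius_nm optional explicit merge radius (default
#'   `2 x` mean precision).
#' @return a named list of class `localize_config`.
#' @export
localize_config <- function(threshold_k = 3, roi_halfwidth = 3L,
                            bg_radius = 5L, smooth_sigma_px = 1.3,
                            filter_fraction = 0.30,
                            merge = TRUE, merge_radius_nm = NULL) {
  structure(list(threshold_k = threshold_k,
                 roi_halfwidth = as.integer(roi_halfwidth),
                 bg_radius = as.integer(bg_radius),
                 smooth_sigma_px = smooth_sigma_px,
                 filter_fraction = filter_fraction, merge = merge,
                 merge_radius_nm = merge_radius_nm),
            class = "localize_config")
}

# Localize one frame; returns a plain data.frame (possibly 0 rows).
localize_frame <- function(frame, config, pixel_size_nm, gain,
                           frame_index) {
  bn <- estimate_background_noise(frame, config$bg_radius)
  if (config$smooth_sigma_px > 0) {
    det <- EBImage::gblur(frame - bn$background, config$smooth_sigma_px)
    det_noise <- mad(det, center = 0)
    cand <- detect_peaks(det, matrix(0, nrow(det), ncol(det)), det_noise,
                         k = config$threshold_k,
                         roi_halfwidth = config$roi_halfwidth)
    # a genuine peak must also satisfy the raw-pixel rule: counts above
    # background by more than k raw-noise SDs
    if (nrow(cand) > 0L) {
      ok <- frame[cand] > bn$background[cand] +
        config$threshold_k * bn$noise_sd
      cand <- cand[ok, , drop = FALSE]
    }
  } else {
    cand <- detect_peaks(frame, bn$background, bn$noise_sd,
                         k = config$threshold_k,
                         roi_halfwidth = config$roi_halfwidth)
  }
  if (nrow(cand) == 0L) return(NULL)
  fits <- lapply(seq_len(nrow(cand)), function(i)
    fit_candidate(frame, bn$background, cand[i, 1], cand[i, 2],
                  config$roi_halfwidth, pixel_size_nm, gain, bn$noise_sd))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) return(NULL)
  m <- do.call(rbind, fits)
  # the detection rule applied to the fitted signal: its peak amplitude
  # (photons over the 2D Gaussian footprint, in counts) must exceed k
  # noise SDs; discards shot-noise outliers that have no PSF shape
  amp <- m[, "photons"] * gain / (2 * pi * (m[, "sigma_nm"] /
                                              pixel_size_nm)^2)
  m <- m[amp > config$threshold_k * bn$noise_sd, , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  data.frame(frame = frame_index, x_nm = m[, "x_nm"], y_nm = m[, "y_nm"],
             sigma_nm = m[, "sigma_nm"], photons = m[, "photons"],
             background = m[, "background"],
             precision_nm = estimate_precision(m[, "sigma_nm"],
                                               m[, "photons"],
                                               m[, "background"],
                                               pixel_size_nm),
             n_merged = 1L)
}

#' Localize every frame of a movie
#'
#' The per-frame pipeline (background estimation, peak detection at
#' `k` noise SDs above background, centre-of-gravity fitting, precision
#' estimation) followed by the PSF-diameter filter and consecutive-frame
#' merging. Fully deterministic: rerunning on the same movie and
#' configuration yields a bit-identical table.
#'
#' @param stack a `movie_stack` from [simulate_movie()] or
#'   [read_movie()].
#' @param config a [localize_config()].
#' @param verbose log per-stage record counts.
#' @return a `loc_table`.
#' @export
localize_movie <- function(stack, config = localize_config(),
                           verbose = FALSE) {
  stopifnot(inherits(stack, "movie_stack"))
  p <- stack$params
  nf <- dim(stack$data)[3]
  per_frame <- vector("list", nf)
  for (f in seq_len(nf))
    per_frame[[f]] <- localize_frame(stack$data[, , f], config,
                                     p$pixel_size_nm, p$camera_gain, f)
  raw <- do.call(rbind, per_frame)
  if (is.null(raw) || nrow(raw) == 0L) {
    log_stage(verbose, "localize: no signals detected")
    return(empty_loc_table(p$pixel_size_nm, source = "localize_movie"))
  }
  tab <- loc_table(raw, p$pixel_size_nm, source = "localize_movie")
  log_stage(verbose, "detected: %d raw localizations in %d frames",
            nrow(tab), nf)
  tab <- filter_by_diameter(tab, config$filter_fraction, verbose = verbose)
  if (isTRUE(config$merge))
    tab <- merge_consecutive(tab, radius_nm = config$merge_radius_nm,
                             verbose = verbose)
  rownames(tab) <- NULL
  tab
}
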