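# Simulation of chromatin ground truths, blinking fBALM movies with a
# full camera model, and 3D confocal foci stacks.

#' Structure parameters for a simulated chromatin ground truth
#'
#' Chromatin in fBALM reconstructions of cardiomyocyte nuclei appears as
#' a "spider's web": dense signal clusters of 100--400 nm diameter at the
#' intersections of a filamentous network, separated by DNA-sparse voids
#' of similar size. The generator emulates this morphology with Gaussian
#' site blobs at cluster centres connected by jittered backbone
#' polylines, all confined to an elliptical nuclear boundary.
#'
#' @param nucleus_center numeric length 2; ellipse centre in nm.
#' @param nucleus_semiaxes numeric length 2; ellipse semi-axes in nm.
#' @param n_clusters number of chromatin clusters (>= 1).
#' @param n_sites total number of dye-binding sites to place (>= 1).
#' @param diameter_range_nm numeric length 2; cluster diameters are drawn
#'   uniformly from this range. Default `c(100, 400)` nm, the cluster
#'   size range observed in fBALM images of HL-1 nuclei.
#' @param backbone_fraction fraction of sites placed along backbone
#'   polylines rather than in cluster blobs (ignored when the structure
#'   has no backbone, i.e. a single cluster).
#' @param backbone_sd_nm transverse Gaussian jitter of backbone sites, nm.
#' @return an object of class `chromatin_params`.
#' @seealso [generate_chromatin_structure()]
#' @export
chromatin_params <- function(nucleus_center = c(6400, 6400),
                             nucleus_semiaxes = c(5000, 4000),
                             n_clusters = 60,
                             n_sites = 20000,
                             diameter_range_nm = c(100, 400),
                             backbone_fraction = 0.3,
                             backbone_sd_nm = 25) {
  if (any(!is.finite(nucleus_semiaxes)) || any(nucleus_semiaxes <= 0))
    stop_param("degenerate nucleus: semi-axes must be > 0")
  if (n_clusters < 1) stop_param("`n_clusters` must be >= 1")
  if (n_sites < 1) stop_param("`n_sites` must be >= 1")
  if (length(diameter_range_nm) != 2L ||
      diameter_range_nm[1] > diameter_range_nm[2] ||
      diameter_range_nm[1] <= 0)
    stop_param("`diameter_range_nm` must be an increasing positive pair")
  if (backbone_fraction < 0 || backbone_fraction >= 1)
    stop_param("`backbone_fraction` must be in [0, 1)")
  structure(list(nucleus_center = as.numeric(nucleus_center),
                 nucleus_semiaxes = as.numeric(nucleus_semiaxes),
                 n_clusters = as.integer(n_clusters),
                 n_sites = as.integer(n_sites),
                 diameter_range_nm = as.numeric(diameter_range_nm),
                 backbone_fraction = backbone_fraction,
                 backbone_sd_nm = backbone_sd_nm),
            class = "chromatin_params")
}

inside_ellipse <- function(xy, center, semiaxes) {
  ((xy[, 1] - center[1]) / semiaxes[1])^2 +
    ((xy[, 2] - center[2]) / semiaxes[2])^2 <= 1
}

# Uniform points in an ellipse via the unit-disc transform.
runif_ellipse <- function(n, center, semiaxes, shrink = 1) {
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + shrink * semiaxes[1] * r * cos(th),
        center[2] + shrink * semiaxes[2] * r * sin(th))
}

#' Generate a clustered "spider-web" chromatin ground truth
#'
#' Places cluster centres uniformly inside the nuclear ellipse (with a
#' margin so blobs stay inside), draws per-cluster diameters uniformly
#' from the configured range, connects each centre to its (up to) three
#' nearest neighbours by jittered polylines, and distributes binding
#' sites between truncated Gaussian blobs at the centres and the backbone
#' polylines. Every site is guaranteed to lie inside the nuclear
#' boundary and within half a diameter of its cluster centre (blob
#' sites); the requested site count is met exactly.
#'
#' A cluster's "diameter" is interpreted as the full extent of its blob:
#' sites are drawn from an isotropic Gaussian with `sd = diameter / 4`,
#' truncated at radius `diameter / 2`.
#'
#' @param params a [chromatin_params()] object.
#' @param seed integer; fixes the structure exactly.
#' @return an object of class `chromatin_gt` with elements
#'   `site_positions` (n x 2 matrix, nm), `cluster_centers`,
#'   `cluster_diameters_nm`, `nucleus` (list `center`, `semiaxes`) and
#'   `backbone_paths` (list of polyline matrices).
#' @export
generate_chromatin_structure <- function(params = chromatin_params(),
                                         seed = NULL) {
  stopifnot(inherits(params, "chromatin_params"))
  with_seed(seed, {
    ctr <- params$nucleus_center
    ax <- params$nucleus_semiaxes
    drange <- params$diameter_range_nm
    ncl <- params$n_clusters
    diam <- runif(ncl, drange[1], drange[2])
    # keep whole blobs inside: margin of half the largest possible diameter
    shrink <- max(0.1, 1 - (drange[2] / 2) / min(ax))
    centers <- runif_ellipse(ncl, ctr, ax, shrink = shrink)

    # backbone: connect each centre to its <= 3 nearest neighbours
    paths <- list()
    if (ncl > 1) {
      dmat <- as.matrix(stats::dist(centers))
      diag(dmat) <- Inf
      seen <- matrix(FALSE, ncl, ncl)
      for (i in seq_len(ncl)) {
        nb <- order(dmat[i, ])[seq_len(min(3L, ncl - 1L))]
        for (j in nb) {
          a <- min(i, j); b <- max(i, j)
          if (seen[a, b]) next
          seen[a, b] <- TRUE
          # 4-segment polyline with mid-point jitter for a curved look
          tt <- seq(0, 1, length.out = 5)
          pl <- cbind(centers[i, 1] + tt * (centers[j, 1] - centers[i, 1]),
                      centers[i, 2] + tt * (centers[j, 2] - centers[i, 2]))
          jit <- matrix(rnorm(6, 0, 40), 3, 2)
          pl[2:4, ] <- pl[2:4, ] + jit
          paths[[length(paths) + 1L]] <- pl
        }
      }
    }

    n <- params$n_sites
    n_bb <- if (length(paths) > 0L) round(params$backbone_fraction * n) else 0L
    n_blob <- n - n_bb

    sample_blob <- function(m) {
      cl <- sample.int(ncl, m, replace = TRUE)
      out <- matrix(NA_real_, m, 2)
      todo <- seq_len(m)
      while (length(todo) > 0L) {
        k <- length(todo)
        sdv <- diam[cl[todo]] / 4
        cand <- cbind(centers[cl[todo], 1] + rnorm(k, 0, sdv),
                      centers[cl[todo], 2] + rnorm(k, 0, sdv))
        r <- sqrt(rowSums((cand - centers[cl[todo], , drop = FALSE])^2))
        ok <- r <= diam[cl[todo]] / 2 & inside_ellipse(cand, ctr, ax)
        out[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
      out
    }
    sample_backbone <- function(m) {
      out <- matrix(NA_real_, m, 2)
      todo <- seq_len(m)
      while (length(todo) > 0L) {
        k <- length(todo)
        pid <- sample.int(length(paths), k, replace = TRUE)
        cand <- t(vapply(pid, function(p) {
          pl <- paths[[p]]
          s <- sample.int(nrow(pl) - 1L, 1L)
          u <- runif(1)
          pl[s, ] + u * (pl[s + 1L, ] - pl[s, ])
        }, numeric(2)))
        cand <- cand + matrix(rnorm(2 * k, 0, params$backbone_sd_nm), k, 2)
        ok <- inside_ellipse(cand, ctr, ax)
        out[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
      out
    }

    sites <- rbind(if (n_blob > 0L) sample_blob(n_blob),
                   if (n_bb > 0L) sample_backbone(n_bb))
    colnames(sites) <- c("x_nm", "y_nm")
    structure(list(site_positions = sites,
                   cluster_centers = centers,
                   cluster_diameters_nm = diam,
                   nucleus = list(center = ctr, semiaxes = ax),
                   backbone_paths = paths,
                   params = params),
              class = "chromatin_gt")
  })
}

#' @export
print.chromatin_gt <- function(x, ...) {
  cat(sprintf(paste0("Chromatin ground truth: %d sites, %d clusters ",
                     "(diameters %.0f-%.0f nm), %d backbone paths\n"),
              nrow(x$site_positions), length(x$cluster_diameters_nm),
              min(x$cluster_diameters_nm), max(x$cluster_diameters_nm),
              length(x$backbone_paths)))
  invisible(x)
}

#' @export
plot.chromatin_gt <- function(x, ...) {
  plot(x$site_positions, pch = ".", asp = 1, xlab = "x (nm)",
       ylab = "y (nm)", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  lines(x$nucleus$center[1] + x$nucleus$semiaxes[1] * cos(th),
        x$nucleus$center[2] + x$nucleus$semiaxes[2] * sin(th), col = 2)
  invisible(x)
}

#' Acquisition and camera parameters for a simulated fBALM movie
#'
#' @param pixel_size_nm camera pixel size in sample space (nm).
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm).
#' @param n_frames number of movie frames (>= 1).
#' @param mean_events_per_frame expected number of new binding events per
#'   frame (Poisson).
#' @param mean_on_frames mean binding duration in frames (geometric,
#'   support >= 1 frame).
#' @param photons_per_frame_mean expected detected photons emitted by a
#'   bound dye per frame (Poisson).
#' @param background_photons_per_pixel expected background photons per
#'   pixel per frame (Poisson).
#' @param read_noise_sd Gaussian camera read noise, in counts.
#' @param camera_offset camera baseline offset, counts.
#' @param camera_gain counts per detected photon.
#' @param fov_px field of view, pixels, length 2 (rows, cols).
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(pixel_size_nm = 100,
                               psf_sigma_nm = 130,
                               n_frames = 1000,
                               mean_events_per_frame = 8,
                               mean_on_frames = 3,
                               photons_per_frame_mean = 1000,
                               background_photons_per_pixel = 10,
                               read_noise_sd = 2,
                               camera_offset = 100,
                               camera_gain = 1,
                               fov_px = c(128, 128)) {
  check_positive(pixel_size_nm, "pixel_size_nm")
  check_positive(psf_sigma_nm, "psf_sigma_nm")
  check_positive(mean_on_frames, "mean_on_frames")
  check_positive(photons_per_frame_mean, "photons_per_frame_mean")
  check_positive(camera_gain, "camera_gain")
  if (n_frames < 1) stop_param("`n_frames` must be >= 1")
  if (mean_events_per_frame < 0)
    stop_param("`mean_events_per_frame` must be >= 0")
  if (background_photons_per_pixel < 0 || read_noise_sd < 0 ||
      camera_offset < 0)
    stop_param("background, read noise and offset must be >= 0")
  structure(list(pixel_size_nm = pixel_size_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 n_frames = as.integer(n_frames),
                 mean_events_per_frame = mean_events_per_frame,
                 mean_on_frames = mean_on_frames,
                 photons_per_frame_mean = photons_per_frame_mean,
                 background_photons_per_pixel = background_photons_per_pixel,
                 read_noise_sd = read_noise_sd,
                 camera_offset = camera_offset,
                 camera_gain = camera_gain,
                 fov_px = as.integer(fov_px)),
            class = "acquisition_params")
}

# Pixel-integrated Gaussian PSF weights over a square ROI around (x, y)
# (pixel units, origin at the outer corner of pixel (1,1)).
psf_pixel_weights <- function(x_px, y_px, sigma_px, half) {
  cx <- floor(x_px); cy <- floor(y_px)
  jx <- (cx - half):(cx + half)   # column indices - 1 (0-based cell)
  iy <- (cy - half):(cy + half)
  wx <- pnorm(jx + 1, x_px, sigma_px) - pnorm(jx, x_px, sigma_px)
  wy <- pnorm(iy + 1, y_px, sigma_px) - pnorm(iy, y_px, sigma_px)
  list(cols = jx + 1L, rows = iy + 1L, w = outer(wy, wx))
}

#' Simulate a binding-activated blinking movie over a chromatin structure
#'
#' The kinetic model is memoryless transient binding, consistent with the
#' fBALM mechanism in which dyes associate with transiently renatured
#' double-stranded DNA and fluoresce until dissociation or bleaching: new
#' events arrive per frame as Poisson draws at uniformly chosen sites,
#' stay on for a geometric number of consecutive frames, and emit a
#' Poisson number of photons per frame. Each event-frame is rendered as a
#' pixel-integrated isotropic 2D Gaussian PSF; Poisson background and
#' shot noise, Gaussian read noise, camera offset and gain complete the
#' camera model. Counts are rounded and clipped to `[0, 65535]` (16-bit
#' range).
#'
#' @param gt a `chromatin_gt` object (or any list with a `site_positions`
#'   n x 2 matrix in nm).
#' @param params an [acquisition_params()] object.
#' @param seed integer; fixes the movie bit-exactly.
#' @return a list with elements `movie` (class `movie_stack`: integer
#'   array rows x cols x frames plus `params`) and `events` (data frame
#'   of emission records: `site_index`, `first_frame`, `last_frame`,
#'   `x_nm`, `y_nm`, `total_photons`, and list column
#'   `photons_per_frame`).
#' @export
simulate_movie <- function(gt, params = acquisition_params(), seed = NULL) {
  stopifnot(inherits(params, "acquisition_params"))
  sites <- gt$site_positions
  if (is.null(sites) || nrow(sites) == 0L)
    stop_param("ground truth has no sites")
  a <- params$pixel_size_nm
  sigma_px <- params$psf_sigma_nm / a
  if (sigma_px < 0.25)
    warning("PSF sigma is below 0.25 pixel: the movie is undersampled",
            call. = FALSE)
  nr <- params$fov_px[1]; nc <- params$fov_px[2]
  nf <- params$n_frames
  half <- max(3L, ceiling(4 * sigma_px))

  with_seed(seed, {
    # --- draw all events up front -------------------------------------
    n_new <- rpois(nf, params$mean_events_per_frame)
    n_ev <- sum(n_new)
    movie <- array(0L, dim = c(nr, nc, nf))
    if (n_ev > 0L) {
      first <- rep.int(seq_len(nf), n_new)
      site <- sample.int(nrow(sites), n_ev, replace = TRUE)
      dur <- rgeom(n_ev, 1 / params$mean_on_frames) + 1L
      last <- pmin(first + dur - 1L, nf)
      len <- last - first + 1L
      photons <- lapply(len, function(l) rpois(l, params$photons_per_frame_mean))
    } else {
      first <- last <- site <- integer(0)
      photons <- list()
    }

    # per-frame index of active (event, frame-within-event) pairs
    if (n_ev > 0L) {
      ev_id <- rep.int(seq_len(n_ev), last - first + 1L)
      ev_fr <- unlist(lapply(seq_len(n_ev),
                             function(e) first[e]:last[e]), use.names = FALSE)
      ev_ph <- unlist(photons, use.names = FALSE)
      ord <- order(ev_fr)
      ev_id <- ev_id[ord]; ev_fr <- ev_fr[ord]; ev_ph <- ev_ph[ord]
      frame_split <- split(seq_along(ev_fr), ev_fr)
    } else frame_split <- list()

    x_px <- sites[site, 1] / a
    y_px <- sites[site, 2] / a
    b <- params$background_photons_per_pixel
    for (f in seq_len(nf)) {
      lam <- matrix(b, nr, nc)
      rows_f <- frame_split[[as.character(f)]]
      if (!is.null(rows_f)) {
        for (r in rows_f) {
          e <- ev_id[r]
          pw <- psf_pixel_weights(x_px[e], y_px[e], sigma_px, half)
          okc <- pw$cols >= 1L & pw$cols <= nc
          okr <- pw$rows >= 1L & pw$rows <= nr
          if (any(okr) && any(okc))
            lam[pw$rows[okr], pw$cols[okc]] <-
              lam[pw$rows[okr], pw$cols[okc]] +
              ev_ph[r] * pw$w[okr, okc, drop = FALSE]
        }
      }
      ph <- rpois(nr * nc, lam)
      cnt <- round(params$camera_offset + params$camera_gain * ph +
                     rnorm(nr * nc, 0, params$read_noise_sd))
      movie[, , f] <- matrix(pmin.int(pmax.int(as.integer(cnt), 0L), 65535L),
                             nr, nc)
    }

    events <- data.frame(site_index = site, first_frame = first,
                         last_frame = last,
                         x_nm = sites[site, 1], y_nm = sites[site, 2],
                         total_photons = vapply(photons, sum, numeric(1)))
    events$photons_per_frame <- photons
    stack <- structure(list(data = movie, params = params),
                       class = "movie_stack")
    list(movie = stack, events = events)
  })
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fBALM movie: %d frames of %d x %d px (%.0f nm pixels)\n",
              d[3], d[1], d[2], x$params$pixel_size_nm))
  invisible(x)
}

#' Generate point-like nuclear foci uniformly inside an ellipsoid
#'
#' Emulates EdU-labelled replication foci used as chromatin-bound 3D
#' reference points for nearest-neighbour morphometry.
#'
#' @param n_foci number of foci (>= 2; nearest-neighbour analysis is
#'   undefined for fewer).
#' @param nucleus list with `center` (length 3, nm) and `semiaxes`
#'   (length 3, nm).
#' @param intensity_mean mean focus intensity (arbitrary units); per-focus
#'   intensities are drawn from a gamma distribution with shape 4.
#' @param seed integer seed.
#' @return an object of class `foci3d`: list with `positions` (n x 3
#'   matrix, nm), `intensities`, `nucleus`.
#' @export
generate_foci_3d <- function(n_foci, nucleus = list(center = c(5000, 5000, 2500),
                                                    semiaxes = c(4500, 4500, 2000)),
                             intensity_mean = 1000, seed = NULL) {
  if (n_foci < 2)
    stop_param("`n_foci` must be >= 2 (nearest neighbours undefined)")
  check_positive(nucleus$semiaxes, "nucleus$semiaxes")
  with_seed(seed, {
    n <- as.integer(n_foci)
    out <- matrix(NA_real_, n, 3)
    todo <- n
    filled <- 0L
    while (todo > 0L) {
      m <- max(16L, ceiling(todo * 2.1))  # ellipsoid fills pi/6 of its box
      u <- matrix(runif(3 * m, -1, 1), m, 3)
      keep <- rowSums(u^2) <= 1
      u <- u[keep, , drop = FALSE]
      take <- min(nrow(u), todo)
      if (take > 0L) {
        out[filled + seq_len(take), ] <-
          sweep(u[seq_len(take), , drop = FALSE] %*% diag(nucleus$semiaxes),
                2, nucleus$center, "+")
        filled <- filled + take
        todo <- todo - take
      }
    }
    colnames(out) <- c("x_nm", "y_nm", "z_nm")
    structure(list(positions = out,
                   intensities = stats::rgamma(n, shape = 4,
                                               scale = intensity_mean / 4),
                   nucleus = nucleus),
              class = "foci3d")
  })
}

#' @export
print.foci3d <- function(x, ...) {
  cat(sprintf("3D foci set: %d foci\n", nrow(x$positions)))
  invisible(x)
}

#' Contract a 3D foci set isotropically about its centroid
#'
#' Models nuclear shrinkage (e.g. on abrupt acidification) as an
#' isotropic linear rescaling; the convex-hull volume then scales by the
#' cube of the linear factor.
#'
#' @param foci a `foci3d` object.
#' @param linear_factor scale factor in `(0, 1]`.
#' @return the contracted `foci3d` object (nucleus semi-axes scaled
#'   accordingly).
#' @export
apply_isotropic_contraction <- function(foci, linear_factor) {
  stopifnot(inherits(foci, "foci3d"))
  if (!is.numeric(linear_factor) || length(linear_factor) != 1L ||
      linear_factor <= 0 || linear_factor > 1)
    stop_param("`linear_factor` must be in (0, 1]")
  ctr <- colMeans(foci$positions)
  pos <- sweep(sweep(foci$positions, 2, ctr, "-") * linear_factor,
               2, ctr, "+")
  nuc <- foci$nucleus
  if (!is.null(nuc)) {
    nuc$semiaxes <- nuc$semiaxes * linear_factor
    nuc$center <- ctr + (nuc$center - ctr) * linear_factor
  }
  structure(list(positions = pos, intensities = foci$intensities,
                 nucleus = nuc),
            class = "foci3d")
}

#' Render a 3D confocal-like stack from a foci set
#'
#' Each focus becomes a 3D Gaussian (anisotropic: lateral and axial
#' sigma) scaled by its intensity, sampled on the voxel grid; Poisson
#' shot noise on signal plus background and Gaussian read noise complete
#' the camera model.
#'
#' @param foci a `foci3d` object.
#' @param voxel_nm numeric length 3: voxel size (x, y, z) in nm.
#' @param psf_sigma_nm numeric length 2: lateral and axial PSF sigma, nm.
#' @param dim_vox integer length 3 (nx, ny, nz); default covers the
#'   nuclear ellipsoid plus a margin.
#' @param background_photons,read_noise_sd,offset,gain camera model.
#' @param photons_scale photons per intensity unit at a focus.
#' @param shot_noise logical; set `FALSE` to skip Poisson shot noise and
#'   return the deterministic expected image (useful for benchmarking).
#' @param seed integer seed.
#' @return list with `stack` (numeric array ny x nx x nz, counts),
#'   `voxel_nm`, and `n_clipped` (foci outside the rendered volume).
#' @export
render_confocal_stack <- function(foci, voxel_nm = c(80, 80, 250),
                                  psf_sigma_nm = c(120, 360),
                                  dim_vox = NULL,
                                  background_photons = 5,
                                  read_noise_sd = 2, offset = 100, gain = 1,
                                  photons_scale = 1, shot_noise = TRUE,
                                  seed = NULL) {
  stopifnot(inherits(foci, "foci3d"))
  check_positive(voxel_nm, "voxel_nm")
  check_positive(psf_sigma_nm, "psf_sigma_nm")
  pos <- foci$positions
  if (is.null(dim_vox)) {
    hi <- apply(pos, 2, max) + 4 * psf_sigma_nm[c(1, 1, 2)]
    dim_vox <- ceiling(hi / voxel_nm)
  }
  nx <- dim_vox[1]; ny <- dim_vox[2]; nz <- dim_vox[3]
  sx <- psf_sigma_nm[1] / voxel_nm[1]
  sy <- psf_sigma_nm[1] / voxel_nm[2]
  sz <- psf_sigma_nm[2] / voxel_nm[3]
  px <- pos[, 1] / voxel_nm[1]
  py <- pos[, 2] / voxel_nm[2]
  pz <- pos[, 3] / voxel_nm[3]
  inside <- px >= 0 & px <= nx & py >= 0 & py <= ny & pz >= 0 & pz <= nz
  n_clipped <- sum(!inside)
  hx <- ceiling(4 * sx); hy <- ceiling(4 * sy); hz <- ceiling(4 * sz)
  lam <- array(background_photons, dim = c(ny, nx, nz))
  amp <- foci$intensities * photons_scale
  for (i in which(inside)) {
    jx <- max(1, floor(px[i]) - hx):min(nx, floor(px[i]) + hx + 1)
    iy <- max(1, floor(py[i]) - hy):min(ny, floor(py[i]) + hy + 1)
    kz <- max(1, floor(pz[i]) - hz):min(nz, floor(pz[i]) + hz + 1)
    wx <- pnorm(jx, px[i], sx) - pnorm(jx - 1, px[i], sx)
    wy <- pnorm(iy, py[i], sy) - pnorm(iy - 1, py[i], sy)
    wz <- pnorm(kz, pz[i], sz) - pnorm(kz - 1, pz[i], sz)
    blk <- outer(outer(wy, wx), wz) * amp[i]
    lam[iy, jx, kz] <- lam[iy, jx, kz] + blk
  }
  with_seed(seed, {
    ph <- if (shot_noise) array(rpois(length(lam), lam), dim = dim(lam))
          else lam
    cnt <- round(offset + gain * ph +
                   rnorm(length(lam), 0, read_noise_sd))
    stack <- array(pmax(cnt, 0), dim = dim(lam))
    list(stack = stack, voxel_nm = voxel_nm, n_clipped = n_clipped)
  })
}
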