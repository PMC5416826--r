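# Shared fixtures, all generated in code. Heavier objects are built
# lazily and cached for the duration of the test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# A small clustered structure plus a short movie and its localization
# table: the workhorse fixture for localization/rendering/FRC tests.
small_sim <- function() cached("small_sim", function() {
  gt <- generate_chromatin_structure(chromatin_params(
    nucleus_center = c(3200, 3200), nucleus_semiaxes = c(2500, 2200),
    n_clusters = 12, n_sites = 4000), seed = 3)
  sim <- simulate_movie(gt, acquisition_params(
    n_frames = 200, mean_events_per_frame = 3, fov_px = c(64, 64)),
    seed = 4)
  tab <- localize_movie(sim$movie)
  list(gt = gt, movie = sim$movie, events = sim$events, table = tab)
})

# Sparse isolated single-frame emitters with known ground truth, for
# accuracy and recall measurements.
isolated_sim <- function() cached("isolated_sim", function() {
  set.seed(101)
  pos <- cbind(runif(3000, 800, 12000), runif(3000, 800, 12000))
  gt <- list(site_positions = pos)
  sim <- simulate_movie(gt, acquisition_params(
    n_frames = 350, mean_events_per_frame = 2, mean_on_frames = 1,
    fov_px = c(128, 128)), seed = 11)
  sim
})

# Match localizations to emission records frame by frame; returns
# squared errors (nm^2) of matched pairs and the per-event recall.
match_to_events <- function(tab, events, radius_nm = 100) {
  err2 <- numeric(0)
  hit <- logical(nrow(events))
  for (i in seq_len(nrow(tab))) {
    cand <- which(events$first_frame == tab$frame[i])
    if (!length(cand)) next
    d2 <- (events$x_nm[cand] - tab$x_nm[i])^2 +
          (events$y_nm[cand] - tab$y_nm[i])^2
    j <- which.min(d2)
    if (d2[j] < radius_nm^2) {
      err2 <- c(err2, d2[j])
      hit[cand[j]] <- TRUE
    }
  }
  list(err2 = err2, hit = hit)
}

# Synthetic localization table helper.
make_table <- function(x, y, frame = seq_along(x), sigma = 130,
                       photons = 1000, background = 3, pixel = 100) {
  n <- length(x)
  loc_table(data.frame(frame = frame, x_nm = x, y_nm = y,
                       sigma_nm = rep_len(sigma, n),
                       photons = rep_len(photons, n),
                       background = rep_len(background, n),
                       precision_nm = estimate_precision(
                         rep_len(sigma, n), rep_len(photons, n),
                         rep_len(background, n), pixel),
                       n_merged = 1L),
            pixel_size_nm = pixel)
}

# Noise-free pixel-integrated Gaussian spot, computed independently of
# the simulator (direct erf-difference arithmetic).
gauss_spot <- function(xc_px, yc_px, n_photons, sigma_px, nr, nc) {
  wx <- pnorm(seq_len(nc), xc_px, sigma_px) -
    pnorm(seq_len(nc) - 1, xc_px, sigma_px)
  wy <- pnorm(seq_len(nr), yc_px, sigma_px) -
    pnorm(seq_len(nr) - 1, yc_px, sigma_px)
  n_photons * outer(wy, wx)
}

# Analytic FRC curve object for resolution-inversion tests.
analytic_frc_curve <- function(q, frc, threshold = 1 / 7) {
  cv <- data.frame(q_per_nm = q, frc = frc,
                   n_pixels = rep(100L, length(q)))
  attr(cv, "pixel_size_nm") <- NA_real_
  attr(cv, "threshold") <- threshold
  class(cv) <- c("frc_curve", "data.frame")
  cv
}
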