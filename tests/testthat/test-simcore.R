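# Ground-truth structure generation, movie simulation and 3D foci
# generation.

test_that("chromatin structure respects cluster geometry and confinement", {
  # single cluster with a fixed 200 nm diameter: sites concentrate
  # around the centre
  p1 <- chromatin_params(n_clusters = 1, n_sites = 1000,
                         diameter_range_nm = c(200, 200),
                         backbone_fraction = 0)
  gt1 <- generate_chromatin_structure(p1, seed = 1)
  d <- sqrt(rowSums(sweep(gt1$site_positions, 2,
                          gt1$cluster_centers[1, ])^2))
  expect_gte(mean(d <= 200), 0.95)
  expect_equal(nrow(gt1$site_positions), 1000)

  # diameters land in the configured range
  gt2 <- generate_chromatin_structure(chromatin_params(
    n_clusters = 40, n_sites = 500), seed = 2)
  expect_true(all(gt2$cluster_diameters_nm >= 100 &
                    gt2$cluster_diameters_nm <= 400))

  # every site inside the nuclear ellipse
  nc <- gt2$nucleus$center; ax <- gt2$nucleus$semiaxes
  r2 <- ((gt2$site_positions[, 1] - nc[1]) / ax[1])^2 +
        ((gt2$site_positions[, 2] - nc[2]) / ax[2])^2
  expect_true(all(r2 <= 1))
})

test_that("structure generation is deterministic under a seed", {
  p <- chromatin_params(n_clusters = 10, n_sites = 800)
  a <- generate_chromatin_structure(p, seed = 7)
  b <- generate_chromatin_structure(p, seed = 7)
  expect_identical(a$site_positions, b$site_positions)
  expect_identical(a$cluster_diameters_nm, b$cluster_diameters_nm)
  c <- generate_chromatin_structure(p, seed = 8)
  expect_false(identical(a$site_positions, c$site_positions))
})

test_that("degenerate structure parameters are rejected", {
  expect_error(chromatin_params(nucleus_semiaxes = c(0, 100)),
               "degenerate")
  expect_error(chromatin_params(n_clusters = 0), "n_clusters")
  expect_error(chromatin_params(diameter_range_nm = c(400, 100)),
               "diameter_range")
})

test_that("movie total photons agree with the emission records and the
          truncation-corrected expectation", {
  # one event with a large photon budget, clean camera: summed counts
  # match the drawn photons within shot noise
  gt <- list(site_positions = cbind(800, 800))
  ap <- acquisition_params(pixel_size_nm = 100, n_frames = 1,
                           mean_events_per_frame = 1, mean_on_frames = 1,
                           photons_per_frame_mean = 10000,
                           background_photons_per_pixel = 0,
                           read_noise_sd = 0, camera_offset = 0,
                           camera_gain = 2, fov_px = c(16, 16))
  sim <- simulate_movie(gt, ap, seed = 4)
  expect_equal(nrow(sim$events), 1)
  expect_lt(abs(sum(sim$movie$data) - 10000 * 2), 3 * sqrt(10000) * 2)

  # Poisson event-count check: 8 events/frame over 1000 frames
  gt2 <- list(site_positions = cbind(runif(50, 200, 1400),
                                     runif(50, 200, 1400)))
  ap2 <- acquisition_params(n_frames = 1000, mean_events_per_frame = 8,
                            photons_per_frame_mean = 50,
                            background_photons_per_pixel = 1,
                            fov_px = c(16, 16))
  sim2 <- simulate_movie(gt2, ap2, seed = 6)
  expect_lt(abs(nrow(sim2$events) - 8000), 3 * sqrt(8000))

  # photon conservation in expectation over seeds, with the exact
  # correction for events truncated at the end of the movie:
  # E[min(dur, m)] = (1 - (1-p)^m) / p for a geometric duration
  nf <- 300; lam <- 4; nph <- 200; mu_on <- 2
  p_off <- 1 / mu_on
  e_min <- (1 - (1 - p_off)^(nf:1)) / p_off
  expected <- lam * nph * sum(e_min)
  totals <- vapply(1:6, function(s) {
    sm <- simulate_movie(gt2, acquisition_params(
      n_frames = nf, mean_events_per_frame = lam, mean_on_frames = mu_on,
      photons_per_frame_mean = nph, background_photons_per_pixel = 1,
      fov_px = c(16, 16)), seed = 100 + s)
    sum(sm$events$total_photons)
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("a movie without emitters is pure background downstream", {
  gt <- list(site_positions = cbind(800, 800))
  ap <- acquisition_params(n_frames = 20, mean_events_per_frame = 0,
                           fov_px = c(64, 64))
  sim <- simulate_movie(gt, ap, seed = 9)
  expect_equal(nrow(sim$events), 0)
  tab <- localize_movie(sim$movie)
  expect_lte(nrow(tab), 1)
})

test_that("movies are bit-identical under a fixed seed", {
  gt <- generate_chromatin_structure(chromatin_params(
    n_clusters = 3, n_sites = 300,
    nucleus_center = c(800, 800), nucleus_semiaxes = c(600, 500)),
    seed = 1)
  ap <- acquisition_params(n_frames = 10, fov_px = c(16, 16))
  m1 <- simulate_movie(gt, ap, seed = 42)
  m2 <- simulate_movie(gt, ap, seed = 42)
  expect_identical(m1$movie$data, m2$movie$data)
  expect_identical(m1$events$total_photons, m2$events$total_photons)
})

test_that("undersampled PSF raises a warning", {
  gt <- list(site_positions = cbind(800, 800))
  ap <- acquisition_params(psf_sigma_nm = 20, pixel_size_nm = 100,
                           n_frames = 2, fov_px = c(16, 16))
  expect_warning(simulate_movie(gt, ap, seed = 1), "undersampled")
})

test_that("3D foci generation is exact, confined and seeded", {
  nuc <- list(center = c(5000, 5000, 2500), semiaxes = c(4000, 4000, 2000))
  f <- generate_foci_3d(15000, nucleus = nuc, seed = 3)
  expect_equal(nrow(f$positions), 15000)
  r2 <- rowSums(sweep(sweep(f$positions, 2, nuc$center), 2,
                      nuc$semiaxes, "/")^2)
  expect_true(all(r2 <= 1))
  f2 <- generate_foci_3d(15000, nucleus = nuc, seed = 3)
  expect_identical(f$positions, f2$positions)
  expect_error(generate_foci_3d(1), "n_foci")
})

test_that("isotropic contraction follows the cube law exactly", {
  f <- generate_foci_3d(50, seed = 4)
  expect_equal(apply_isotropic_contraction(f, 1)$positions, f$positions)

  cube <- structure(list(positions = as.matrix(expand.grid(
    x_nm = c(0, 1000), y_nm = c(0, 1000), z_nm = c(0, 1000))),
    intensities = rep(1, 8), nucleus = NULL), class = "foci3d")
  half <- apply_isotropic_contraction(cube, 0.5)
  expect_equal(convex_hull_volume(half$positions) /
                 convex_hull_volume(cube$positions), 0.125,
               tolerance = 1e-9)

  f3 <- apply_isotropic_contraction(f, 0.8434)
  expect_equal(convex_hull_volume(f3$positions) /
                 convex_hull_volume(f$positions), 0.8434^3,
               tolerance = 1e-9)
  expect_error(apply_isotropic_contraction(f, 0), "linear_factor")
  expect_error(apply_isotropic_contraction(f, -1), "linear_factor")
})

test_that("confocal rendering places and separates foci correctly", {
  # one focus at a voxel centre, no noise: stack argmax at that voxel
  one <- structure(list(positions = matrix(c(840, 1240, 1375), 1),
                        intensities = 500, nucleus = NULL),
                   class = "foci3d")
  st <- render_confocal_stack(one, voxel_nm = c(80, 80, 250),
                              dim_vox = c(25, 25, 11),
                              background_photons = 0, read_noise_sd = 0,
                              offset = 0, shot_noise = FALSE)
  am <- which(st$stack == max(st$stack), arr.ind = TRUE)
  # x = 840 nm -> voxel 11 (centre 840), y -> voxel 16, z -> voxel 6
  expect_equal(unname(am[1, ]), c(16, 11, 6))

  # two foci 2 um apart give two distinct regional maxima
  two <- structure(list(positions = rbind(c(1000, 1000, 1375),
                                          c(3000, 1000, 1375)),
                        intensities = c(3000, 3000), nucleus = NULL),
                   class = "foci3d")
  st2 <- render_confocal_stack(two, voxel_nm = c(80, 80, 250),
                               psf_sigma_nm = c(100, 300),
                               dim_vox = c(50, 50, 11),
                               background_photons = 2, seed = 1)
  cand <- detect_foci_3d(st2$stack, k = 4)
  expect_equal(nrow(cand), 2)

  # zero-intensity foci: all-background stack
  zero <- structure(list(positions = matrix(c(1000, 1000, 1375), 1),
                         intensities = 0, nucleus = NULL),
                    class = "foci3d")
  st3 <- render_confocal_stack(zero, dim_vox = c(20, 20, 8),
                               background_photons = 0, read_noise_sd = 0,
                               offset = 7, shot_noise = FALSE)
  expect_true(all(st3$stack == 7))
})
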