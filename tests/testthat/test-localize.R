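# Background/noise estimation, peak detection, centroid fitting,
# precision, diameter filter and consecutive-frame merging.

test_that("background and noise estimation is robust", {
  # flat frame: background reproduced exactly, zero noise
  flat <- matrix(100, 64, 64)
  bn <- estimate_background_noise(flat)
  expect_true(all(bn$background == 100))
  expect_equal(bn$noise_sd, 0)

  # flat + Gaussian noise: MAD-based SD consistent within 10%
  set.seed(1)
  noisy <- matrix(100 + rnorm(128^2, 0, 10), 128, 128)
  bn2 <- estimate_background_noise(noisy)
  expect_lt(abs(bn2$noise_sd - 10) / 10, 0.10)

  # a hot pixel does not perturb the background map beyond the kernel
  hot <- flat
  hot[30, 30] <- 5000
  bn3 <- estimate_background_noise(hot)
  far <- bn3$background[abs(row(flat) - 30) > 6 | abs(col(flat) - 30) > 6]
  # (the constant-time median filter quantizes at ~0.02 counts here)
  expect_true(all(abs(far - 100) < 0.1))
})

test_that("the detection threshold is sharp at k noise SDs above background", {
  frame <- matrix(100, 32, 32)
  bg <- matrix(100, 32, 32)
  frame[16, 16] <- 131
  expect_equal(nrow(detect_peaks(frame, bg, 10, k = 3)), 1)
  frame[16, 16] <- 129
  expect_equal(nrow(detect_peaks(frame, bg, 10, k = 3)), 0)
  # boundary value: strictly-above comparison
  frame[16, 16] <- 130
  expect_equal(nrow(detect_peaks(frame, bg, 10, k = 3)), 0)
  frame[16, 16] <- 130.5
  expect_equal(nrow(detect_peaks(frame, bg, 10, k = 3)), 1)
})

test_that("five isolated emitters yield exactly five matching candidates", {
  set.seed(2)
  truth <- cbind(row = c(10, 10, 32, 50, 54), col = c(10, 50, 30, 12, 52))
  frame <- matrix(rpois(64^2, 10), 64, 64)
  for (i in 1:5)
    frame <- frame + gauss_spot(truth[i, "col"] - 0.5,
                                truth[i, "row"] - 0.5, 1000, 1.3, 64, 64)
  bn <- estimate_background_noise(frame)
  cand <- detect_peaks(frame, bn$background, bn$noise_sd, k = 3)
  # candidate local maxima at the emitters (noise maxima near threshold
  # may also appear; every emitter must be found within 1 pixel)
  matched <- vapply(seq_len(5), function(i)
    any(abs(cand[, "row"] - truth[i, "row"]) <= 1 &
          abs(cand[, "col"] - truth[i, "col"]) <= 1), logical(1))
  expect_true(all(matched))
  strong <- cand[frame[cand] - bn$background[cand] > 50, , drop = FALSE]
  expect_equal(nrow(strong), 5)
})

test_that("centre-of-gravity fitting is exact on symmetric input and
          matches hand-computed weighted means", {
  # symmetric blob centred on a pixel: centroid at that pixel centre
  frame <- matrix(0, 21, 21)
  frame <- frame + gauss_spot(10.5, 10.5, 1000, 1.3, 21, 21)
  f <- fit_localization(frame, frame * 0, 0, c(11, 11), 3, 100, 1)
  expect_equal(f$x_nm, 10.5 * 100, tolerance = 1e-9)
  expect_equal(f$y_nm, 10.5 * 100, tolerance = 1e-9)

  # two-pixel weights {3, 1}: x = first centre + 25 nm
  frame2 <- matrix(0, 15, 15)
  frame2[8, 8] <- 3
  frame2[8, 9] <- 1
  f2 <- fit_localization(frame2, frame2 * 0, 0, c(8, 8), 3, 100, 1)
  expect_equal(f2$x_nm, (8 - 0.5) * 100 + 25, tolerance = 1e-9)
  expect_equal(f2$y_nm, (8 - 0.5) * 100, tolerance = 1e-9)

  # noise-free sub-pixel offset recovered within 0.05 pixel
  for (off in list(c(0.3, -0.2), c(0.45, 0.45))) {
    fr <- gauss_spot(10.5 + off[1], 10.5 + off[2], 1000, 1.3, 21, 21)
    ff <- fit_localization(fr, fr * 0, 0, c(11, 11), 3, 100, 1)
    expect_lt(abs(ff$x_nm / 100 - (10.5 + off[1])), 0.05)
    expect_lt(abs(ff$y_nm / 100 - (10.5 + off[2])), 0.05)
  }

  # ROI leaving the frame drops the candidate
  expect_equal(nrow(fit_localization(frame, frame * 0, 0, c(2, 2), 3,
                                     100, 1)), 0)
})

test_that("Thompson precision follows the closed form and its scalings", {
  expect_equal(estimate_precision(130, 1000, 0, 100),
               sqrt((130^2 + 100^2 / 12) / 1000), tolerance = 1e-12)
  expect_equal(estimate_precision(130, 1000, 0, 100), 4.2, tolerance = 0.01)
  # quadrupling photons halves the precision at zero background
  expect_equal(estimate_precision(130, 4000, 0, 100),
               estimate_precision(130, 1000, 0, 100) / 2)
  # any background strictly degrades precision
  expect_gt(estimate_precision(130, 1000, 5, 100),
            estimate_precision(130, 1000, 0, 100))
  expect_error(estimate_precision(130, 0, 0, 100), "photons")
})

test_that("diameter filter keeps exactly ceil((1 - f) n) of distinct sigmas", {
  tb <- make_table(1:10 * 10, 1:10 * 10, sigma = 1:10)
  kept <- filter_by_diameter(tb, 0.30)
  expect_equal(nrow(kept), 7)
  expect_true(all(kept$sigma_nm <= 7))

  expect_equal(nrow(filter_by_diameter(tb, 0)), 10)

  set.seed(3)
  big <- make_table(runif(10000), runif(10000), sigma = sample(1e6, 10000))
  expect_equal(nrow(filter_by_diameter(big, 0.30)), 7000)

  # property: retained count is ceil(0.7 n) for any n with distinct sigmas
  for (n in c(1, 2, 3, 10, 33, 101)) {
    tbn <- make_table(seq_len(n), seq_len(n), sigma = sample(n) + 0.5)
    expect_equal(nrow(filter_by_diameter(tbn, 0.30)), ceiling(0.7 * n))
  }
  # ties at the threshold are all kept
  tie <- make_table(1:4, 1:4, sigma = c(1, 2, 2, 2))
  expect_equal(nrow(filter_by_diameter(tie, 0.30)), 4)
})

test_that("consecutive-frame merging links, collapses and is idempotent", {
  # coincident rows in consecutive frames collapse with summed photons
  tb <- make_table(c(1000, 1000), c(2000, 2000), frame = c(5, 6),
                   photons = c(800, 600))
  m <- merge_consecutive(tb)
  expect_equal(nrow(m), 1)
  expect_equal(m$photons, 1400)
  expect_equal(m$n_merged, 2L)
  expect_equal(m$frame, 5)

  # distant rows stay separate
  r <- 2 * mean_precision(tb)
  tb2 <- make_table(c(1000, 1000 + 10 * r), c(2000, 2000), frame = c(5, 6))
  expect_equal(nrow(merge_consecutive(tb2)), 2)

  # a three-frame chain collapses to one row with photon-weighted position
  tb3 <- make_table(c(1000, 1001, 1002), c(2000, 2000, 2000),
                    frame = c(3, 4, 5), photons = c(500, 1000, 500))
  m3 <- merge_consecutive(tb3)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$n_merged, 3L)
  expect_equal(m3$x_nm, (500 * 1000 + 1000 * 1001 + 500 * 1002) / 2000)
  expect_equal(m3$frame, 3)

  # non-consecutive frames never merge
  tb4 <- make_table(c(1000, 1000), c(2000, 2000), frame = c(3, 5))
  expect_equal(nrow(merge_consecutive(tb4)), 2)

  # idempotence on a realistic random table
  set.seed(4)
  n <- 400
  tb5 <- make_table(runif(n, 0, 20000), runif(n, 0, 20000),
                    frame = sample(1:50, n, replace = TRUE),
                    photons = runif(n, 500, 2000))
  m5 <- merge_consecutive(tb5)
  m55 <- merge_consecutive(m5)
  expect_equal(as.data.frame(m55), as.data.frame(m5))
})

test_that("merge conflicts resolve to the closest pair", {
  # two rows in frame 1 compete for one row in frame 2: nearest wins
  tb <- make_table(c(0, 30, 1), c(0, 0, 0), frame = c(1, 1, 2))
  m <- merge_consecutive(tb, radius_nm = 50)
  expect_equal(nrow(m), 2)
  merged <- m[m$n_merged == 2L, ]
  expect_lt(merged$x_nm, 10)   # the (0,0) row captured the frame-2 row
})

test_that("localize_movie is deterministic and accurate on simulated data", {
  fx <- small_sim()
  t1 <- localize_movie(fx$movie)
  expect_identical(as.data.frame(t1), as.data.frame(fx$table))

  # high-SNR recall against the emission records (detection stage:
  # diameter filter off, since it removes a fixed 30% regardless)
  iso <- isolated_sim()
  tab <- localize_movie(iso$movie, localize_config(filter_fraction = 0))
  ev <- iso$events
  interior <- ev$x_nm > 400 & ev$x_nm < 12400 &
              ev$y_nm > 400 & ev$y_nm < 12400
  mm <- match_to_events(tab, ev)
  expect_gte(mean(mm$hit[interior]), 0.95)
})

test_that("empty and pathological movies localize to empty tables", {
  stack <- structure(list(data = array(100L, dim = c(16, 16, 3)),
                          params = acquisition_params(n_frames = 3,
                                                      fov_px = c(16, 16))),
                     class = "movie_stack")
  tab <- localize_movie(stack)
  expect_equal(nrow(tab), 0)
  expect_true(is.na(mean_precision(tab)))
})
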