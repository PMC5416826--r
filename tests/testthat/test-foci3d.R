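# 3D foci detection, centroid localization, nearest-neighbour and
# volume morphometry.

test_that("nearest-neighbour distances match the exhaustive oracle", {
  two <- rbind(c(0, 0, 0), c(500, 0, 0))
  nn <- nn_distances(two)
  expect_equal(nn$distances, c(500, 500))
  expect_equal(nn$mean_nn, 500)

  set.seed(1)
  pos <- matrix(runif(900, 0, 5000), 300, 3)
  nn2 <- nn_distances(pos)
  # brute-force O(n^2) oracle
  ref <- vapply(1:300, function(i) {
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    min(d[-i])
  }, numeric(1))
  expect_equal(nn2$distances, ref)

  # homogeneity: distances scale exactly with the coordinates
  nn3 <- nn_distances(pos * 3.5)
  expect_equal(nn3$distances, 3.5 * nn2$distances)

  expect_error(nn_distances(matrix(0, 1, 3)), "at least 2")
})

test_that("convex hull volume is exact on known solids and converges on
          an ellipsoid", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) * 1000
  expect_equal(convex_hull_volume(cube / 1000), 1, tolerance = 1e-12)
  v <- nuclear_volume(structure(list(positions = cube,
                                     intensities = rep(1, 8),
                                     nucleus = NULL), class = "foci3d"))
  expect_equal(v$volume_um3, 1, tolerance = 1e-12)

  # interior points change nothing
  set.seed(2)
  inner <- matrix(runif(300, 100, 900), 100, 3)
  expect_equal(convex_hull_volume(rbind(cube, inner)),
               convex_hull_volume(cube), tolerance = 1e-12)

  # uniform fill of an ellipsoid: hull volume within 5% of (4/3) pi abc
  # (the hull deficit of a uniform fill shrinks as n^(-2/3): ~9% at
  # n = 2000, ~3.5% at n = 8000)
  nuc <- list(center = c(5000, 5000, 2500), semiaxes = c(4000, 3000, 1500))
  f <- generate_foci_3d(8000, nucleus = nuc, seed = 3)
  vol <- nuclear_volume(f)$volume_um3
  truth <- 4 / 3 * pi * prod(nuc$semiaxes / 1000)
  expect_lt(abs(vol - truth) / truth, 0.05)

  # coplanar points are rejected
  flat <- cbind(runif(10), runif(10), 0.5)
  expect_error(convex_hull_volume(flat), "coplanar")
})

test_that("hull volume agrees with an independent reference on random
          point sets", {
  # reference values frozen from scipy.spatial.ConvexHull on the same
  # deterministically generated points
  set.seed(42)
  pts <- matrix(runif(60), 20, 3)
  expect_equal(convex_hull_volume(pts), 0.38537994725844765,
               tolerance = 1e-9)
  set.seed(43)
  pts2 <- matrix(rnorm(90), 30, 3)
  expect_equal(convex_hull_volume(pts2), 16.49458710800986,
               tolerance = 1e-9)
})

test_that("3D detection and centroids recover rendered foci", {
  # 100 well-separated foci on a grid with jitter
  set.seed(4)
  gx <- as.matrix(expand.grid(x = (1:5) * 1500, y = (1:5) * 1500,
                              z = (1:4) * 2000))
  pos <- gx + matrix(runif(nrow(gx) * 3, -200, 200), nrow(gx))
  f <- structure(list(positions = pos, intensities = rep(3000, nrow(pos)),
                      nucleus = NULL), class = "foci3d")
  st <- render_confocal_stack(f, voxel_nm = c(80, 80, 250),
                              psf_sigma_nm = c(120, 360),
                              dim_vox = c(110, 110, 38),
                              background_photons = 2, seed = 5)
  cand <- detect_foci_3d(st$stack, k = 4)
  expect_equal(nrow(cand), nrow(pos))
  loc <- localize_foci_3d(st$stack, voxel_nm = c(80, 80, 250), k = 4)
  expect_equal(nrow(loc$positions), nrow(pos))
  # every focus recovered within one (axial) voxel; lateral-dominated
  # mean error well below a voxel
  err <- vapply(seq_len(nrow(pos)), function(i) {
    d <- sqrt(colSums((t(loc$positions) - pos[i, ])^2))
    min(d)
  }, numeric(1))
  expect_lt(max(err), 250)
  expect_lt(mean(err), 150)
})

test_that("an all-background stack yields essentially no candidates", {
  set.seed(6)
  stack <- array(rpois(100 * 100 * 50, 10) +
                   rnorm(100 * 100 * 50, 0, 2), c(100, 100, 50))
  cand <- detect_foci_3d(stack, k = 4)
  expect_lte(nrow(cand), 1)   # <= 1 false candidate per 5e5 voxels here
})

test_that("3D centroid is exact on symmetric input and robust to a
          tilted baseline", {
  stack <- array(0, c(15, 15, 11))
  stack[8, 8, 6] <- 10
  stack[7, 8, 6] <- 5; stack[9, 8, 6] <- 5
  stack[8, 7, 6] <- 5; stack[8, 9, 6] <- 5
  stack[8, 8, 5] <- 5; stack[8, 8, 7] <- 5
  p <- centroid_3d(stack, c(8, 8, 6), c(3, 3, 2), c(80, 80, 250))
  expect_equal(unname(p), c(7.5 * 80, 7.5 * 80, 5.5 * 250))

  # noise-free sub-voxel offset within 0.05 voxel
  off <- c(0.3, -0.25, 0.2)
  wx <- pnorm(1:15, 7.5 + off[1], 1.4) - pnorm(0:14, 7.5 + off[1], 1.4)
  wy <- pnorm(1:15, 7.5 + off[2], 1.4) - pnorm(0:14, 7.5 + off[2], 1.4)
  wz <- pnorm(1:11, 5.5 + off[3], 1.3) - pnorm(0:10, 5.5 + off[3], 1.3)
  st2 <- outer(outer(wy, wx), wz) * 5000
  p2 <- centroid_3d(st2, c(8, 8, 6), c(4, 4, 3), c(1, 1, 1))
  expect_lt(abs(p2[["x"]] - (7.5 + off[1])), 0.05)
  expect_lt(abs(p2[["y"]] - (7.5 + off[2])), 0.05)
  expect_lt(abs(p2[["z"]] - (5.5 + off[3])), 0.05)

  # a tilted background plane biases the centroid less after baseline
  # subtraction than without it
  plane <- outer(outer(15 + seq(0, 14, by = 1), rep(1, 15)), rep(1, 11))
  st3 <- st2 * 5 + plane
  with_base <- centroid_3d(st3, c(8, 8, 6), c(4, 4, 3), c(1, 1, 1))
  roi <- st3[4:12, 4:12, 3:9]
  wy3 <- apply(roi, 1, sum)
  naive_y <- sum((4:12 - 0.5) * wy3) / sum(roi)
  expect_lt(abs(with_base[["y"]] - (7.5 + off[2])),
            abs(naive_y - (7.5 + off[2])))
})

test_that("before/after comparison obeys identity, cube law and
          thinning bias", {
  f <- generate_foci_3d(600, seed = 7)
  same <- compare_before_after(f, f)
  expect_equal(same$delta_mean_nn_nm, 0)
  expect_equal(same$volume_change_pct, 0)

  contracted <- apply_isotropic_contraction(f, 0.8434)
  ch <- compare_before_after(f, contracted)
  expect_equal(ch$volume_change_pct, 100 * (0.8434^3 - 1),
               tolerance = 1e-9)
  expect_lt(ch$delta_mean_nn_nm, 0)

  # scale equivariance: delta <D> scales as s, volume change as s^3 - 1
  s <- 0.7
  scaled <- structure(list(positions = f$positions * s,
                           intensities = f$intensities, nucleus = NULL),
                      class = "foci3d")
  ch2 <- compare_before_after(f, scaled)
  expect_equal(ch2$delta_mean_nn_nm,
               (s - 1) * nn_distances(f)$mean_nn, tolerance = 1e-9)
  expect_equal(ch2$volume_change_pct, 100 * (s^3 - 1), tolerance = 1e-9)

  # random 10% thinning raises the mean nn distance in expectation
  set.seed(8)
  deltas <- replicate(50, {
    keep <- sample(600, 540)
    thinned <- structure(list(positions = f$positions[keep, ],
                              intensities = f$intensities[keep],
                              nucleus = NULL), class = "foci3d")
    nn_distances(thinned)$mean_nn - nn_distances(f)$mean_nn
  })
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.9)
})
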