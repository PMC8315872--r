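# sphere test volume: radius R (voxels) of bright signal on dark background
sphere_volume <- function(d = c(40, 40, 40), R = 8, fg = 150, bg = 20) {
  ctr <- (d - 1) / 2
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  r <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  list(vol = volume3d(array(ifelse(r <= R, fg, bg), dim = d)),
       r = array(r, dim = d))
}

test_that("edge indicator is 1 on flat regions and follows the ramp form", {
  flat <- volume3d(array(4, dim = c(8, 8, 8)))
  expect_equal(as.numeric(edge_indicator(flat, 1)$data),
               rep(1, 512))

  # ramp f = 2x + 3y - z (mm units), no smoothing: g = 1/(1 + 14) inside
  d <- c(10, 10, 10)
  idx <- as.matrix(expand.grid(0:9, 0:9, 0:9))
  ramp <- volume3d(array(2 * idx[, 1] + 3 * idx[, 2] - idx[, 3], dim = d))
  g <- edge_indicator(ramp, sigma = 0)
  expect_equal(g$data[4, 4, 4], 1 / (1 + 14), tolerance = 1e-6)

  # step edge: minimum of g lies on the edge plane
  st <- volume3d(array(rep(c(0, 0, 0, 0, 0, 100, 100, 100, 100, 100),
                           each = 1, times = 100), dim = d))
  gs <- edge_indicator(st, sigma = 1)
  prof <- gs$data[, 5, 5]
  expect_true(which.min(prof) %in% c(5L, 6L))
  expect_error(edge_indicator(ramp, sigma = -1), "sigma")
})

test_that("mean-shape initialization has the right sign and location", {
  sph <- sphere_volume()
  # landmarks on a sphere of radius 6 voxels around the center
  set.seed(1)
  dirs <- matrix(rnorm(150), 50, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ctr <- (dim(sph$vol$data) - 1) / 2
  lm <- sweep(6 * dirs, 2, ctr, "+")
  phi0 <- initialize_from_mean_shape(sph$vol, lm, intensity_weighted = FALSE,
                                     prior_radius_mm = 2)
  expect_s3_class(phi0, "level_set_field")
  m <- phi0$phi < 0
  expect_true(any(m) && !all(m))
  # region centroid within 1 voxel of the landmark centroid
  w <- which(m, arr.ind = TRUE) - 1
  expect_true(all(abs(colMeans(w) - colMeans(lm)) <= 1))
  # intensity weighting concentrates the region on the bright class
  phi1 <- initialize_from_mean_shape(sph$vol, lm, intensity_weighted = TRUE,
                                     prior_radius_mm = 3)
  expect_gte(mean(sph$vol$data[phi1$phi < 0] > 20), 0.9)
  expect_error(
    initialize_from_mean_shape(sph$vol, lm + 1000),
    "outside the ROI")
})

test_that("DRLSE is deterministic and reports numerical blow-ups", {
  sph <- sphere_volume(d = c(24, 24, 24), R = 6)
  g <- edge_indicator(sph$vol, 1)
  phi <- array(3, dim = dim(sph$vol$data))
  phi[sph$r <= 3] <- -3
  p <- drlse_params(n_iter = 50)
  a <- drlse_evolve(level_set_field(phi), g, p)
  b <- drlse_evolve(level_set_field(phi), g, p)
  expect_identical(a$phi, b$phi)
  # absurd edge weight forces NaN; the error names the iteration
  expect_error(
    drlse_evolve(level_set_field(sph$r - 3), g,
                 drlse_params(lambda = 1e308, n_iter = 50)),
    "iteration")
  expect_error(drlse_params(mu = 0.3, dt = 1), "stability")
})

test_that("masks from level sets threshold at zero and count volumes", {
  d <- c(20, 20, 20)
  expect_equal(sum(mask_from_levelset(
    level_set_field(array(1, dim = d)))$data), 0)
  # signed distance to a sphere of radius 7.3 voxels
  ctr <- (d - 1) / 2
  idx <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  r <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)), dim = d)
  m <- mask_from_levelset(level_set_field(r - 7.3))
  expect_lt(abs(sum(m$data) - 4 / 3 * pi * 7.3^3) / (4 / 3 * pi * 7.3^3),
            0.02)
  # largest-component option keeps the biggest blob only
  two <- array(1, dim = d)
  two[2:4, 2:4, 2:4] <- -1
  two[10:16, 10:16, 10:16] <- -1
  ml <- mask_from_levelset(level_set_field(two), largest_component = TRUE)
  expect_equal(sum(ml$data), 7^3)
})

test_that("region growing floods homogeneous blobs and respects tolerance", {
  d <- c(16L, 16L, 16L)
  vol <- array(10, dim = d)
  vol[4:8, 4:8, 4:8] <- 100      # blob A
  vol[12:14, 12:14, 12:14] <- 100  # blob B, disconnected
  v <- volume3d(vol)
  cfg <- region_grow_config(c(5L, 5L, 5L), tolerance = 5)
  m <- region_growing_segment(v, cfg)
  truth <- array(FALSE, dim = d)
  truth[4:8, 4:8, 4:8] <- TRUE
  expect_identical(m$data, truth)   # exactly blob A, never across contrast

  # tolerance 0 on a noisy image: only voxels equal to the running mean
  set.seed(2)
  nv <- volume3d(array(sample(1:5, prod(d), TRUE), dim = d))
  m0 <- region_growing_segment(nv, region_grow_config(c(0L, 0L, 0L), 0))
  expect_true(all(nv$data[m0$data] == nv$data[1, 1, 1]))

  expect_error(region_growing_segment(v, region_grow_config(c(20L, 0L, 0L), 1)),
               "inside the grid")
  expect_error(region_grow_config(c(0L, 0L, 0L), -1), "tolerance")
})

test_that("curvature repair removes spikes but leaves smooth spheres alone", {
  d <- c(32, 32, 32)
  ctr <- (d - 1) / 2
  idx <- as.matrix(expand.grid(0:31, 0:31, 0:31))
  ball <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 9, dim = d)
  sphere <- binary_mask(ball)
  expect_identical(curvature_repair(sphere)$data, sphere$data)

  spiked <- ball
  spiked[16, 16, 26] <- TRUE   # 1-voxel spike off the pole (r = 9 surface)
  rep_ <- curvature_repair(binary_mask(spiked), 95)
  expect_false(rep_$data[16, 16, 26])
  # remainder unchanged
  expect_identical(rep_$data[ball], ball[ball])

  # locality: changes confined to a 2-voxel band of the input boundary
  set.seed(3)
  m <- random_blob_mask(c(20L, 20L, 20L))
  r2 <- curvature_repair(m, 90)
  changed <- m$data != r2$data
  bnd <- labyrinthSeg:::boundary_voxels(m$data)
  band <- labyrinthSeg:::binary_dilate(bnd, 2L)
  expect_true(all(band[changed]))
  expect_error(curvature_repair(binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("the baseline pipeline is deterministic and segments clean phantoms", {
  sp <- small_spec(noise_sd = 0, bias_amplitude = 0)
  s <- generate_phantom(sp, seed = 30)
  cfg <- auto_region_grow_config(s$volume)
  a <- segment_region_growing_baseline(s$volume, cfg)
  b <- segment_region_growing_baseline(s$volume, cfg)
  expect_identical(a$data, b$data)
  r <- evaluate_segmentation(a, s$truth_mask)
  expect_gte(r$dsc, 0.90)
})

test_that("the full shape-model pipeline segments its own atlas accurately", {
  sp <- phantom_spec(noise_sd = 0, bias_amplitude = 0)
  coh <- generate_cohort(4, sp, seed = 31)
  ssm <- build_shape_model(lapply(coh, function(s) s$landmarks))
  atlas <- coh[[1]]
  model <- attach_atlas(ssm, atlas$landmarks, atlas$volume,
                        mask_roi(atlas$truth_mask))
  res <- segment_is3dls(atlas$volume, model)
  r <- evaluate_segmentation(res$mask, atlas$truth_mask)
  expect_gte(r$dsc, 0.95)

  # provenance round-trips through JSON serialization
  tfile <- tempfile(fileext = ".json")
  write_transform(res$provenance$transform, tfile)
  expect_equal(read_transform(tfile)$A, res$provenance$transform$A,
               tolerance = 1e-12)
  rfile <- tempfile(fileext = ".json")
  write_roi(res$provenance$roi, rfile)
  expect_identical(read_roi(rfile)$lower, res$provenance$roi$lower)
  expect_identical(read_roi(rfile)$upper, res$provenance$roi$upper)
})
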