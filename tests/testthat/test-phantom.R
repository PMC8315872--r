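test_that("phantom generation is bit-reproducible for a fixed (spec, seed)", {
  sp <- small_spec()
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth_mask$data, b$truth_mask$data)
  expect_identical(a$landmarks, b$landmarks)
  c_ <- generate_phantom(sp, seed = 8)
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("a noiseless, bias-free phantom has exactly two intensity levels", {
  sp <- small_spec(noise_sd = 0, bias_amplitude = 0)
  s <- generate_phantom(sp, seed = 1)
  vals <- sort(unique(as.numeric(s$volume$data)))
  expect_equal(vals, c(sp$bg_intensity, sp$fg_intensity))
  expect_identical(array(s$volume$data == sp$fg_intensity,
                         dim = sp$grid_shape),
                   s$truth_mask$data)
})

test_that("mask voxel count matches a 3x super-sampled voxelization oracle", {
  sp <- small_spec()
  center <- (sp$grid_shape - 1) * sp$spacing / 2
  s <- generate_phantom(sp, seed = 3,
                        pose = similarity_transform(translation = center))
  n_pkg <- sum(s$truth_mask$data)

  # super-sample at 3x resolution over the labyrinth bounding box (canonical
  # frame because the pose is a pure translation)
  fine <- sp$spacing[1] / 3
  cloud <- oracle_surface_cloud(sp, 2000L)
  lo <- apply(cloud, 2, min) - 1
  hi <- apply(cloud, 2, max) + 1
  gx <- seq(lo[1], hi[1], by = fine)
  gy <- seq(lo[2], hi[2], by = fine)
  gz <- seq(lo[3], hi[3], by = fine)
  n_fine <- 0
  curve <- oracle_helix_points(sp$cochlea)
  for (z in gz) {
    pts <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)), z)
    n_fine <- n_fine + sum(oracle_inside(pts, sp, curve))
  }
  expected <- n_fine * (fine / sp$spacing[1])^3
  expect_lt(abs(n_pkg - expected) / expected, 0.05)
})

test_that("landmarks sit at fixed parametric positions and follow the pose", {
  sp <- small_spec()
  a <- sample_landmarks(sp)
  b <- sample_landmarks(sp)
  expect_identical(a, b)
  t_ <- c(3, -2, 1)
  shifted <- sample_landmarks(sp, similarity_transform(translation = t_))
  expect_equal(shifted, sweep(a, 2, t_, "+"), tolerance = 1e-12)
})

test_that("landmarks lie on the phantom surface", {
  sp <- phantom_spec()
  s <- generate_phantom(sp, seed = 5)
  set.seed(99)
  cloud <- apply_similarity(s$pose, oracle_surface_cloud(s$spec, 30000L))
  d <- oracle_pairwise_min(s$landmarks, cloud)
  expect_lt(max(d), 0.5 * max(sp$spacing))
})

test_that("cohorts share landmark counts and sample the stated pose law", {
  expect_length(generate_cohort(0, small_spec(), seed = 1), 0)
  sp <- small_spec()
  coh <- generate_cohort(5, sp, seed = 11)
  expect_length(coh, 5L)
  expect_true(all(vapply(coh, function(s) nrow(s$landmarks), 1L) ==
                    sp$n_landmarks))
  # per-sample shape jitter: truth masks differ between samples
  expect_false(identical(coh[[1]]$truth_mask$data, coh[[2]]$truth_mask$data))
  expect_error(generate_cohort(-1, sp), "nonnegative")
})

test_that("mean sampled translation over a large cohort is near zero", {
  sp <- small_spec()
  coh <- generate_cohort(200, sp, seed = 42)
  center <- (sp$grid_shape - 1) * sp$spacing / 2
  tr <- t(vapply(coh, function(s) s$pose$translation - center, numeric(3)))
  mean_vox <- colMeans(tr) / sp$spacing
  expect_true(all(abs(mean_vox) <= 0.5))
})

test_that("structures that do not fit raise an error naming the primitive", {
  sp <- small_spec()
  sp$cochlea$base_radius <- 14
  expect_error(generate_phantom(sp, seed = 1), "cochlea")
})
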