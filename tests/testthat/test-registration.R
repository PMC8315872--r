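test_that("rigid maps apply A x + b and preserve distances", {
  expect_equal(apply_rigid(rigid_transform(), rbind(c(1, 2, 3))),
               rbind(c(1, 2, 3)))
  Rz <- euler_to_matrix(0, 0, pi / 2)
  expect_equal(apply_rigid(rigid_transform(Rz), rbind(c(1, 0, 0))),
               rbind(c(0, 1, 0)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    t_ <- rigid_transform(random_rotation(), rnorm(3, sd = 5))
    p <- matrix(rnorm(6), 2, 3)
    q <- apply_rigid(t_, p)
    expect_lt(abs(sqrt(sum((q[1, ] - q[2, ])^2)) -
                    sqrt(sum((p[1, ] - p[2, ])^2))), 1e-10)
  }
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
})

test_that("transform inversion and Euler conversions round-trip", {
  set.seed(2)
  for (i in 1:10) {
    t_ <- rigid_transform(random_rotation(), rnorm(3))
    p <- matrix(rnorm(9), 3, 3)
    expect_equal(apply_rigid(invert_transform(t_), apply_rigid(t_, p)), p,
                 tolerance = 1e-10)
    ang <- runif(3, -1.2, 1.2)
    R <- euler_to_matrix(ang[1], ang[2], ang[3])
    back <- labyrinthSeg:::matrix_to_euler(R)
    expect_equal(euler_to_matrix(back[1], back[2], back[3]), R,
                 tolerance = 1e-10)
  }
})

test_that("tricubic interpolation reproduces constants, grid values and cubics", {
  set.seed(3)
  vol <- volume3d(array(7.5, dim = c(6, 6, 6)))
  q <- matrix(runif(30, 0, 5), 10, 3)
  expect_equal(as.numeric(tricubic_interpolate(vol, q)), rep(7.5, 10))

  arr <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  vol <- volume3d(arr, spacing = c(0.5, 0.5, 1), origin = c(-1, 2, 0))
  idx <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  at_grid <- tricubic_interpolate(vol,
    sweep(idx %*% diag(vol$spacing), 2, vol$origin, "+"))
  expect_equal(as.numeric(at_grid), as.numeric(arr), tolerance = 1e-12)

  # exact on a linear ramp in world units
  f <- function(p) 2 * p[, 1] + 3 * p[, 2] - p[, 3]
  ramp <- volume3d(array(f(sweep(idx %*% diag(c(0.5, 0.5, 1)), 2,
                                 c(-1, 2, 0), "+")), dim = c(8, 8, 8)),
                   spacing = c(0.5, 0.5, 1), origin = c(-1, 2, 0))
  qi <- cbind(runif(50, 0.5, 2), runif(50, 2.5, 5), runif(50, 1, 6))
  expect_equal(as.numeric(tricubic_interpolate(ramp, qi)), f(qi),
               tolerance = 1e-9)

  # out-of-bounds queries return the volume minimum and are flagged
  oob <- tricubic_interpolate(ramp, rbind(c(-50, 0, 0)))
  expect_true(attr(oob, "oob")[1])
  expect_equal(as.numeric(oob), min(ramp$data))
})

test_that("mutual information satisfies its defining identities", {
  set.seed(4)
  arr <- array(rnorm(20^3), dim = c(20, 20, 20))
  v <- volume3d(arr)
  self <- mutual_information(v, v, bins = 16)
  expect_equal(self$mi, self$h_x, tolerance = 1e-12)
  expect_equal(self$h_x, self$h_y, tolerance = 1e-12)

  # joint distribution exactly [[0.5, 0], [0, 0.5]] -> MI = 1 bit
  a <- volume3d(array(rep(c(0, 1), 32), dim = c(4, 4, 4)))
  mi2 <- mutual_information(a, a, bins = 2)
  expect_equal(mi2$mi, 1, tolerance = 1e-12)
  expect_equal(mi2$h_xy, 1, tolerance = 1e-12)

  expect_error(mutual_information(v, volume3d(array(1, c(2, 2, 2)))),
               "same grid")
})

test_that("joint entropy is bounded by the marginal entropies", {
  set.seed(5)
  for (i in 1:10) {
    x <- volume3d(array(rnorm(1000), dim = c(10, 10, 10)))
    y <- volume3d(array(rnorm(1000) + 0.5 * x$data, dim = c(10, 10, 10)))
    mi <- mutual_information(x, y, bins = 8)
    expect_lte(mi$h_xy, mi$h_x + mi$h_y + 1e-12)
    expect_gte(mi$mi, -1e-12)
    expect_equal(sum(mi$joint), mi$n)
  }
})

test_that("independently shuffled images carry almost no mutual information", {
  set.seed(6)
  n <- 100000
  base <- rnorm(n)
  x <- volume3d(array(sample(base), dim = c(50, 50, 40)))
  y <- volume3d(array(sample(base), dim = c(50, 50, 40)))
  expect_lte(mutual_information(x, y, bins = 32)$mi, 0.05)
})

test_that("registering an image to itself stays at the identity", {
  sp <- small_spec()
  s <- generate_phantom(sp, seed = 20)
  reg <- register_rigid(s$volume, s$volume)
  expect_lte(sqrt(sum(reg$transform$b^2)), 0.1 * max(sp$spacing))
  expect_lte(rotation_angle(reg$transform$A) * 180 / pi, 0.1)
  for (tr in reg$mi_trace_levels)
    expect_true(all(diff(tr) >= -1e-12))
  flat <- volume3d(array(1, dim = c(8, 8, 8)))
  expect_error(register_rigid(flat, flat), "constant image")
})

test_that("a known rigid offset is recovered within half a voxel", {
  sp <- small_spec()
  center <- (sp$grid_shape - 1) * sp$spacing / 2
  s <- generate_phantom(sp, seed = 21,
                        pose = similarity_transform(translation = center))
  true_tf <- rigid_transform(euler_to_matrix(0.08, -0.05, 0.1),
                             c(1.2, -0.8, 1.5))
  moving <- resample_volume(s$volume, s$volume, true_tf)
  reg <- register_rigid(s$volume, moving)
  expected <- invert_transform(true_tf)
  expect_lte(sqrt(sum((reg$transform$b - expected$b)^2)) / sp$spacing[1], 0.5)
  expect_lte(rotation_angle(reg$transform$A, expected$A) * 180 / pi, 1)
  expect_true(all(diff(reg$mi_trace) >= -1e-12))
})

test_that("ROI localization maps the atlas box onto the subject", {
  sp <- small_spec()
  s <- generate_phantom(sp, seed = 22)
  box <- mask_roi(s$truth_mask, 0L)
  loc <- localize_roi(s$volume, s$volume, box, margin_voxels = 3L)
  expect_true(all(loc$roi$lower <= box$lower) &&
                all(loc$roi$lower >= box$lower - 4L))
  expect_true(all(loc$roi$upper >= box$upper) &&
                all(loc$roi$upper <= box$upper + 4L))

  # pure translation of the subject shifts the box by the same amount
  shift_vox <- c(3L, -2L, 2L)
  tf <- rigid_transform(diag(3), shift_vox * sp$spacing)
  moved <- resample_volume(s$volume, s$volume, tf)
  loc2 <- localize_roi(moved, s$volume, box, margin_voxels = 0L)
  # moved(x) = subject(x + shift) so the structure sits at -shift in the
  # moved frame
  expect_true(all(abs(loc2$roi$lower - (box$lower - shift_vox)) <= 1))
  expect_true(all(abs(loc2$roi$upper - (box$upper - shift_vox)) <= 1))
  expect_error(roi_box(c(0, 0, 0), c(0, 5, 5)), "lower < upper")
})
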