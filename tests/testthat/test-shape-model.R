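test_that("centroid size matches its closed form and is homogeneous", {
  expect_equal(centroid_size(matrix(c(1, 2, 3), 4, 3, byrow = TRUE)), 0)
  expect_equal(centroid_size(rbind(c(0, 0, 0), c(2, 0, 0))), sqrt(2))
  set.seed(1)
  s <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(3.7 * s), 3.7 * centroid_size(s))
  expect_error(centroid_size(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("Procrustes distance is the summed squared correspondence error", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(0, 1, 0))
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), 2)
  expect_equal(procrustes_distance(b, a), procrustes_distance(a, b))
  expect_error(procrustes_distance(a, rbind(a, c(1, 1, 1))), "same number")
})

test_that("SVD alignment recovers similarity maps exactly", {
  set.seed(2)
  ref <- matrix(rnorm(24), 8, 3)
  al <- align_to_reference(ref, ref)
  expect_equal(al$aligned, ref, tolerance = 1e-12)
  expect_equal(al$transform$scale, 1, tolerance = 1e-12)
  expect_equal(al$transform$rotation, diag(3), tolerance = 1e-10)

  Rz <- euler_to_matrix(0, 0, pi / 2)
  moved <- sweep(ref %*% t(Rz), 2, c(5, -3, 2), "+")
  back <- align_to_reference(moved, ref)
  expect_lt(procrustes_distance(back$aligned, ref), 1e-12)
  expect_equal(apply_similarity(back$transform, moved), back$aligned,
               tolerance = 1e-10)
})

test_that("alignment is near-optimal against brute-force rotation sampling", {
  set.seed(3)
  shape <- matrix(rnorm(30), 10, 3)
  ref <- shape %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.05), 10, 3)
  al <- align_to_reference(shape, ref)
  d_aligned <- procrustes_distance(al$aligned, ref)
  # oracle: best over 1000 random rotations of the normalized shape
  c_s <- colMeans(shape); c_r <- colMeans(ref)
  xn <- sweep(shape, 2, c_s) * centroid_size(ref) / centroid_size(shape)
  best <- Inf
  for (i in 1:1000) {
    cand <- sweep(xn %*% t(random_rotation()), 2, c_r, "+")
    best <- min(best, procrustes_distance(cand, ref))
  }
  expect_lte(d_aligned, best + 1e-12)
})

test_that("degenerate (collinear) shapes are rejected", {
  line <- cbind(1:5, 0, 0)
  ref <- matrix(rnorm(15), 5, 3)
  expect_error(align_to_reference(line, ref), "rank-deficient")
  expect_error(align_to_reference(matrix(1, 5, 3), ref), "zero centroid size")
})

test_that("GPA on identical shapes converges immediately", {
  set.seed(4)
  s <- matrix(rnorm(18), 6, 3)
  g <- generalized_procrustes_align(rep(list(s), 5))
  expect_true(g$converged)
  expect_lte(g$iterations, 2L)
  for (sh in g$shapes)
    expect_lt(procrustes_distance(sh, g$mean), 1e-12)
})

test_that("GPA is invariant to similarity transforms of its input", {
  set.seed(5)
  base <- matrix(rnorm(36), 12, 3)
  shapes <- lapply(1:8, function(i)
    apply_similarity(similarity_transform(runif(1, 0.5, 2),
                                          random_rotation(),
                                          rnorm(3, sd = 10)), base))
  g <- generalized_procrustes_align(shapes)
  expect_true(g$converged)
  # all aligned shapes coincide and the mean equals the normalized base
  # up to a global rotation
  for (sh in g$shapes) expect_lt(procrustes_distance(sh, g$mean), 1e-16)
  rec <- align_to_reference(g$mean, base)$aligned
  expect_lt(procrustes_distance(rec, base) / centroid_size(base)^2, 1e-8)
  # aligned-set invariants: centroid 0, unit centroid size
  for (sh in g$shapes) {
    expect_lt(max(abs(colMeans(sh))), 1e-8)
    expect_lt(abs(centroid_size(sh) - 1), 1e-8)
  }
})

test_that("the GPA objective never increases across iterations", {
  set.seed(6)
  shapes <- lapply(1:10, function(i) matrix(rnorm(30), 10, 3))
  g <- generalized_procrustes_align(shapes)
  expect_true(all(diff(g$objective_trace) <= 1e-12))
  expect_error(generalized_procrustes_align(shapes[1]), "at least two")
})

test_that("non-convergence sets the flag and warns rather than failing", {
  set.seed(7)
  shapes <- lapply(1:6, function(i) matrix(rnorm(30), 10, 3))
  expect_warning(g <- generalized_procrustes_align(shapes, tol = 0,
                                                   max_iter = 2L),
                 "did not converge")
  expect_false(g$converged)
  expect_identical(g$iterations, 2L)
})

test_that("the GPA mean recovers the generating template of a jittered cohort", {
  sp <- small_spec()
  template <- sample_landmarks(sp)
  shapes <- lapply(1:50, function(i) {
    set.seed(1000 + i)
    spec_i <- labyrinthSeg:::jitter_spec(sp)
    pose <- similarity_transform(runif(1, 0.9, 1.1), random_rotation(),
                                 rnorm(3, sd = 2))
    sample_landmarks(spec_i, pose)
  })
  g <- generalized_procrustes_align(shapes)
  # compare in template units after similarity alignment
  rec <- align_to_reference(g$mean, template)$aligned
  per_lm <- sqrt(rowSums((rec - template)^2))
  # jitter displaces a landmark by ~5% of its centroid distance; the mean of
  # 50 samples must land within twice that sd
  radius <- sqrt(rowSums(sweep(template, 2, colMeans(template))^2))
  expect_true(all(per_lm <= 2 * sp$jitter_sd * radius + 0.05))
})

test_that("the mean shape is the normalized pointwise average", {
  set.seed(8)
  shapes <- lapply(1:5, function(i) matrix(rnorm(21), 7, 3))
  m <- compute_mean_shape(shapes)
  raw <- Reduce(`+`, shapes) / 5
  raw <- sweep(raw, 2, colMeans(raw))
  expect_equal(m, raw / sqrt(sum(raw^2)), tolerance = 1e-12)
  one <- compute_mean_shape(shapes[1])
  n1 <- sweep(shapes[[1]], 2, colMeans(shapes[[1]]))
  expect_equal(one, n1 / sqrt(sum(n1^2)), tolerance = 1e-12)
  # two shapes symmetric about a template average back to the template
  tmpl <- matrix(rnorm(21), 7, 3)
  delta <- matrix(rnorm(21, sd = 0.1), 7, 3)
  m2 <- compute_mean_shape(list(tmpl + delta, tmpl - delta))
  tn <- sweep(tmpl, 2, colMeans(tmpl))
  expect_equal(m2, tn / sqrt(sum(tn^2)), tolerance = 1e-12)
})
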