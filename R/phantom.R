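#' Specification of a synthetic inner-ear phantom
#'
#' Describes a T2-like inner-ear phantom: a bright fluid-filled labyrinth on
#' a dark background. The labyrinth is the union of three parametric
#' primitives in a canonical (unposed) frame centered on the vestibule:
#'
#' * **cochlea** — a tube of constant radius swept along a conical helix
#'   (radius shrinking linearly with the turn parameter, apex rising with a
#'   constant pitch);
#' * **vestibule** — an axis-aligned ellipsoid at the canonical origin,
#'   tangent to the base of the cochlear helix;
#' * **canals** — three partial tori with mutually roughly orthogonal ring
#'   planes, attached around the vestibule.
#'
#' Each generated sample applies a random similarity pose (translation,
#' rotation, isotropic scale) about the grid center, then adds a smooth
#' multiplicative bias field and additive Gaussian noise. Additive Gaussian
#' (rather than Rician) noise is a deliberate simplification.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing mm per axis (3 positive reals).
#' @param cochlea list: `turns` (>0), `tube_radius` (mm), `pitch` (mm per
#'   turn), `base_radius` (mm, helix radius at the base), `taper` (fraction
#'   of `base_radius` lost over the full spiral), `center` (mm, canonical).
#' @param vestibule list: `semi_axes` (3 mm values).
#' @param canals list of 3 lists: `major_radius`, `minor_radius` (mm),
#'   `center` (mm), `normal` (ring-plane normal), `arc_deg` (swept arc).
#' @param fg_intensity,bg_intensity foreground/background intensity
#'   (arbitrary units, `fg > bg`).
#' @param noise_sd additive Gaussian noise sd (intensity units, >= 0).
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (dimensionless, >= 0).
#' @param n_landmarks number of surface landmarks (>= 3).
#' @param jitter_sd relative sd of per-sample shape-parameter jitter used by
#'   [generate_cohort()].
#' @param pose_trans_voxels half-range of the uniform pose translation, in
#'   voxels per axis.
#' @param pose_rot_deg half-range of the uniform per-axis pose rotation
#'   (degrees).
#' @param pose_scale_range length-2 range of the uniform isotropic pose
#'   scale.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(0.4, 0.4, 0.4),
                         cochlea = list(turns = 2.5, tube_radius = 1.0,
                                        pitch = 1.8, base_radius = 3.0,
                                        taper = 0.55,
                                        center = c(-4.2, 0, -2.0)),
                         vestibule = list(semi_axes = c(2.8, 2.2, 2.0)),
                         canals = list(
                           list(major_radius = 3.2, minor_radius = 0.9,
                                center = c(2.2, 0, 2.6), normal = c(0, 0, 1),
                                arc_deg = 270),
                           list(major_radius = 3.2, minor_radius = 0.9,
                                center = c(1.0, 2.4, 1.6), normal = c(1, 0, 0),
                                arc_deg = 270),
                           list(major_radius = 3.2, minor_radius = 0.9,
                                center = c(1.0, -2.4, 1.6), normal = c(0, 1, 0),
                                arc_deg = 270)),
                         fg_intensity = 180, bg_intensity = 30,
                         noise_sd = 18, bias_amplitude = 0.2,
                         n_landmarks = 64L,
                         jitter_sd = 0.05,
                         pose_trans_voxels = 5,
                         pose_rot_deg = 10,
                         pose_scale_range = c(0.9, 1.1)) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing = as.numeric(spacing),
                         cochlea = cochlea, vestibule = vestibule,
                         canals = canals,
                         fg_intensity = fg_intensity,
                         bg_intensity = bg_intensity,
                         noise_sd = noise_sd,
                         bias_amplitude = bias_amplitude,
                         n_landmarks = as.integer(n_landmarks),
                         jitter_sd = jitter_sd,
                         pose_trans_voxels = pose_trans_voxels,
                         pose_rot_deg = pose_rot_deg,
                         pose_scale_range = as.numeric(pose_scale_range)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be 3 positive integers")
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("spacing must be 3 positive reals (mm)")
    if (cochlea$turns <= 0 || cochlea$tube_radius <= 0 ||
        cochlea$pitch <= 0 || cochlea$base_radius <= 0 ||
        cochlea$taper < 0 || cochlea$taper >= 1)
      stop("cochlea parameters must be positive (taper in [0, 1))")
    if (any(vestibule$semi_axes <= 0))
      stop("vestibule semi-axes must be positive")
    if (length(canals) != 3L)
      stop("exactly three semicircular canals are required")
    for (cn in canals)
      if (cn$major_radius <= 0 || cn$minor_radius <= 0 ||
          cn$arc_deg <= 0 || cn$arc_deg > 360)
        stop("canal radii must be positive, arc in (0, 360] degrees")
    if (fg_intensity <= bg_intensity)
      stop("fg_intensity must exceed bg_intensity")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
    if (n_landmarks < 3L) stop("n_landmarks must be >= 3")
    if (jitter_sd < 0) stop("jitter_sd must be >= 0")
    if (length(pose_scale_range) != 2L || any(pose_scale_range <= 0) ||
        pose_scale_range[1] > pose_scale_range[2])
      stop("pose_scale_range must be an increasing positive pair")
  })
  invisible(spec)
}

# --- canonical geometry -----------------------------------------------------

# Points and tangents of the conical helix at parameters t in [0, 2*pi*turns].
helix_curve <- function(cochlea, t) {
  tmax <- 2 * pi * cochlea$turns
  r <- cochlea$base_radius * (1 - cochlea$taper * t / tmax)
  x <- r * cos(t)
  y <- r * sin(t)
  z <- cochlea$pitch * t / (2 * pi)
  sweep(cbind(x, y, z), 2, cochlea$center, "+")
}

helix_tangent <- function(cochlea, t) {
  tmax <- 2 * pi * cochlea$turns
  r <- cochlea$base_radius * (1 - cochlea$taper * t / tmax)
  dr <- -cochlea$base_radius * cochlea$taper / tmax
  dx <- dr * cos(t) - r * sin(t)
  dy <- dr * sin(t) + r * cos(t)
  dz <- rep(cochlea$pitch / (2 * pi), length(t))
  d <- cbind(dx, dy, dz)
  d / sqrt(rowSums(d^2))
}

# Rotation taking the canonical torus normal (0,0,1) onto `normal`.
normal_to_rotation <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2],
         z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  c_ <- sum(z * n)
  if (sum(v^2) < 1e-16) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip about x for antiparallel normal
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Dense sample points along the helix center line (arc step ~ tube_radius/8).
helix_samples <- function(cochlea, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- cochlea$tube_radius / 8
  tmax <- 2 * pi * cochlea$turns
  # generous arc-length estimate for the number of samples
  arc <- tmax * sqrt(cochlea$base_radius^2 + (cochlea$pitch / (2 * pi))^2)
  n <- max(64L, ceiling(arc / step_mm))
  helix_curve(cochlea, seq(0, tmax, length.out = n))
}

# Inside tests for canonical-frame points (n x 3), vectorized per primitive.
inside_vestibule <- function(pts, vestibule) {
  rowSums(sweep(pts, 2, vestibule$semi_axes, "/")^2) <= 1
}

inside_canal <- function(pts, canal) {
  Rm <- normal_to_rotation(canal$normal)
  q <- sweep(pts, 2, canal$center, "-") %*% Rm  # = t(Rm) applied rowwise
  rad <- sqrt(q[, 1]^2 + q[, 2]^2)
  d2 <- (rad - canal$major_radius)^2 + q[, 3]^2
  u <- atan2(q[, 2], q[, 1]) %% (2 * pi)
  d2 <= canal$minor_radius^2 & u <= canal$arc_deg * pi / 180
}

inside_cochlea <- function(pts, cochlea, curve = NULL) {
  if (is.null(curve)) curve <- helix_samples(cochlea)
  # cheap bounding-box prefilter before the exact distance-to-curve test
  lo <- apply(curve, 2, min) - cochlea$tube_radius - 1e-9
  hi <- apply(curve, 2, max) + cochlea$tube_radius + 1e-9
  cand <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
          pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
          pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  out <- logical(nrow(pts))
  if (any(cand))
    out[cand] <- cpp_min_dists(pts[cand, , drop = FALSE], curve) <=
      cochlea$tube_radius
  out
}

inside_labyrinth <- function(pts, spec, curve = NULL) {
  ins <- inside_cochlea(pts, spec$cochlea, curve) |
    inside_vestibule(pts, spec$vestibule)
  for (cn in spec$canals) ins <- ins | inside_canal(pts, cn)
  ins
}

#' Dense surface point cloud of the canonical phantom
#'
#' Quasi-uniform samples on the surface of each primitive in the canonical
#' (unposed) frame; used for fit checking and available for validation.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_primitive approximate samples per primitive.
#' @return n x 3 matrix of mm coordinates with a `primitive` attribute
#'   (character vector naming the source primitive of each row).
#' @export
phantom_surface_points <- function(spec, n_per_primitive = 1500L) {
  parts <- list(
    cochlea = primitive_surface("cochlea", spec, n_per_primitive),
    vestibule = primitive_surface("vestibule", spec, n_per_primitive),
    canal1 = primitive_surface("canal", spec, n_per_primitive, canal = 1L),
    canal2 = primitive_surface("canal", spec, n_per_primitive, canal = 2L),
    canal3 = primitive_surface("canal", spec, n_per_primitive, canal = 3L))
  pts <- do.call(rbind, parts)
  attr(pts, "primitive") <- rep(names(parts), vapply(parts, nrow, 1L))
  pts
}

# Golden-ratio (u, v) surface sampling of one primitive; deterministic.
primitive_surface <- function(what, spec, k, canal = 1L) {
  k <- as.integer(k)
  i <- seq_len(k) - 1L
  golden <- (sqrt(5) - 1) / 2
  u <- (i + 0.5) / k
  v <- (i * golden) %% 1
  if (what == "cochlea") {
    co <- spec$cochlea
    tmax <- 2 * pi * co$turns
    p <- helix_curve(co, u * tmax)
    tg <- helix_tangent(co, u * tmax)
    zref <- c(0, 0, 1)
    e1 <- cbind(tg[, 2] * zref[3] - tg[, 3] * zref[2],
                tg[, 3] * zref[1] - tg[, 1] * zref[3],
                tg[, 1] * zref[2] - tg[, 2] * zref[1])
    nr <- sqrt(rowSums(e1^2))
    bad <- nr < 1e-8
    if (any(bad)) { e1[bad, ] <- rep(c(1, 0, 0), each = sum(bad)); nr[bad] <- 1 }
    e1 <- e1 / nr
    e2 <- cbind(tg[, 2] * e1[, 3] - tg[, 3] * e1[, 2],
                tg[, 3] * e1[, 1] - tg[, 1] * e1[, 3],
                tg[, 1] * e1[, 2] - tg[, 2] * e1[, 1])
    th <- 2 * pi * v
    p + co$tube_radius * (e1 * cos(th) + e2 * sin(th))
  } else if (what == "vestibule") {
    z <- 1 - 2 * u
    th <- 2 * pi * (i * golden)
    s <- sqrt(pmax(0, 1 - z^2))
    sweep(cbind(s * cos(th), s * sin(th), z), 2,
          spec$vestibule$semi_axes, "*")
  } else {
    cn <- spec$canals[[canal]]
    uu <- u * cn$arc_deg * pi / 180
    vv <- 2 * pi * v
    ring <- cn$major_radius + cn$minor_radius * cos(vv)
    q <- cbind(ring * cos(uu), ring * sin(uu), cn$minor_radius * sin(vv))
    sweep(q %*% t(normal_to_rotation(cn$normal)), 2, cn$center, "+")
  }
}

# --- landmark sampling ------------------------------------------------------

# Fixed landmark allocation across the five primitives.  The weights are the
# approximate relative surface areas of the default geometry, frozen so that
# shape-jittered cohort samples keep identical per-primitive counts (and
# hence point-to-point correspondence).
landmark_allocation <- function(n) {
  w <- c(cochlea = 0.40, vestibule = 0.22,
         canal1 = 0.38 / 3, canal2 = 0.38 / 3, canal3 = 0.38 / 3)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Sample corresponding surface landmarks of a phantom
#'
#' Landmarks are placed at fixed parametric surface coordinates of the five
#' primitives (the same parameter list for every phantom with the same
#' `n_landmarks`), then mapped through the pose. Point-to-point
#' correspondence across a cohort therefore holds by construction.
#'
#' @param spec a [phantom_spec()] (possibly shape-jittered).
#' @param pose a [similarity_transform()] mapping canonical to world mm
#'   coordinates.
#' @return n_landmarks x 3 matrix of world mm coordinates.
#' @export
sample_landmarks <- function(spec, pose = similarity_transform()) {
  validate_phantom_spec(spec)
  alloc <- landmark_allocation(spec$n_landmarks)
  parts <- list()
  if (alloc[1] > 0) parts$cochlea <- primitive_surface("cochlea", spec, alloc[1])
  if (alloc[2] > 0) parts$vestibule <- primitive_surface("vestibule", spec, alloc[2])
  for (c_ in 1:3)
    if (alloc[2 + c_] > 0)
      parts[[paste0("canal", c_)]] <-
        primitive_surface("canal", spec, alloc[2 + c_], canal = c_)
  pts <- do.call(rbind, parts)
  rownames(pts) <- NULL
  apply_similarity(pose, pts)
}

# --- phantom generation -----------------------------------------------------

#' Generate one synthetic inner-ear phantom
#'
#' Voxelizes the posed labyrinth (union of the three parametric primitives)
#' on the spec's grid, then builds the intensity volume as
#' `level * (1 + bias_amplitude * B) + noise` where `level` is
#' `fg_intensity` inside the labyrinth and `bg_intensity` outside, `B` is a
#' smooth random cosine bias field normalized to unit peak amplitude, and
#' the noise is i.i.d. Gaussian. Deterministic for fixed `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param pose optional [similarity_transform()]; when `NULL` a random pose
#'   is drawn from the spec's pose distributions (translation uniform in
#'   +/- `pose_trans_voxels` voxels, per-axis rotation uniform in
#'   +/- `pose_rot_deg` degrees, scale uniform in `pose_scale_range`).
#' @return A `phantom_sample`: list with `volume` ([volume3d()]),
#'   `truth_mask` ([binary_mask()]), `landmarks` (n x 3 mm), `pose`, `seed`
#'   and the (possibly jittered) `spec`.
#' @export
generate_phantom <- function(spec, seed = 1L, pose = NULL) {
  validate_phantom_spec(spec)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  center <- (spec$grid_shape - 1) * spec$spacing / 2
  if (is.null(pose)) {
    tr <- stats::runif(3, -spec$pose_trans_voxels, spec$pose_trans_voxels) *
      spec$spacing
    ang <- stats::runif(3, -spec$pose_rot_deg, spec$pose_rot_deg) * pi / 180
    sc <- stats::runif(1, spec$pose_scale_range[1], spec$pose_scale_range[2])
    pose <- similarity_transform(sc, euler_to_matrix(ang[1], ang[2], ang[3]),
                                 center + tr)
  }
  check_phantom_fit(spec, pose)

  vol0 <- volume3d(array(0, dim = spec$grid_shape), spec$spacing, c(0, 0, 0))
  world <- grid_world_coords(vol0)
  canon <- apply_similarity(invert_transform(pose), world)
  curve <- helix_samples(spec$cochlea)
  ins <- inside_labyrinth(canon, spec, curve)
  if (!any(ins))
    stop("phantom truth mask is empty: structures missed the grid")
  mask <- array(ins, dim = spec$grid_shape)

  level <- array(spec$bg_intensity, dim = spec$grid_shape)
  level[mask] <- spec$fg_intensity

  data <- level
  if (spec$bias_amplitude > 0) {
    bias <- random_bias_field(spec$grid_shape, world, center)
    data <- data * (1 + spec$bias_amplitude * bias)
  }
  if (spec$noise_sd > 0)
    data <- data + array(stats::rnorm(length(data), 0, spec$noise_sd),
                         dim = spec$grid_shape)

  lm <- sample_landmarks(spec, pose)
  structure(list(volume = volume3d(data, spec$spacing, c(0, 0, 0)),
                 truth_mask = binary_mask(mask, spec$spacing, c(0, 0, 0)),
                 landmarks = lm, pose = pose, seed = seed, spec = spec),
            class = "phantom_sample")
}

# Smooth standardized bias field: sum of three random-direction cosines,
# normalized to max |B| = 1.  Consumes RNG (phases/directions/weights).
random_bias_field <- function(grid_shape, world, center) {
  extent <- pmax(grid_shape, 2) * 1  # normalize coordinates below
  b <- 0
  xc <- sweep(world, 2, center, "-")
  span <- apply(world, 2, function(v) diff(range(v)) + 1e-9)
  xn <- sweep(xc, 2, span, "/")  # roughly [-0.5, 0.5] per axis
  for (m in 1:3) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    freq <- stats::runif(1, 0.5, 1.2)
    phase <- stats::runif(1, 0, 2 * pi)
    w <- stats::runif(1, 0.5, 1)
    b <- b + w * cos(2 * pi * freq * (xn %*% dir) + phase)
  }
  b <- b / max(abs(b))
  array(b, dim = grid_shape)
}

# Every posed surface point must stay >= 2 voxels inside the grid.
check_phantom_fit <- function(spec, pose, margin_voxels = 2) {
  cloud <- phantom_surface_points(spec, 600L)
  prim <- attr(cloud, "primitive")
  posed <- apply_similarity(pose, cloud)
  lo <- margin_voxels * spec$spacing
  hi <- (spec$grid_shape - 1 - margin_voxels) * spec$spacing
  bad <- posed[, 1] < lo[1] | posed[, 2] < lo[2] | posed[, 3] < lo[3] |
         posed[, 1] > hi[1] | posed[, 2] > hi[2] | posed[, 3] > hi[3]
  if (any(bad))
    stop(sprintf(
      "phantom primitive '%s' does not fit in the grid with a %g-voxel margin",
      prim[which(bad)[1]], margin_voxels))
  invisible(TRUE)
}

#' Generate a cohort of shape-jittered phantoms
#'
#' Each sample gets independent multiplicative Gaussian jitter (relative sd
#' `spec$jitter_sd`) on the primitive shape parameters (cochlea tube radius,
#' pitch and base radius; vestibule semi-axes; canal radii) and an
#' independent random similarity pose. Landmark counts are identical across
#' samples, so the cohort's landmark matrices are in correspondence.
#'
#' @param n number of samples (>= 0).
#' @param spec base [phantom_spec()].
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @return list of `phantom_sample` objects (length `n`).
#' @export
generate_cohort <- function(n, spec = phantom_spec(), seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("`n` must be a nonnegative integer")
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    seed_i <- (as.integer(seed) %% 1000000L) * 1000L + i
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed_i + 500000000L)
    spec_i <- jitter_spec(spec)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    generate_phantom(spec_i, seed = seed_i)
  })
}

jitter_spec <- function(spec) {
  j <- function(x) {
    f <- 1 + stats::rnorm(length(x), 0, spec$jitter_sd)
    x * pmin(pmax(f, 1 - 3 * spec$jitter_sd), 1 + 3 * spec$jitter_sd)
  }
  spec$cochlea$tube_radius <- j(spec$cochlea$tube_radius)
  spec$cochlea$pitch <- j(spec$cochlea$pitch)
  spec$cochlea$base_radius <- j(spec$cochlea$base_radius)
  spec$vestibule$semi_axes <- j(spec$vestibule$semi_axes)
  for (k in seq_along(spec$canals)) {
    spec$canals[[k]]$major_radius <- j(spec$canals[[k]]$major_radius)
    spec$canals[[k]]$minor_radius <- j(spec$canals[[k]]$minor_radius)
  }
  validate_phantom_spec(spec)
  spec
}
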